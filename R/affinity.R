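#' Define a chemical species
#'
#' A species is a host (receptor or coassembly site population), a reporter
#' dye, or an analyte. Ids must be unique within a scenario and the role is
#' fixed at creation.
#'
#' @param id Short unique identifier (single non-empty string).
#' @param role One of `"host"`, `"dye"`, `"analyte"`.
#' @param name Optional free-text name.
#' @return An object of class `species`.
#' @examples
#' species("GC5A", "host", "guanidinium calixarene")
#' @export
species <- function(id, role = c("host", "dye", "analyte"), name = id) {
  role <- match.arg(role)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("species id must be a single non-empty string", call. = FALSE)
  }
  structure(list(id = id, role = role, name = name), class = "species")
}

#' @export
print.species <- function(x, ...) {
  cat(sprintf("<species> %s [%s] %s\n", x$id, x$role, x$name))
  invisible(x)
}

#' Build an association-constant table
#'
#' Holds pairwise 1:1 association constants Ka (in M^-1) between hosts and
#' guests (dyes or analytes), optionally indexed by an environmental
#' condition label such as a pH value. A (host, guest) pair absent from the
#' table is interpreted as Ka = 0, i.e. no interaction.
#'
#' @param entries A data.frame with columns `host`, `guest`, `Ka_per_M` and
#'   optionally `condition` (defaults to `"default"`).
#' @return An object of class `affinity_table` with elements `entries`
#'   (tidy data.frame) and `conditions` (ordered unique condition labels).
#' @examples
#' affinity_table(data.frame(host = "H1", guest = "D1", Ka_per_M = 1e6))
#' @export
affinity_table <- function(entries) {
  if (!is.data.frame(entries)) stop("entries must be a data.frame", call. = FALSE)
  required <- c("host", "guest", "Ka_per_M")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols)) {
    stop("affinity table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"condition" %in% names(entries)) entries$condition <- "default"
  entries$host <- as.character(entries$host)
  entries$guest <- as.character(entries$guest)
  entries$condition <- as.character(entries$condition)
  ka <- entries$Ka_per_M
  if (!is.numeric(ka) || any(!is.finite(ka))) {
    stop("every Ka must be finite and numeric", call. = FALSE)
  }
  if (any(ka < 0)) stop("negative Ka rejected; use Ka = 0 for no interaction", call. = FALSE)
  key <- paste(entries$host, entries$guest, entries$condition, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (host, guest, condition) entries in affinity table", call. = FALSE)
  }
  entries <- entries[, c("host", "guest", "condition", "Ka_per_M")]
  structure(
    list(entries = entries, conditions = unique(entries$condition)),
    class = "affinity_table"
  )
}

#' @export
print.affinity_table <- function(x, ...) {
  cat(sprintf("<affinity_table> %d entries, %d condition(s): %s\n",
              nrow(x$entries), length(x$conditions),
              paste(x$conditions, collapse = ", ")))
  print(utils::head(x$entries, 10))
  if (nrow(x$entries) > 10) cat("...\n")
  invisible(x)
}

#' Look up one association constant
#'
#' @param affinities An [affinity_table()].
#' @param host,guest Species ids.
#' @param condition Condition label.
#' @return Ka in M^-1; 0 when the pair is absent.
#' @export
ka_lookup <- function(affinities, host, guest, condition = "default") {
  stopifnot(inherits(affinities, "affinity_table"))
  e <- affinities$entries
  hit <- e$host == host & e$guest == guest & e$condition == condition
  if (!any(hit)) return(0)
  e$Ka_per_M[which(hit)[1L]]
}

#' Dense Ka matrix for a set of hosts and guests
#'
#' @inheritParams ka_lookup
#' @param hosts,guests Character vectors of species ids.
#' @return Numeric matrix (guests in rows, hosts in columns); absent pairs 0.
#' @export
ka_matrix <- function(affinities, hosts, guests, condition = "default") {
  stopifnot(inherits(affinities, "affinity_table"))
  K <- matrix(0, nrow = length(guests), ncol = length(hosts),
              dimnames = list(guests, hosts))
  e <- affinities$entries[affinities$entries$condition == condition, , drop = FALSE]
  keep <- e$host %in% hosts & e$guest %in% guests
  e <- e[keep, , drop = FALSE]
  if (nrow(e)) K[cbind(e$guest, e$host)] <- e$Ka_per_M
  K
}

#' Describe the contents of one solution
#'
#' A composition lists the analytical (total) concentrations, in molar
#' units, of every host, dye and analyte present in one sensor-unit
#' solution, together with the environmental condition label under which the
#' affinities apply.
#'
#' @param host_totals Named numeric vector of host total concentrations (M).
#' @param dye_totals Named numeric vector of dye total concentrations (M).
#' @param analyte_totals Named numeric vector of analyte totals (M); may be
#'   empty or zero.
#' @param condition Condition label (must exist in the affinity table used).
#' @return An object of class `composition`.
#' @examples
#' composition(c(H1 = 1e-6), c(D1 = 1e-6))
#' @export
composition <- function(host_totals, dye_totals, analyte_totals = numeric(0),
                        condition = "default") {
  check_totals <- function(x, what, require_one = FALSE) {
    if (length(x) == 0 && !require_one) return(stats::setNames(numeric(0), character(0)))
    if (require_one && length(x) == 0) {
      stop("at least one ", what, " must be present", call. = FALSE)
    }
    if (is.null(names(x)) || any(!nzchar(names(x))) || anyDuplicated(names(x))) {
      stop(what, " totals must have unique non-empty names", call. = FALSE)
    }
    if (!is.numeric(x) || any(!is.finite(x))) {
      stop(what, " totals must be finite numbers", call. = FALSE)
    }
    if (any(x < 0)) stop("negative ", what, " concentration rejected", call. = FALSE)
    x
  }
  host_totals <- check_totals(host_totals, "host", require_one = TRUE)
  dye_totals <- check_totals(dye_totals, "dye", require_one = TRUE)
  analyte_totals <- check_totals(analyte_totals, "analyte")
  overlap <- intersect(names(host_totals), c(names(dye_totals), names(analyte_totals)))
  if (length(overlap)) {
    stop("species id(s) used as both host and guest: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  structure(
    list(host_totals = host_totals, dye_totals = dye_totals,
         analyte_totals = analyte_totals, condition = condition),
    class = "composition"
  )
}

#' @export
print.composition <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(sprintf("%s=%.3g M", names(v), v), collapse = ", ") else "-"
  cat("<composition>\n",
      " hosts:    ", fmt(x$host_totals), "\n",
      " dyes:     ", fmt(x$dye_totals), "\n",
      " analytes: ", fmt(x$analyte_totals), "\n",
      " condition:", x$condition, "\n", sep = "")
  invisible(x)
}

# guests of a composition in stable order: dyes first, then analytes
guest_totals <- function(comp) {
  c(comp$dye_totals, comp$analyte_totals)
}
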