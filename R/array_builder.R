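#' One sensor unit: a reporter pair under one condition
#'
#' The atomic sensing element: a set of host site populations (e.g. the
#' calixarene and cyclodextrin populations of a coassembly) with total
#' concentrations, exactly one reporter dye with its total, and an
#' environmental condition label. Provenance records which construction
#' strategy generated the unit.
#'
#' @param id Unit id (unique within an array).
#' @param host_totals Named numeric vector of host totals (M, > 0).
#' @param dye Dye species id.
#' @param dye_total Dye total (M, > 0).
#' @param condition Condition label.
#' @param provenance List with at least `strategy`.
#' @return Object of class `sensor_unit`.
#' @export
sensor_unit <- function(id, host_totals, dye, dye_total,
                        condition = "default",
                        provenance = list(strategy = "manual")) {
  if (is.null(names(host_totals)) || any(!nzchar(names(host_totals)))) {
    stop("host_totals must be named", call. = FALSE)
  }
  if (any(host_totals <= 0)) stop("listed host totals must be > 0", call. = FALSE)
  if (length(dye) != 1L) stop("exactly one dye per unit", call. = FALSE)
  if (dye_total <= 0) stop("dye total must be > 0", call. = FALSE)
  structure(
    list(id = id, host_totals = host_totals, dye = dye, dye_total = dye_total,
         condition = condition, provenance = provenance),
    class = "sensor_unit"
  )
}

# chemistry key used for deduplication: sorted host totals, dye + total,
# condition; totals compared at 1e-12 relative tolerance via signif(., 12)
unit_chem_key <- function(unit) {
  ht <- unit$host_totals[order(names(unit$host_totals))]
  paste(
    paste(names(ht), signif(ht, 12), sep = "=", collapse = ";"),
    paste(unit$dye, signif(unit$dye_total, 12), sep = "="),
    unit$condition,
    sep = "|"
  )
}

#' An ordered collection of sensor units
#'
#' @param id Array id.
#' @param units List of [sensor_unit()] objects with unique ids.
#' @param affinities Optional shared [affinity_table()].
#' @param photophysics Optional shared [photophysics_registry()].
#' @return Object of class `sensor_array`.
#' @export
sensor_array <- function(id, units, affinities = NULL, photophysics = NULL) {
  ok <- vapply(units, inherits, logical(1), "sensor_unit")
  if (!all(ok)) stop("units must all be sensor_unit objects", call. = FALSE)
  ids <- vapply(units, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("unit ids must be unique", call. = FALSE)
  if (!is.null(affinities)) stopifnot(inherits(affinities, "affinity_table"))
  structure(
    list(id = id, units = stats::setNames(units, ids),
         affinities = affinities, photophysics = photophysics),
    class = "sensor_array"
  )
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %s: %d unit(s)\n", x$id, length(x$units)))
  for (u in x$units) {
    cat(sprintf("  %-12s hosts{%s} dye %s=%.3g M cond=%s [%s]\n",
                u$id,
                paste(sprintf("%s=%.3g", names(u$host_totals), u$host_totals),
                      collapse = ","),
                u$dye, u$dye_total, u$condition,
                u$provenance$strategy %||% "manual"))
  }
  invisible(x)
}

#' @export
length.sensor_array <- function(x) length(x$units)

`%||%` <- function(a, b) if (is.null(a)) b else a

new_strategy_array <- function(id, units, strategy, affinities, photophysics,
                               check_duplicates = TRUE) {
  if (check_duplicates) {
    keys <- vapply(units, unit_chem_key, character(1))
    if (anyDuplicated(keys)) {
      stop("duplicate unit definitions in ", strategy, " array", call. = FALSE)
    }
  }
  sensor_array(id, units, affinities, photophysics)
}

#' Strategy A: array from different reporter pairs
#'
#' One unit per (host set, dye) reporter pair; both receptor and dye change
#' across units. A single-pair array is allowed but flagged with a warning
#' as non-discriminating.
#'
#' @param pairs List of `list(hosts = ..., dye = ...)`; `hosts` is either a
#'   character vector (each host dosed at `host_total`) or a named numeric
#'   vector of explicit totals (M).
#' @param host_total Default per-host total (M), 1.0 uM as in typical runs.
#' @param dye_total Dye total per unit (M).
#' @param condition Condition label.
#' @param affinities,photophysics Optional shared registries.
#' @param id Array id.
#' @return A [sensor_array()].
#' @export
build_reporter_pair_array <- function(pairs, host_total = 1e-6, dye_total = 1e-6,
                                      condition = "default",
                                      affinities = NULL, photophysics = NULL,
                                      id = "reporter_pair") {
  if (length(pairs) < 1) stop("at least one reporter pair required", call. = FALSE)
  if (length(pairs) < 2) {
    warning("single-pair array constructed; it cannot discriminate on its own",
            call. = FALSE)
  }
  units <- lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    hosts <- p$hosts
    ht <- if (is.numeric(hosts)) hosts else stats::setNames(rep(host_total, length(hosts)), hosts)
    sensor_unit(sprintf("U%02d_%s", k, p$dye), ht, p$dye, dye_total, condition,
                provenance = list(strategy = "reporter_pair", pair = k))
  })
  new_strategy_array(id, units, "reporter_pair", affinities, photophysics)
}

#' Strategy B: array from dye replacement
#'
#' The host (coassembly) composition is fixed; one unit per dye.
#'
#' @param hosts Character vector of host ids or named numeric totals (M).
#' @param dyes Character vector of dye ids (>= 1; >= 2 for discrimination).
#' @inheritParams build_reporter_pair_array
#' @return A [sensor_array()].
#' @export
build_dye_replacement_array <- function(hosts, dyes, host_total = 1e-6,
                                        dye_total = 1e-6, condition = "default",
                                        affinities = NULL, photophysics = NULL,
                                        id = "dye_replacement") {
  if (length(dyes) < 1) stop("at least one dye required", call. = FALSE)
  ht <- if (is.numeric(hosts)) hosts else stats::setNames(rep(host_total, length(hosts)), hosts)
  units <- lapply(seq_along(dyes), function(k) {
    sensor_unit(sprintf("U%02d_%s", k, dyes[k]), ht, dyes[k], dye_total, condition,
                provenance = list(strategy = "dye_replacement", dye = dyes[k]))
  })
  new_strategy_array(id, units, "dye_replacement", affinities, photophysics)
}

#' Strategy C: array from coassembly-ratio adjustment
#'
#' The total of the second macrocycle (`cd`) is fixed and the first (`ca`)
#' is varied as `ratio * cd_total`; one unit per ratio. The dye dose follows
#' the dosing rule: `"dye-tracks-varied"` sets the dye total equal to the
#' varied component's total (the usual pairing of the dye with the
#' calixarene sites), `"dye-fixed"` keeps it at `dye_total`.
#'
#' @param ca,cd Host ids of the varied and fixed coassembly components.
#' @param ratios Positive numeric vector of ca:cd molar ratios.
#' @param dye Dye id.
#' @param cd_total Fixed component total (M).
#' @param dosing Dye dosing rule.
#' @param dye_total Dye total used under `"dye-fixed"` dosing (M).
#' @inheritParams build_reporter_pair_array
#' @return A [sensor_array()].
#' @export
build_coassembly_ratio_array <- function(ca, cd, ratios, dye, cd_total = 1e-6,
                                         dosing = c("dye-tracks-varied", "dye-fixed"),
                                         dye_total = 1e-6, condition = "default",
                                         affinities = NULL, photophysics = NULL,
                                         id = "coassembly_ratio") {
  dosing <- match.arg(dosing)
  if (length(ratios) < 1) stop("at least one ratio required", call. = FALSE)
  if (any(ratios <= 0)) stop("ratios must be positive", call. = FALSE)
  units <- lapply(seq_along(ratios), function(k) {
    ca_total <- ratios[k] * cd_total
    dt <- if (dosing == "dye-tracks-varied") ca_total else dye_total
    ht <- stats::setNames(c(ca_total, cd_total), c(ca, cd))
    sensor_unit(sprintf("U%02d_r%g", k, ratios[k]), ht, dye, dt, condition,
                provenance = list(strategy = "coassembly_ratio",
                                  ratio = ratios[k], dosing = dosing))
  })
  new_strategy_array(id, units, "coassembly_ratio", affinities, photophysics)
}

#' Strategy D: array from reporter-pair-ratio adjustment
#'
#' The dye total is fixed; every host in the set is dosed at
#' `ratio * dye_total`, one unit per ratio. All units share the same
#' affinities, so any downstream discrimination is attributable to the
#' nonlinearity of the competitive binding isotherm alone.
#'
#' @param hosts Character vector of host ids (each dosed at ratio x dye).
#' @param dye Dye id.
#' @param ratios Positive host:dye molar ratios, e.g. `c(4/5, 1, 6/5, 7/5)`.
#' @param dye_total Fixed dye total (M).
#' @inheritParams build_reporter_pair_array
#' @return A [sensor_array()].
#' @export
build_pair_ratio_array <- function(hosts, dye, ratios, dye_total = 1e-6,
                                   condition = "default",
                                   affinities = NULL, photophysics = NULL,
                                   id = "pair_ratio") {
  if (length(ratios) < 1) stop("at least one ratio required", call. = FALSE)
  if (any(ratios <= 0)) stop("ratios must be positive", call. = FALSE)
  if (dye_total <= 0) stop("dye total must be > 0", call. = FALSE)
  degenerate <- length(unique(ratios)) == 1L && length(ratios) > 1L
  if (degenerate) {
    warning("all reporter ratios equal: degenerate array", call. = FALSE)
  }
  units <- lapply(seq_along(ratios), function(k) {
    ht <- stats::setNames(rep(ratios[k] * dye_total, length(hosts)), hosts)
    sensor_unit(sprintf("U%02d_x%g", k, ratios[k]), ht, dye, dye_total, condition,
                provenance = list(strategy = "pair_ratio", ratio = ratios[k]))
  })
  new_strategy_array(id, units, "pair_ratio", affinities, photophysics,
                     check_duplicates = !degenerate)
}

#' Strategy E: array from environmental-condition change
#'
#' A single reporter pair at fixed totals, replicated across environmental
#' conditions (e.g. pH values); the affinity table must index every
#' condition.
#'
#' @param hosts Character vector of host ids or named totals (M).
#' @param dye Dye id.
#' @param conditions Character vector of condition labels.
#' @param affinities [affinity_table()] indexing every condition (required).
#' @inheritParams build_reporter_pair_array
#' @return A [sensor_array()].
#' @export
build_condition_array <- function(hosts, dye, conditions, affinities,
                                  host_total = 1e-6, dye_total = 1e-6,
                                  photophysics = NULL, id = "condition") {
  stopifnot(inherits(affinities, "affinity_table"))
  if (length(conditions) < 1) stop("at least one condition required", call. = FALSE)
  missing_cond <- setdiff(conditions, affinities$conditions)
  if (length(missing_cond)) {
    stop("condition(s) missing from affinity table: ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  ht <- if (is.numeric(hosts)) hosts else stats::setNames(rep(host_total, length(hosts)), hosts)
  units <- lapply(seq_along(conditions), function(k) {
    sensor_unit(sprintf("U%02d_%s", k, conditions[k]), ht, dye, dye_total,
                conditions[k],
                provenance = list(strategy = "condition", condition = conditions[k]))
  })
  new_strategy_array(id, units, "condition", affinities, photophysics)
}

#' Sensor-unit library combinatorics
#'
#' Counts the sensor units obtainable from coassembled receptors and dyes:
#' `n_coassembly_ratios` coassembly variants x `n_dyes` dye choices gives
#' the intermediate unit count, and `n_pair_ratios` reporter-pair ratios per
#' unit expands it to the full library. With 2 receptors, 2 dyes, 5
#' coassembly ratios and 5 pair ratios this yields the 50-unit library (10
#' intermediate units).
#'
#' @param n_receptors Number of receptors forming the coassemblies (>= 1;
#'   informational - the coassembly variants are counted by
#'   `n_coassembly_ratios`).
#' @param n_dyes,n_coassembly_ratios,n_pair_ratios Positive counts.
#' @return List with `total` and `intermediate` unit counts.
#' @examples
#' enumerate_units(2, 2, 5, 5)  # $total 50, $intermediate 10
#' @export
enumerate_units <- function(n_receptors, n_dyes, n_coassembly_ratios, n_pair_ratios) {
  counts <- c(n_receptors, n_dyes, n_coassembly_ratios, n_pair_ratios)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all counts must be integers >= 1", call. = FALSE)
  }
  intermediate <- n_coassembly_ratios * n_dyes
  list(total = intermediate * n_pair_ratios, intermediate = intermediate)
}

#' Materialize the full cross-product unit library
#'
#' Generates the concrete sensor units counted by [enumerate_units()]:
#' every coassembly ratio x dye x reporter-pair ratio, using the same
#' dosing conventions as the strategy builders (fixed `cd_total`,
#' `ca = ratio * cd`, hosts dosed at `pair_ratio * dye_total`).
#'
#' @param ca,cd Host ids of the two coassembling receptors.
#' @param dyes Character vector of dye ids.
#' @param coassembly_ratios,pair_ratios Positive numeric vectors.
#' @param cd_total,dye_total Base totals (M).
#' @param condition Condition label.
#' @return A [sensor_array()] holding the full library.
#' @export
materialize_unit_library <- function(ca, cd, dyes, coassembly_ratios, pair_ratios,
                                     cd_total = 1e-6, dye_total = 1e-6,
                                     condition = "default") {
  units <- list()
  k <- 0L
  for (r in coassembly_ratios) for (d in dyes) for (p in pair_ratios) {
    k <- k + 1L
    ht <- stats::setNames(c(r * cd_total, cd_total) * p, c(ca, cd))
    units[[k]] <- sensor_unit(
      sprintf("L%03d_%s_r%g_p%g", k, d, r, p), ht, d, dye_total, condition,
      provenance = list(strategy = "library", coassembly_ratio = r,
                        pair_ratio = p))
  }
  sensor_array("unit_library", units)
}

#' Combine two sensor arrays
#'
#' Concatenates the unit lists (a's units first, order stable) and removes
#' units of `b` whose chemistry duplicates a unit of `a`. Shared affinity
#' tables are merged; the same (host, guest, condition) entry with
#' conflicting Ka values is an error, as are conflicting photophysics for
#' the same dye.
#'
#' @param a,b [sensor_array()] objects.
#' @param id Id of the combined array; default `"a+b"`.
#' @return A [sensor_array()].
#' @export
combine_arrays <- function(a, b, id = paste(a$id, b$id, sep = "+")) {
  stopifnot(inherits(a, "sensor_array"), inherits(b, "sensor_array"))
  affinities <- merge_affinities(a$affinities, b$affinities)
  photo <- merge_photophysics(a$photophysics, b$photophysics)
  units <- unname(a$units)
  keys <- vapply(units, unit_chem_key, character(1))
  for (u in unname(b$units)) {
    k <- unit_chem_key(u)
    if (k %in% keys) next
    if (u$id %in% vapply(units, `[[`, character(1), "id")) {
      u$id <- paste(b$id, u$id, sep = ".")
    }
    units <- c(units, list(u))
    keys <- c(keys, k)
  }
  sensor_array(id, units, affinities, photo)
}

merge_affinities <- function(x, y) {
  if (is.null(x)) return(y)
  if (is.null(y)) return(x)
  ex <- x$entries
  ey <- y$entries
  kx <- paste(ex$host, ex$guest, ex$condition, sep = "\r")
  ky <- paste(ey$host, ey$guest, ey$condition, sep = "\r")
  shared <- intersect(kx, ky)
  if (length(shared)) {
    vx <- ex$Ka_per_M[match(shared, kx)]
    vy <- ey$Ka_per_M[match(shared, ky)]
    bad <- abs(vx - vy) > 1e-12 * pmax(vx, vy, 1)
    if (any(bad)) {
      stop("conflicting Ka definitions for: ",
           paste(gsub("\r", "/", shared[bad]), collapse = "; "), call. = FALSE)
    }
  }
  affinity_table(rbind(ex, ey[!ky %in% kx, , drop = FALSE]))
}

merge_photophysics <- function(x, y) {
  if (is.null(x)) return(y)
  if (is.null(y)) return(x)
  out <- x
  for (nm in names(y)) {
    if (nm %in% names(out)) {
      px <- out[[nm]]; py <- y[[nm]]
      if (px$phi_free != py$phi_free || px$phi_bound != py$phi_bound ||
          px$phi_da != py$phi_da) {
        stop("conflicting photophysics for dye '", nm, "'", call. = FALSE)
      }
    } else {
      out[[nm]] <- y[[nm]]
    }
  }
  out
}
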