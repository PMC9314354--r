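#' Read and write affinity tables as tidy CSV
#'
#' Columns: `host`, `guest`, `condition`, `Ka_per_M`. Values round-trip at
#' 15 significant digits.
#'
#' @param affinities An [affinity_table()].
#' @param path CSV file path.
#' @return `write_affinity_table` returns the path invisibly;
#'   `read_affinity_table` returns an [affinity_table()].
#' @export
write_affinity_table <- function(affinities, path) {
  stopifnot(inherits(affinities, "affinity_table"))
  e <- affinities$entries
  e$Ka_per_M <- sprintf("%.15g", e$Ka_per_M)
  utils::write.csv(e, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_affinity_table
#' @export
read_affinity_table <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot read affinity table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  required <- c("host", "guest", "Ka_per_M")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("affinity file '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$Ka_per_M))))
  if (length(bad)) {
    stop("affinity file '", path, "': non-numeric Ka in data row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df$Ka_per_M <- as.numeric(df$Ka_per_M)
  affinity_table(df)
}

#' Read and write response matrices as CSV
#'
#' Header row of unit ids plus a leading `class` column; values round-trip
#' at 15 significant digits. The seed and noise CV travel in comment
#' metadata lines (`# key: value`) at the top of the file.
#'
#' @param x A `response_matrix`.
#' @param path CSV file path.
#' @return `write_response_matrix` returns the path invisibly;
#'   `read_response_matrix` returns a `response_matrix`.
#' @export
write_response_matrix <- function(x, path) {
  stopifnot(is.data.frame(x), "class" %in% names(x))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(seed = attr(x, "seed"), noise_cv = attr(x, "noise_cv"))
  for (nm in names(meta)) {
    if (!is.null(meta[[nm]])) writeLines(sprintf("# %s: %.15g", nm, meta[[nm]]), con)
  }
  out <- x
  for (nm in setdiff(names(out), "class")) {
    out[[nm]] <- sprintf("%.15g", out[[nm]])
  }
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_response_matrix
#' @export
read_response_matrix <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (l in lines[meta_lines]) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.+)$", l))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- as.numeric(m[3])
  }
  df <- utils::read.csv(text = paste(if (length(meta_lines)) lines[-meta_lines] else lines,
                                     collapse = "\n"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  if (!"class" %in% names(df)) {
    stop("response matrix '", path, "' lacks a 'class' column", call. = FALSE)
  }
  value_cols <- setdiff(names(df), "class")
  for (nm in value_cols) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (any(is.na(v))) {
      stop("response matrix '", path, "': non-numeric value in column '", nm,
           "', data row(s) ", paste(which(is.na(v)), collapse = ", "),
           call. = FALSE)
    }
    df[[nm]] <- v
  }
  structure(df, seed = meta$seed, noise_cv = meta$noise_cv,
            class = c("response_matrix", "data.frame"))
}

#' Round-trip sensor arrays through YAML
#'
#' The array definition (units with host totals, dye, condition,
#' provenance) is written as human-readable YAML; affinities and
#' photophysics travel separately.
#'
#' @param array A [sensor_array()].
#' @param path YAML file path.
#' @return `write_sensor_array` returns the path invisibly;
#'   `read_sensor_array` a [sensor_array()] (without registries).
#' @export
write_sensor_array <- function(array, path) {
  stopifnot(inherits(array, "sensor_array"))
  obj <- list(
    id = array$id,
    units = lapply(unname(array$units), function(u) {
      list(id = u$id,
           hosts = as.list(u$host_totals),
           dye = u$dye, dye_total = u$dye_total,
           condition = u$condition,
           provenance = u$provenance)
    })
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_sensor_array
#' @export
read_sensor_array <- function(path) {
  obj <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse array file '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  if (is.null(obj$id) || is.null(obj$units)) {
    stop("array file '", path, "' lacks id/units", call. = FALSE)
  }
  units <- lapply(obj$units, function(u) {
    sensor_unit(u$id, unlist(u$hosts), u$dye, u$dye_total,
                u$condition %||% "default",
                provenance = u$provenance %||% list(strategy = "manual"))
  })
  sensor_array(obj$id, units)
}

#' Write a run manifest
#'
#' Records everything needed to regenerate an output directory: seed, noise
#' CV, package version, and the md5 of every written artifact.
#'
#' @param dir Output directory.
#' @param seed,noise_cv Run parameters (may be NULL).
#' @param files Character vector of artifact paths already written.
#' @param extra Named list of additional fields.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(dir, seed = NULL, noise_cv = NULL,
                           files = character(0), extra = list()) {
  manifest <- c(list(
    package = "sensarray",
    version = as.character(utils::packageVersion("sensarray")),
    seed = seed, noise_cv = noise_cv,
    artifacts = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  ), extra)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path, precision = 15)
  invisible(path)
}
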