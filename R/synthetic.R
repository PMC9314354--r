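#' Specification of a synthetic sensing scenario
#'
#' Defines the statistical structure of a simulated affinity panel and
#' response experiment: species counts, the log-uniform sampling law for
#' association constants, dye photophysics assignment, replicate count and
#' the multiplicative noise model. The seed is recorded in every generated
#' artifact.
#'
#' @param n_hosts,n_dyes,n_analytes Species counts (>= 1).
#' @param ka_bounds Two increasing positive bounds (M^-1) for log-uniform Ka
#'   sampling; default `c(1e4, 1e9)`, a typical calixarene/cyclodextrin
#'   host-guest span.
#' @param conditions Character vector of condition labels (default one).
#' @param replicates Replicates per analyte (>= 2), default 6.
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   replicate noise on I/I0; default 0.02.
#' @param dye_mode `"quench"`, `"enhance"`, or `"mixed"` (alternating).
#' @param seed Integer seed recorded in all outputs.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_hosts = 2, n_dyes = 2, n_analytes = 3,
                          ka_bounds = c(1e4, 1e9), conditions = "default",
                          replicates = 6, noise_cv = 0.02,
                          dye_mode = c("quench", "enhance", "mixed"),
                          seed = 1L) {
  dye_mode <- match.arg(dye_mode)
  if (length(ka_bounds) != 2 || any(ka_bounds <= 0) || diff(ka_bounds) <= 0) {
    stop("ka_bounds must be two increasing positive values", call. = FALSE)
  }
  if (replicates < 2) stop("replicates must be >= 2", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  stopifnot(n_hosts >= 1, n_dyes >= 1, n_analytes >= 1)
  structure(
    list(n_hosts = n_hosts, n_dyes = n_dyes, n_analytes = n_analytes,
         ka_bounds = ka_bounds, conditions = conditions,
         replicates = as.integer(replicates), noise_cv = noise_cv,
         dye_mode = dye_mode, seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

spec_hash <- function(spec) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(unclass(spec), file = f)
  unname(tools::md5sum(f))
}

scenario_species <- function(spec) {
  list(hosts = sprintf("H%d", seq_len(spec$n_hosts)),
       dyes = sprintf("D%d", seq_len(spec$n_dyes)),
       analytes = sprintf("A%d", seq_len(spec$n_analytes)))
}

#' Draw a random affinity panel
#'
#' Samples one association constant per (host, guest, condition) triple,
#' log-uniformly between the bounds of the scenario; condition-indexed
#' copies are drawn independently. Reproducible under the recorded seed.
#'
#' @param spec A [scenario_spec()].
#' @return An [affinity_table()] with attributes `seed` and `spec_hash`.
#' @export
sample_affinity_panel <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  sp <- scenario_species(spec)
  guests <- c(sp$dyes, sp$analytes)
  grid <- expand.grid(host = sp$hosts, guest = guests,
                      condition = spec$conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lo <- log10(spec$ka_bounds[1]); hi <- log10(spec$ka_bounds[2])
  grid$Ka_per_M <- with_seed(spec$seed, 10^stats::runif(nrow(grid), lo, hi))
  out <- affinity_table(grid)
  attr(out, "seed") <- spec$seed
  attr(out, "spec_hash") <- spec_hash(spec)
  out
}

# evaluate code under a fixed seed, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Default photophysics for a scenario
#'
#' Quench-type dyes get `phi_bound = 0` (near-complete complexation-induced
#' quenching); enhancement-type dyes get `phi_bound = 10 * phi_free`. Under
#' `dye_mode = "mixed"` modes alternate across the dye list.
#'
#' @param spec A [scenario_spec()].
#' @return A [photophysics_registry()].
#' @export
scenario_photophysics <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  sp <- scenario_species(spec)
  ph <- lapply(seq_along(sp$dyes), function(k) {
    mode <- switch(spec$dye_mode,
                   quench = "quench", enhance = "enhance",
                   mixed = if (k %% 2L == 1L) "quench" else "enhance")
    if (mode == "quench") dye_photophysics(sp$dyes[k], phi_free = 1, phi_bound = 0)
    else dye_photophysics(sp$dyes[k], phi_free = 1, phi_bound = 10)
  })
  photophysics_registry(ph)
}

#' Analyte panel container
#'
#' A panel is a data.frame with a `class` column and one numeric column per
#' analyte id holding its total concentration (M) in that sample class.
#' Single-analyte panels are built from a named dose vector.
#'
#' @param doses Either a named numeric vector (one class per analyte, dosed
#'   at the given molar concentration) or a data.frame with a `class`
#'   column plus analyte columns.
#' @return A validated panel data.frame.
#' @export
analyte_panel <- function(doses) {
  if (is.numeric(doses) && !is.null(names(doses))) {
    panel <- as.data.frame(diag(doses, nrow = length(doses)))
    names(panel) <- names(doses)
    panel <- cbind(data.frame(class = names(doses), stringsAsFactors = FALSE), panel)
  } else if (is.data.frame(doses)) {
    panel <- doses
  } else {
    stop("doses must be a named numeric vector or a data.frame", call. = FALSE)
  }
  if (!"class" %in% names(panel)) stop("panel needs a 'class' column", call. = FALSE)
  num <- panel[setdiff(names(panel), "class")]
  if (!all(vapply(num, is.numeric, logical(1))) || any(unlist(num) < 0)) {
    stop("analyte doses must be nonnegative numbers", call. = FALSE)
  }
  if (anyDuplicated(panel$class)) stop("class labels must be unique", call. = FALSE)
  panel
}

#' Simulate a replicate response matrix for an array
#'
#' Computes the noiseless I/I0 fingerprint of every panel class on every
#' sensor unit via [response_ratio()], then perturbs each replicate with
#' multiplicative Gaussian noise `I/I0 * (1 + cv * z)`, `z ~ N(0, 1)`,
#' clipped to stay positive - emulating values randomly assigned around the
#' calculated response. Deterministic under the seed.
#'
#' @param array A [sensor_array()].
#' @param panel An [analyte_panel()] (or named dose vector).
#' @param affinities [affinity_table()]; defaults to the array's own.
#' @param photo Photophysics registry; defaults to the array's own.
#' @param replicates Replicates per class (>= 1).
#' @param noise_cv Coefficient of variation of the replicate noise.
#' @param seed Integer seed.
#' @param tol Solver tolerance.
#' @return A `response_matrix`: data.frame with `class` plus one column per
#'   unit id; attributes `noiseless` (class x unit matrix), `seed`,
#'   `noise_cv`.
#' @export
simulate_responses <- function(array, panel, affinities = NULL, photo = NULL,
                               replicates = 6, noise_cv = 0.02, seed = 1L,
                               tol = 1e-10) {
  stopifnot(inherits(array, "sensor_array"))
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  affinities <- affinities %||% array$affinities
  photo <- photo %||% array$photophysics
  if (is.null(affinities)) stop("no affinity table available", call. = FALSE)
  if (is.null(photo)) stop("no photophysics available", call. = FALSE)
  panel <- analyte_panel(panel)
  analyte_ids <- setdiff(names(panel), "class")
  unit_ids <- names(array$units)

  noiseless <- matrix(NA_real_, nrow = nrow(panel), ncol = length(unit_ids),
                      dimnames = list(panel$class, unit_ids))
  for (i in seq_len(nrow(panel))) {
    doses <- unlist(panel[i, analyte_ids, drop = FALSE])
    doses <- doses[doses > 0]
    for (u in unit_ids) {
      noiseless[i, u] <- tryCatch(
        response_ratio(array$units[[u]], doses, affinities, photo, tol = tol),
        error = function(e) stop("response simulation failed for unit '", u,
                                 "', class '", panel$class[i], "': ",
                                 conditionMessage(e), call. = FALSE))
    }
  }

  rows <- noiseless[rep(seq_len(nrow(panel)), each = replicates), , drop = FALSE]
  values <- with_seed(seed, {
    z <- matrix(stats::rnorm(length(rows)), nrow = nrow(rows))
    pmax(rows * (1 + noise_cv * z), .Machine$double.eps)
  })

  out <- data.frame(class = rep(panel$class, each = replicates),
                    stringsAsFactors = FALSE)
  rownames(values) <- NULL
  out <- cbind(out, as.data.frame(values))
  names(out) <- c("class", unit_ids)
  rownames(out) <- NULL
  structure(out, noiseless = noiseless, seed = as.integer(seed),
            noise_cv = noise_cv, spec_hash = NULL,
            class = c("response_matrix", "data.frame"))
}

#' Extract the numeric response block of a response matrix
#'
#' @param x A `response_matrix`.
#' @return Numeric matrix (samples x units).
#' @export
response_values <- function(x) {
  stopifnot(is.data.frame(x), "class" %in% names(x))
  as.matrix(x[setdiff(names(x), "class")])
}

#' Construct the concentration/affinity ambiguity scenario
#'
#' A single indicator-displacement unit cannot distinguish a low dose of a
#' high-affinity analyte from a high dose of a low-affinity one. This
#' constructor tunes (by 1-D root finding) the dose of the low-affinity
#' analyte B so that its I/I0 on the array's first unit equals that of the
#' high-affinity analyte A, while the two analytes still differ on at least
#' one other unit - so the full array resolves what any single unit cannot.
#'
#' @param array A [sensor_array()] with >= 2 units of distinct affinity
#'   fingerprints.
#' @param affinities,photo Defaults to the array's own registries.
#' @param analyte_high,analyte_low Ids of the high-affinity and low-affinity
#'   analytes (must be in the affinity table).
#' @param dose_high Dose of the high-affinity analyte (M).
#' @param dose_bounds Search interval for the low-affinity dose (M).
#' @param match_tol Required |I/I0(A) - I/I0(B)| on the matched unit.
#' @param min_separation Minimum required response difference on some other
#'   unit.
#' @return List with `array`, `panel` (2-class [analyte_panel()]),
#'   `matched_unit`, `doses`, `separation`.
#' @export
make_ambiguity_scenario <- function(array, affinities = NULL, photo = NULL,
                                    analyte_high = "A1", analyte_low = "A2",
                                    dose_high = 5e-7,
                                    dose_bounds = c(1e-9, 1e-2),
                                    match_tol = 1e-6, min_separation = 1e-3) {
  stopifnot(inherits(array, "sensor_array"))
  if (length(array$units) < 2) {
    stop("ambiguity scenario needs an array with >= 2 units", call. = FALSE)
  }
  affinities <- affinities %||% array$affinities
  photo <- photo %||% array$photophysics
  u1 <- array$units[[1L]]
  rA <- response_ratio(u1, stats::setNames(dose_high, analyte_high), affinities, photo)
  f <- function(dose) {
    response_ratio(u1, stats::setNames(dose, analyte_low), affinities, photo) - rA
  }
  flo <- f(dose_bounds[1]); fhi <- f(dose_bounds[2])
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    stop("ambiguity tuning failed: no dose of '", analyte_low,
         "' crosses the target response on unit 1", call. = FALSE)
  }
  root <- stats::uniroot(f, dose_bounds, tol = 1e-18)
  dose_low <- root$root
  rB <- response_ratio(u1, stats::setNames(dose_low, analyte_low), affinities, photo)
  if (abs(rA - rB) > match_tol) {
    stop(sprintf("ambiguity tuning did not reach match tolerance (|dr| = %.2e)",
                 abs(rA - rB)), call. = FALSE)
  }
  others <- vapply(array$units[-1L], function(u) {
    abs(response_ratio(u, stats::setNames(dose_high, analyte_high), affinities, photo) -
          response_ratio(u, stats::setNames(dose_low, analyte_low), affinities, photo))
  }, numeric(1))
  if (max(others) < min_separation) {
    stop("ambiguity scenario degenerate: analytes indistinguishable on every unit",
         call. = FALSE)
  }
  doses <- data.frame(class = c("high_affinity_low_dose", "low_affinity_high_dose"),
                      stringsAsFactors = FALSE)
  doses[[analyte_high]] <- c(dose_high, 0)
  doses[[analyte_low]] <- c(0, dose_low)
  list(array = array, panel = analyte_panel(doses), matched_unit = u1$id,
       doses = stats::setNames(c(dose_high, dose_low), c(analyte_high, analyte_low)),
       separation = max(others))
}

#' Two-component mixture panel
#'
#' Mixtures of two analytes at the given fractions of a fixed total dose;
#' the endpoints 0 and 1 reproduce the pure components. Emulates
#' adulteration-style panels (e.g. protein or honey/sirup blends at 0, 20,
#' 40, 60, 80, 100 percent).
#'
#' @param analyte_a,analyte_b Analyte ids; the fraction applies to
#'   `analyte_a`.
#' @param fractions Numeric vector in \[0, 1\]; one class per fraction.
#' @param total_dose Total analyte concentration of each mixture (M).
#' @return An [analyte_panel()] with classes named `mix_<percent>`.
#' @export
make_mixture_scenario <- function(analyte_a, analyte_b, fractions, total_dose) {
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (total_dose <= 0) stop("total_dose must be > 0", call. = FALSE)
  panel <- data.frame(class = sprintf("mix_%g", round(100 * fractions, 6)),
                      stringsAsFactors = FALSE)
  panel[[analyte_a]] <- fractions * total_dose
  panel[[analyte_b]] <- (1 - fractions) * total_dose
  analyte_panel(panel)
}

#' Convert a mass-per-volume dose to molar
#'
#' Protein analytes are commonly dosed in ug/mL; the solver works in molar
#' units throughout, so conversion happens upstream via a molecular weight.
#'
#' @param ug_per_ml Dose in micrograms per millilitre.
#' @param mw_da Molecular weight in Daltons (g/mol).
#' @return Concentration in mol/L.
#' @examples
#' ug_per_ml_to_molar(23.8, 66430)  # BSA-sized protein at 23.8 ug/mL
#' @export
ug_per_ml_to_molar <- function(ug_per_ml, mw_da) {
  if (any(mw_da <= 0)) stop("molecular weight must be > 0", call. = FALSE)
  ug_per_ml * 1e-3 / mw_da
}
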