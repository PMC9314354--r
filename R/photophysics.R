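#' Photophysical parameters of a reporter dye
#'
#' The fluorescence model is linear in concentration: total intensity is
#' `phi_free * [D]_free + phi_bound * sum_j [H_j D]` (intensity units per
#' molar). The mode label is derived: `quench` when binding dims the dye
#' (`phi_bound < phi_free`), `enhance` otherwise. Complexation-induced
#' quenching of the dyes used here is typically near-complete, so the
#' default is `phi_bound = 0`; an enhancement dye is obtained by passing
#' e.g. `phi_bound = 10 * phi_free`.
#'
#' @param dye Dye species id.
#' @param phi_free Emission coefficient of the free dye (> 0), arbitrary
#'   intensity units per M.
#' @param phi_bound Emission coefficient of the host-bound dye (>= 0).
#' @param phi_da Emission coefficient of an optional dye-analyte complex
#'   (used only when the direct dye-analyte interaction term is switched on
#'   in [intensity()]); default 0.
#' @return An object of class `dye_photophysics` with a derived `mode`.
#' @examples
#' dye_photophysics("AlPcS4")                    # quench-type
#' dye_photophysics("ANS", phi_bound = 10)       # enhancement-type
#' @export
dye_photophysics <- function(dye, phi_free = 1, phi_bound = 0, phi_da = 0) {
  if (!is.numeric(phi_free) || phi_free <= 0) stop("phi_free must be > 0", call. = FALSE)
  if (!is.numeric(phi_bound) || phi_bound < 0) stop("phi_bound must be >= 0", call. = FALSE)
  if (!is.numeric(phi_da) || phi_da < 0) stop("phi_da must be >= 0", call. = FALSE)
  structure(
    list(dye = dye, phi_free = phi_free, phi_bound = phi_bound, phi_da = phi_da,
         mode = if (phi_bound < phi_free) "quench" else "enhance"),
    class = "dye_photophysics"
  )
}

#' @export
print.dye_photophysics <- function(x, ...) {
  cat(sprintf("<dye_photophysics> %s: phi_free=%.3g phi_bound=%.3g (%s)\n",
              x$dye, x$phi_free, x$phi_bound, x$mode))
  invisible(x)
}

#' Bundle photophysics for several dyes
#'
#' @param ... `dye_photophysics` objects.
#' @return Named list keyed by dye id.
#' @export
photophysics_registry <- function(...) {
  ph <- list(...)
  if (length(ph) == 1L && is.list(ph[[1L]]) && !inherits(ph[[1L]], "dye_photophysics")) {
    ph <- ph[[1L]]
  }
  ok <- vapply(ph, inherits, logical(1), "dye_photophysics")
  if (!all(ok)) stop("all elements must be dye_photophysics objects", call. = FALSE)
  stats::setNames(ph, vapply(ph, `[[`, character(1), "dye"))
}

# resolve a registry entry or a bare dye_photophysics for one dye
resolve_photo <- function(photo, dye) {
  if (inherits(photo, "dye_photophysics")) {
    if (photo$dye != dye) stop("photophysics given for dye '", photo$dye,
                               "', not '", dye, "'", call. = FALSE)
    return(photo)
  }
  p <- photo[[dye]]
  if (is.null(p)) stop("no photophysics registered for dye '", dye, "'", call. = FALSE)
  p
}

#' Fluorescence intensity of one dye at equilibrium
#'
#' `phi_free * [D]_free + phi_bound * sum_j [H_j D]`, assuming the dye stays
#' in the linear range of intensity versus concentration. With
#' `dye_analyte = TRUE` an additive first-order term
#' `phi_da * Ka(dye, analyte) * [D]_free * [A]_free` is included for every
#' analyte whose direct interaction with the dye is tabulated (the pair is
#' stored in the affinity table with the dye in the host column); this
#' perturbative term is off by default.
#'
#' @param state An `equilibrium_state`.
#' @param photo A `dye_photophysics` or a [photophysics_registry()].
#' @param dye Dye species id present in `state`.
#' @param affinities Affinity table; only needed when `dye_analyte = TRUE`.
#' @param dye_analyte Include the direct dye-analyte emission term?
#' @param analytes Analyte ids to consider for the dye-analyte term;
#'   defaults to every species in `state` that is neither the dye nor a host.
#' @return Intensity in arbitrary units (>= 0).
#' @export
intensity <- function(state, photo, dye, affinities = NULL,
                      dye_analyte = FALSE, analytes = NULL) {
  if (!dye %in% names(state$free) || !dye %in% rownames(state$complexes)) {
    stop("unknown dye id '", dye, "'", call. = FALSE)
  }
  p <- resolve_photo(photo, dye)
  val <- p$phi_free * state$free[[dye]] +
    p$phi_bound * sum(state$complexes[dye, ])
  if (isTRUE(dye_analyte)) {
    if (is.null(affinities)) {
      stop("dye_analyte term requires the affinity table", call. = FALSE)
    }
    if (is.null(analytes)) {
      analytes <- setdiff(names(state$free),
                          c(dye, colnames(state$complexes)))
    }
    for (a in analytes) {
      kda <- ka_lookup(affinities, dye, a, state$condition)
      if (kda > 0) {
        val <- val + p$phi_da * kda * state$free[[dye]] * state$free[[a]]
      }
    }
  }
  unname(val)
}

#' Fluorescence response ratio I/I0 of a sensor unit
#'
#' Solves the unit without analyte (baseline intensity I0) and with the
#' analyte dose added (intensity I) and returns I/I0 - the signal of
#' indicator-displacement sensing. The ratio is 1 when the analyte binds
#' nothing, > 1 when a quench-type dye is displaced, < 1 when an
#' enhancement-type dye is displaced.
#'
#' @param unit A [sensor_unit()] (hosts + one dye + condition).
#' @param analyte_totals Named numeric vector of analyte doses (M); may be
#'   empty.
#' @param affinities An [affinity_table()].
#' @param photo Photophysics for the unit's dye (single object or registry).
#' @param tol,max_iter Passed to [solve_equilibrium()].
#' @param dye_analyte Include the direct dye-analyte emission term.
#' @return I/I0, dimensionless.
#' @export
response_ratio <- function(unit, analyte_totals, affinities, photo,
                           tol = 1e-10, max_iter = 10000L, dye_analyte = FALSE) {
  stopifnot(inherits(unit, "sensor_unit"))
  comp0 <- composition(unit$host_totals,
                       stats::setNames(unit$dye_total, unit$dye),
                       numeric(0), unit$condition)
  st0 <- solve_equilibrium(comp0, affinities, tol = tol, max_iter = max_iter)
  I0 <- intensity(st0, photo, unit$dye, affinities, dye_analyte)
  if (I0 <= 0) {
    stop("degenerate baseline: I0 = 0 for unit '", unit$id,
         "' (dye fully dark); response ratio undefined", call. = FALSE)
  }
  comp1 <- composition(unit$host_totals,
                       stats::setNames(unit$dye_total, unit$dye),
                       analyte_totals, unit$condition)
  st1 <- solve_equilibrium(comp1, affinities, tol = tol, max_iter = max_iter)
  I1 <- intensity(st1, photo, unit$dye, affinities, dye_analyte)
  I1 / I0
}

#' Titration curve container
#'
#' @param conc Strictly increasing titrant total concentrations (M).
#' @param intensity Intensities at each point (same length).
#' @param kind `"direct"` or `"competitive"`.
#' @return Object of class `titration_curve` (a data.frame with attributes).
#' @export
titration_curve <- function(conc, intensity, kind = c("direct", "competitive")) {
  kind <- match.arg(kind)
  if (length(conc) == 0) stop("empty titration ramp", call. = FALSE)
  if (length(conc) != length(intensity)) {
    stop("conc and intensity lengths differ", call. = FALSE)
  }
  if (any(diff(conc) <= 0)) stop("titration abscissa must be strictly increasing",
                                 call. = FALSE)
  structure(data.frame(conc = conc, intensity = intensity),
            kind = kind, class = c("titration_curve", "data.frame"))
}

#' Direct host-into-dye titration
#'
#' Intensity of a fixed dye total titrated with increasing host totals. For
#' a quench-type dye the curve decreases towards the saturation asymptote;
#' its curvature in the tight-binding regime is the nonlinearity exploited
#' by reporter-ratio sensor arrays.
#'
#' @param host_proportions Named numeric vector giving the relative molar
#'   proportions of the host site populations (e.g. `c(CA = 1, CD = 1)`).
#' @param ramp Non-negative, strictly increasing vector of host
#'   concentrations (M); at step k each host total is
#'   `host_proportions / max(host_proportions) * ramp[k]`, so `ramp` is the
#'   total of the most abundant host population.
#' @param dye Dye id.
#' @param dye_total Fixed dye total (M).
#' @param affinities,photo,condition,tol As elsewhere.
#' @return A [titration_curve()] of kind `"direct"`.
#' @export
direct_titration <- function(host_proportions, ramp, dye, dye_total,
                             affinities, photo, condition = "default",
                             tol = 1e-10) {
  if (length(ramp) == 0) stop("empty titration ramp", call. = FALSE)
  if (any(ramp < 0)) stop("ramp must be nonnegative", call. = FALSE)
  if (length(ramp) > 1 && any(diff(ramp) <= 0)) {
    stop("ramp must be strictly increasing", call. = FALSE)
  }
  prop <- host_proportions / max(host_proportions)
  ints <- vapply(ramp, function(htot) {
    hts <- prop * htot
    if (all(hts == 0)) {
      # no host: dye entirely free
      p <- resolve_photo(photo, dye)
      return(p$phi_free * dye_total)
    }
    comp <- composition(hts, stats::setNames(dye_total, dye),
                        numeric(0), condition)
    st <- solve_equilibrium(comp, affinities, tol = tol)
    intensity(st, photo, dye)
  }, numeric(1))
  titration_curve(ramp, ints, "direct")
}

#' Competitive analyte-into-unit titration
#'
#' Intensity of a fixed host + dye reporter pair titrated with increasing
#' analyte dose. Starting the titration from different host:dye ratios
#' (different points on the direct binding isotherm) yields unequal
#' fluorescence changes for the same analyte dose - the working principle of
#' reporter-ratio arrays.
#'
#' @param unit A [sensor_unit()] fixing hosts, dye and condition.
#' @param analyte Analyte species id.
#' @param ramp Non-negative increasing analyte totals (M).
#' @param affinities,photo,tol As elsewhere.
#' @return A [titration_curve()] of kind `"competitive"`.
#' @export
competitive_titration <- function(unit, analyte, ramp, affinities, photo,
                                  tol = 1e-10) {
  stopifnot(inherits(unit, "sensor_unit"))
  if (length(ramp) == 0) stop("empty titration ramp", call. = FALSE)
  if (any(ramp < 0)) stop("ramp must be nonnegative", call. = FALSE)
  if (length(ramp) > 1 && any(diff(ramp) <= 0)) {
    stop("ramp must be strictly increasing", call. = FALSE)
  }
  ints <- vapply(ramp, function(a) {
    comp <- composition(unit$host_totals,
                        stats::setNames(unit$dye_total, unit$dye),
                        stats::setNames(a, analyte), unit$condition)
    st <- solve_equilibrium(comp, affinities, tol = tol)
    intensity(st, photo, unit$dye)
  }, numeric(1))
  p <- resolve_photo(photo, unit$dye)
  comp0 <- composition(unit$host_totals,
                       stats::setNames(unit$dye_total, unit$dye),
                       numeric(0), unit$condition)
  st0 <- solve_equilibrium(comp0, affinities, tol = tol)
  if (intensity(st0, photo, unit$dye) <= 0) {
    stop("degenerate baseline: I0 = 0 for unit '", unit$id, "'", call. = FALSE)
  }
  titration_curve(ramp, ints, "competitive")
}

#' Write a titration curve as two-column text
#'
#' @param curve A [titration_curve()].
#' @param path Output file.
#' @export
write_titration_curve <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  df <- data.frame(conc_M = sprintf("%.15g", curve$conc),
                   intensity = sprintf("%.15g", curve$intensity))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
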