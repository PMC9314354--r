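#' Maximal discriminable analyte subset of a response matrix
#'
#' Finds, by greedy elimination, an analyte subset on which the jackknifed
#' (leave-one-out) classification is perfect: while accuracy is below 100
#' percent, the class involved in the most leave-one-out misclassifications
#' (counting both the true and the predicted class of every error; ties
#' broken by label order) is removed. The elimination trace makes the
#' choice auditable.
#'
#' @param x A `response_matrix` (or matrix + `classes`).
#' @param classes Class labels when `x` is a bare matrix.
#' @param ridge_frac Ridge fraction passed to [fit_lda()].
#' @return Object of class `discrimination_result`: `retained` classes,
#'   `size`, `accuracy` (percent, on the retained subset), `trace`
#'   (data.frame of eliminated classes with the accuracy before each
#'   removal), `degenerate` flag.
#' @export
max_discriminable_subset <- function(x, classes = NULL, ridge_frac = 1e-8) {
  d <- lda_input(x, classes)
  X <- d$X; cl <- d$classes
  keep <- sort(unique(cl))
  if (length(keep) < 2) stop("need >= 2 classes", call. = FALSE)
  trace <- data.frame(eliminated = character(0), accuracy_before = numeric(0),
                      stringsAsFactors = FALSE)
  repeat {
    sel <- cl %in% keep
    if (length(keep) < 2) {
      return(structure(
        list(retained = keep, size = length(keep), accuracy = NA_real_,
             trace = trace, degenerate = TRUE),
        class = "discrimination_result"))
    }
    rep_ <- jackknife(X[sel, , drop = FALSE], cl[sel], ridge_frac)
    if (rep_$jackknife_accuracy >= 100) {
      return(structure(
        list(retained = keep, size = length(keep),
             accuracy = rep_$jackknife_accuracy, trace = trace,
             degenerate = FALSE),
        class = "discrimination_result"))
    }
    cm <- rep_$confusion
    err <- cm; diag(err) <- 0
    involvement <- rowSums(err) + colSums(err)    # as true + as predicted
    worst <- names(involvement)[which.max(involvement)]  # first max = label order
    trace <- rbind(trace, data.frame(eliminated = worst,
                                     accuracy_before = rep_$jackknife_accuracy,
                                     stringsAsFactors = FALSE))
    keep <- setdiff(keep, worst)
  }
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("<discrimination_result> %d class(es) retained at %.1f%% jackknifed accuracy\n",
              x$size, x$accuracy))
  if (nrow(x$trace)) {
    cat("eliminated:", paste(x$trace$eliminated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Screen all pairwise array combinations
#'
#' For every unordered pair of arrays, concatenates their response columns
#' (the samples must be identical across arrays: same classes in the same
#' order), computes the maximal discriminable subset of the combined
#' responses, and flags pairs whose subset is strictly larger than both
#' constituents' - the bookkeeping behind "n of N combinations improved on
#' the originals".
#'
#' @param matrices Named list (>= 2) of `response_matrix` objects sharing
#'   one sample panel.
#' @param ridge_frac Passed through to the discriminant fits.
#' @return Object of class `combination_report`: `pairs` (data.frame:
#'   array_a, array_b, size_a, size_b, size_combined, better),
#'   `singles` (per-array subset sizes), `n_pairs`, `n_better`.
#' @export
screen_combinations <- function(matrices, ridge_frac = 1e-8) {
  if (length(matrices) < 2) stop("need >= 2 arrays", call. = FALSE)
  nm <- names(matrices)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("matrices must be a named list", call. = FALSE)
  }
  cls <- lapply(matrices, function(m) as.character(m$class))
  for (k in seq_along(cls)[-1L]) {
    if (!identical(cls[[1L]], cls[[k]])) {
      stop("inconsistent analyte panels: samples of '", nm[k],
           "' differ from '", nm[1L], "'", call. = FALSE)
    }
  }
  labels <- cls[[1L]]
  blocks <- lapply(matrices, response_values)
  singles <- vapply(seq_along(blocks), function(k) {
    max_discriminable_subset(blocks[[k]], labels, ridge_frac)$size
  }, integer(1))
  names(singles) <- nm
  combos <- utils::combn(seq_along(blocks), 2)
  pairs <- data.frame(
    array_a = nm[combos[1, ]], array_b = nm[combos[2, ]],
    size_a = singles[combos[1, ]], size_b = singles[combos[2, ]],
    size_combined = NA_integer_, better = NA, stringsAsFactors = FALSE,
    row.names = NULL
  )
  for (i in seq_len(ncol(combos))) {
    comb <- cbind(blocks[[combos[1, i]]], blocks[[combos[2, i]]])
    colnames(comb) <- make.unique(colnames(comb))
    res <- max_discriminable_subset(comb, labels, ridge_frac)
    pairs$size_combined[i] <- res$size
    pairs$better[i] <- res$size > pairs$size_a[i] && res$size > pairs$size_b[i]
  }
  structure(
    list(pairs = pairs, singles = singles, n_pairs = nrow(pairs),
         n_better = sum(pairs$better)),
    class = "combination_report"
  )
}

#' @export
print.combination_report <- function(x, ...) {
  cat(sprintf("<combination_report> %d pair(s), %d better than both constituents\n",
              x$n_pairs, x$n_better))
  print(utils::head(x$pairs, 10))
  if (nrow(x$pairs) > 10) cat("...\n")
  invisible(x)
}

#' Summarize arrays and their discrimination results
#'
#' One tidy row per array: component counts, the discriminated-subset size,
#' and the working-principle tag carried over from builder provenance.
#'
#' @param results Named list of `discrimination_result` objects keyed by
#'   array id.
#' @param arrays Named list of [sensor_array()] objects with matching ids.
#' @return A data.frame with columns `array`, `n_receptors`, `n_dyes`,
#'   `n_conditions`, `n_units`, `discriminated`, `principle`.
#' @export
summarize_arrays <- function(results, arrays) {
  if (length(results) < 1) stop("need >= 1 result", call. = FALSE)
  ids <- names(results)
  rows <- lapply(ids, function(id) {
    arr <- arrays[[id]]
    if (is.null(arr)) stop("no array definition for '", id, "'", call. = FALSE)
    hosts <- unique(unlist(lapply(arr$units, function(u) names(u$host_totals))))
    dyes <- unique(vapply(arr$units, `[[`, character(1), "dye"))
    conds <- unique(vapply(arr$units, `[[`, character(1), "condition"))
    strategies <- unique(vapply(arr$units, function(u) {
      u$provenance$strategy %||% "manual"
    }, character(1)))
    data.frame(array = id,
               n_receptors = length(hosts),
               n_dyes = length(dyes),
               n_conditions = length(conds),
               n_units = length(arr$units),
               discriminated = results[[id]]$size,
               principle = paste(strategies, collapse = "+"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
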