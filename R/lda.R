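#' Fit a Fisher linear discriminant model
#'
#' From-scratch canonical discriminant analysis: the discriminant
#' directions solve the generalized eigenproblem of the between-class
#' scatter against the pooled within-class scatter,
#' maximizing the ratio of interclass to intraclass variance. The pooled
#' scatter is ridge-regularized (`ridge = ridge_frac * trace / dim`) before
#' inversion, the eigenproblem is solved through a Cholesky whitening of the
#' regularized scatter, and directions are scaled to unit within-class
#' variance (canonical scaling) with the sign fixed so the
#' largest-magnitude loading is positive. Variance fractions are
#' `eigenvalue_k / sum(eigenvalues) * 100` over the retained
#' `min(classes - 1, units)` factors.
#'
#' @param x A `response_matrix`, or a numeric matrix/data.frame of
#'   responses (samples x units).
#' @param classes Class labels (ignored when `x` is a `response_matrix`).
#' @param ridge_frac Ridge fraction for the pooled scatter; default `1e-8`.
#' @return An object of class `lda_model`: `scaling` (units x factors),
#'   `eigenvalues`, `var_fractions` (percent, sum 100), `grand_mean`,
#'   `class_means`, `centroids` (score space), `classes` (levels),
#'   `counts`, `within_scatter`, `ridge`.
#' @export
fit_lda <- function(x, classes = NULL, ridge_frac = 1e-8) {
  d <- lda_input(x, classes)
  X <- d$X; cl <- d$classes
  levels_ <- sort(unique(cl))
  K <- length(levels_)
  if (K < 2) stop("need >= 2 classes", call. = FALSE)
  counts <- table(factor(cl, levels = levels_))
  if (any(counts < 2)) {
    stop("every class needs >= 2 samples (offending: ",
         paste(names(counts)[counts < 2], collapse = ", "), ")", call. = FALSE)
  }
  p <- ncol(X)
  gm <- colMeans(X)
  M <- do.call(rbind, lapply(levels_, function(k)
    colMeans(X[cl == k, , drop = FALSE])))
  rownames(M) <- levels_
  Sw <- matrix(0, p, p)
  for (k in levels_) {
    Xi <- sweep(X[cl == k, , drop = FALSE], 2, M[k, ])
    Sw <- Sw + crossprod(Xi)
  }
  Sb <- crossprod(sweep(M, 2, gm) * sqrt(as.numeric(counts)))
  ridge <- ridge_frac * sum(diag(Sw)) / p
  if (ridge <= 0) ridge <- ridge_frac          # all-identical samples guard
  Swr <- Sw + diag(ridge, p)
  R <- tryCatch(chol(Swr), error = function(e) NULL)
  if (is.null(R)) {
    stop("pooled within-class scatter is singular beyond regularization",
         call. = FALSE)
  }
  # A = R^-T Sb R^-1, symmetric; eigenvectors v give directions w = R^-1 v
  A <- backsolve(R, t(backsolve(R, t(Sb), transpose = TRUE)), transpose = TRUE)
  A <- (A + t(A)) / 2
  eg <- eigen(A, symmetric = TRUE)
  r <- min(K - 1L, p)
  vals <- pmax(eg$values[seq_len(r)], 0)
  W <- backsolve(R, eg$vectors[, seq_len(r), drop = FALSE])
  # canonical scaling: unit pooled within-class variance of scores
  n <- nrow(X)
  W <- W * sqrt(n - K)
  for (j in seq_len(r)) {
    if (W[which.max(abs(W[, j])), j] < 0) W[, j] <- -W[, j]
  }
  colnames(W) <- paste0("F", seq_len(r))
  rownames(W) <- colnames(X)
  total <- sum(vals)
  fractions <- if (total > 0) vals / total * 100 else rep(0, r)
  centroids <- sweep(M, 2, gm) %*% W
  structure(
    list(scaling = W, eigenvalues = vals, var_fractions = fractions,
         grand_mean = gm, class_means = M, centroids = centroids,
         classes = levels_, counts = as.integer(counts),
         within_scatter = Sw, ridge = ridge, n = n),
    class = "lda_model"
  )
}

lda_input <- function(x, classes) {
  if (inherits(x, "response_matrix") ||
      (is.data.frame(x) && "class" %in% names(x) && is.null(classes))) {
    classes <- x$class
    X <- response_values(x)
  } else {
    X <- as.matrix(x)
    if (is.null(classes)) stop("class labels required", call. = FALSE)
  }
  if (!is.numeric(X)) stop("responses must be numeric", call. = FALSE)
  if (length(classes) != nrow(X)) stop("label length mismatch", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  list(X = X, classes = as.character(classes))
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes, %d unit(s), %d factor(s)\n",
              length(x$classes), nrow(x$scaling), ncol(x$scaling)))
  cat("variance fractions (%):",
      paste(sprintf("%s=%.2f", colnames(x$scaling), x$var_fractions),
            collapse = " "), "\n")
  invisible(x)
}

#' Project samples onto the canonical discriminant axes
#'
#' Scores are the grand-mean-centred responses projected on each
#' discriminant direction; reprojecting the training data reproduces the
#' model's class centroids.
#'
#' @param model An [fit_lda()] model.
#' @param x Response matrix (`response_matrix`, matrix or data.frame) whose
#'   columns match the training layout.
#' @return Numeric score matrix (samples x factors F1, F2, ...).
#' @export
project <- function(model, x) {
  stopifnot(inherits(model, "lda_model"))
  X <- if (inherits(x, "response_matrix") ||
           (is.data.frame(x) && "class" %in% names(x))) response_values(x)
       else as.matrix(x)
  if (ncol(X) != nrow(model$scaling)) {
    stop("column count does not match the training layout", call. = FALSE)
  }
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), rownames(model$scaling))) {
    if (!setequal(colnames(X), rownames(model$scaling))) {
      stop("columns do not match the training layout", call. = FALSE)
    }
    X <- X[, rownames(model$scaling), drop = FALSE]
  }
  sweep(X, 2, model$grand_mean) %*% model$scaling
}

#' Classify samples by nearest class centroid
#'
#' Distance is Euclidean in the full canonical score space, which under the
#' canonical (within-class-sphering) scaling is equivalent to the
#' Mahalanobis distance in the discriminant subspace. Ties are broken by
#' class label order.
#'
#' @inheritParams project
#' @return Character vector of predicted class labels.
#' @export
classify <- function(model, x) {
  sc <- project(model, x)
  D <- outer(rowSums(sc^2), rep(1, nrow(model$centroids))) -
    2 * sc %*% t(model$centroids) +
    outer(rep(1, nrow(sc)), rowSums(model$centroids^2))
  model$classes[apply(D, 1L, which.min)]
}

#' Leave-one-out (jackknifed) classification report
#'
#' Refits the discriminant model on n - 1 samples, classifies the held-out
#' sample, and repeats for every sample; also reports resubstitution
#' accuracy from the full fit. Requires >= 3 samples per class so every
#' fold retains >= 2.
#'
#' @inheritParams fit_lda
#' @return Object of class `classification_report`: `confusion` (true x
#'   predicted, jackknifed), `resub_accuracy` and `jackknife_accuracy`
#'   (percent), `per_class` (percent, jackknifed), `n`.
#' @export
jackknife <- function(x, classes = NULL, ridge_frac = 1e-8) {
  d <- lda_input(x, classes)
  X <- d$X; cl <- d$classes
  counts <- table(cl)
  if (any(counts < 3)) {
    stop("jackknife requires >= 3 samples per class (offending: ",
         paste(names(counts)[counts < 3], collapse = ", "), ")", call. = FALSE)
  }
  n <- nrow(X)
  full <- fit_lda(X, cl, ridge_frac)
  resub <- classify(full, X)
  pred <- character(n)
  for (i in seq_len(n)) {
    m <- fit_lda(X[-i, , drop = FALSE], cl[-i], ridge_frac)
    pred[i] <- classify(m, X[i, , drop = FALSE])
  }
  levels_ <- full$classes
  confusion <- table(true = factor(cl, levels_), predicted = factor(pred, levels_))
  per_class <- 100 * diag(confusion) / rowSums(confusion)
  structure(
    list(confusion = confusion,
         resub_accuracy = 100 * mean(resub == cl),
         jackknife_accuracy = 100 * mean(pred == cl),
         per_class = per_class, n = n),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> n=%d resubstitution=%.2f%% jackknifed=%.2f%%\n",
              x$n, x$resub_accuracy, x$jackknife_accuracy))
  print(x$confusion)
  invisible(x)
}

#' 95 percent confidence ellipse of a score cloud
#'
#' For 2-D canonical scores of one class: centre at the class mean, axis
#' directions from the eigenvectors of the score covariance, semi-axis
#' lengths `sqrt(eigenvalue * qchisq(level, df = 2))`. A cloud lying on a
#' line yields a degenerate (zero) minor axis, flagged in the result.
#'
#' @param scores Numeric matrix with 2 columns and >= 3 rows.
#' @param level Coverage level, default 0.95.
#' @return Object of class `confidence_ellipse`: `center`, `radii`
#'   (semi-axes, decreasing), `axes` (columns = axis directions), `angle`
#'   (radians of the major axis), `level`, `n`, `degenerate`.
#' @export
confidence_ellipse <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("scores must be 2-D", call. = FALSE)
  if (nrow(scores) < 3) stop("need >= 3 points for an ellipse", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  ctr <- colMeans(scores)
  S <- stats::cov(scores)
  eg <- eigen(S, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  radii <- sqrt(vals * stats::qchisq(level, df = 2))
  degenerate <- radii[2] <= 1e-12 * max(radii[1], 1e-300)
  structure(
    list(center = ctr, radii = radii, axes = eg$vectors,
         angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
         level = level, n = nrow(scores), degenerate = degenerate),
    class = "confidence_ellipse"
  )
}

#' Confidence ellipses for every class of a score plot
#'
#' @param scores Score matrix (uses the first two factors).
#' @param classes Class labels.
#' @param level Coverage level.
#' @return Named list of [confidence_ellipse()] objects.
#' @export
class_ellipses <- function(scores, classes, level = 0.95) {
  classes <- as.character(classes)
  sc2 <- as.matrix(scores)[, 1:2, drop = FALSE]
  lv <- sort(unique(classes))
  stats::setNames(lapply(lv, function(k) {
    confidence_ellipse(sc2[classes == k, , drop = FALSE], level)
  }), lv)
}

# squared ellipse-frame norm of a point: <= 1 inside
ellipse_norm2 <- function(e, pt) {
  r <- pmax(e$radii, 1e-12 * max(e$radii[1], 1e-300))
  u <- crossprod(e$axes, pt - e$center) / r
  sum(u * u)
}

ellipse_boundary_point <- function(e, t) {
  as.numeric(e$center + e$axes %*% (e$radii * c(cos(t), sin(t))))
}

ellipse_pair_overlap <- function(e1, e2, tol = 1e-9) {
  if (ellipse_norm2(e1, e2$center) <= 1 + tol) return(TRUE)
  if (ellipse_norm2(e2, e1$center) <= 1 + tol) return(TRUE)
  # minimum of the e1-frame norm over the boundary of e2
  f <- function(t) ellipse_norm2(e1, ellipse_boundary_point(e2, t))
  tgrid <- seq(0, 2 * pi, length.out = 721L)[-721L]
  vals <- vapply(tgrid, f, numeric(1))
  i <- which.min(vals)
  h <- 2 * pi / 720
  opt <- stats::optimize(f, interval = c(tgrid[i] - h, tgrid[i] + h))
  sqrt(min(vals[i], opt$objective)) <= 1 + tol
}

#' Pairwise geometric overlap of confidence ellipses
#'
#' Two ellipses overlap when one centre lies inside the other or their
#' boundaries intersect; tangency within `tol` counts as overlap. The test
#' is symmetric.
#'
#' @param ellipses Named list of [confidence_ellipse()] objects (>= 2).
#' @param tol Tangency tolerance, default `1e-9`.
#' @return Symmetric logical matrix; `any_overlap` attribute flags whether
#'   any pair overlaps.
#' @export
overlap_check <- function(ellipses, tol = 1e-9) {
  if (length(ellipses) < 2) stop("need >= 2 ellipses", call. = FALSE)
  nm <- names(ellipses) %||% paste0("E", seq_along(ellipses))
  n <- length(ellipses)
  M <- matrix(FALSE, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ov <- ellipse_pair_overlap(ellipses[[i]], ellipses[[j]], tol)
    M[i, j] <- M[j, i] <- ov
  }
  attr(M, "any_overlap") <- any(M)
  M
}
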