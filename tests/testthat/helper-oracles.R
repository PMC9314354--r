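# Independent oracles used by the tests. Each re-derives the quantity it
# checks through a different route than the implementation under test.

# 1:1 single-pair bound concentration by pure bisection on the mass balance
# f(x) = Ka (Ht - x)(Gt - x) - x over [0, min(Ht, Gt)].
bisect_pair_bound <- function(host_total, guest_total, Ka, steps = 200L) {
  if (Ka == 0 || host_total == 0 || guest_total == 0) return(0)
  f <- function(x) Ka * (host_total - x) * (guest_total - x) - x
  lo <- 0
  hi <- min(host_total, guest_total)
  for (i in seq_len(steps)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# single-host / multi-guest free-host concentration by bisection on
# g(h) = h (1 + sum_i K_i G_i / (1 + K_i h)) - Ht, monotone increasing in h
bisect_single_host_free <- function(host_total, guest_totals, kas, steps = 200L) {
  g <- function(h) h * (1 + sum(kas * guest_totals / (1 + kas * h))) - host_total
  lo <- 0
  hi <- host_total
  for (i in seq_len(steps)) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# dense-grid scan over free-host for one host + any guests: returns the grid
# point minimizing the absolute host mass-balance residual (guest frees
# eliminated analytically)
grid_single_host_free <- function(host_total, guest_totals, kas, n = 20001L) {
  hs <- seq(0, host_total, length.out = n)
  res <- abs(hs * (1 + vapply(hs, function(h)
    sum(kas * guest_totals / (1 + kas * h)), numeric(1))) - host_total)
  hs[which.min(res)]
}

# brute-force canonical discriminant oracle: explicit scatter matrices and a
# plain (non-symmetric) eigendecomposition of solve(Sw_ridge) %*% Sb
oracle_lda_scores <- function(X, classes, ridge_frac = 1e-8) {
  X <- as.matrix(X)
  classes <- as.character(classes)
  lv <- sort(unique(classes))
  p <- ncol(X)
  gm <- colMeans(X)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (k in lv) {
    Xi <- X[classes == k, , drop = FALSE]
    mk <- colMeans(Xi)
    for (r in seq_len(nrow(Xi))) {
      d <- Xi[r, ] - mk
      Sw <- Sw + tcrossprod(d)
    }
    dm <- mk - gm
    Sb <- Sb + nrow(Xi) * tcrossprod(dm)
  }
  Swr <- Sw + diag(ridge_frac * sum(diag(Sw)) / p, p)
  eg <- eigen(solve(Swr) %*% Sb)
  r <- min(length(lv) - 1L, p)
  ord <- order(Re(eg$values), decreasing = TRUE)[seq_len(r)]
  W <- Re(eg$vectors[, ord, drop = FALSE])
  list(scores = sweep(X, 2, gm) %*% W,
       eigenvalues = Re(eg$values[ord]))
}

# absolute column-wise correlation between two score matrices (per-factor
# agreement up to sign and scale)
score_agreement <- function(a, b) {
  vapply(seq_len(ncol(a)), function(j) abs(stats::cor(a[, j], b[, j])), numeric(1))
}
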