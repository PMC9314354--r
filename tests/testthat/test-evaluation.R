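make_sep_matrix <- function(K = 5, per = 6, q = 4, sep = 12, seed = 1) {
  fx <- fix_clusters(K = K, per = per, q = q, sep = sep, seed = seed)
  df <- data.frame(class = fx$classes, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(fx$X))
  structure(df, class = c("response_matrix", "data.frame"))
}

test_that("perfectly separated classes are fully retained", {
  rm_ <- make_sep_matrix(K = 5, seed = 4)
  res <- max_discriminable_subset(rm_)
  expect_identical(res$size, 5L)
  expect_equal(res$accuracy, 100)
  expect_identical(nrow(res$trace), 0L)
  expect_false(res$degenerate)
})

test_that("a duplicated fingerprint eliminates exactly one of the pair", {
  fx <- fix_clusters(K = 4, per = 6, q = 4, sep = 12, seed = 6)
  X <- fx$X
  cl <- fx$classes
  # make class c02 sit exactly on c01's fingerprint (same cloud statistics)
  X[cl == "c02", ] <- X[cl == "c01", ] + matrix(stats::rnorm(sum(cl == "c01") * 4,
                                                             sd = 0.5),
                                                ncol = 4)
  res <- max_discriminable_subset(X, cl)
  expect_identical(res$size, 3L)
  eliminated <- res$trace$eliminated
  expect_length(eliminated, 1L)
  expect_true(eliminated %in% c("c01", "c02"))
  expect_true(length(intersect(c("c01", "c02"), res$retained)) == 1L)
})

test_that("greedy subsets never beat the exhaustive optimum and match it when confirmed", {
  exhaustive_best <- function(X, cl) {
    lv <- sort(unique(cl))
    best <- 0L
    for (size in rev(seq(2, length(lv)))) {
      subs <- utils::combn(lv, size, simplify = FALSE)
      for (s in subs) {
        sel <- cl %in% s
        acc <- jackknife(X[sel, , drop = FALSE], cl[sel])$jackknife_accuracy
        if (acc >= 100) return(size)
      }
    }
    best
  }
  for (seed in c(3, 14)) {
    fx <- fix_clusters(K = 5, per = 4, q = 3, sep = 2.2, sd = 1, seed = seed)
    greedy <- max_discriminable_subset(fx$X, fx$classes)$size
    opt <- exhaustive_best(fx$X, fx$classes)
    expect_lte(greedy, opt)
  }
  # on a cleanly separable instance the greedy result is confirmed optimal
  fx <- fix_clusters(K = 5, per = 4, q = 3, sep = 12, seed = 2)
  expect_identical(max_discriminable_subset(fx$X, fx$classes)$size,
                   exhaustive_best(fx$X, fx$classes))
})

test_that("elimination is deterministic with label-order tie-breaks", {
  fx <- fix_clusters(K = 4, per = 6, q = 3, sep = 1, sd = 2, seed = 18)
  r1 <- max_discriminable_subset(fx$X, fx$classes)
  r2 <- max_discriminable_subset(fx$X, fx$classes)
  expect_identical(r1, r2)
})

test_that("pairwise screening counts C(n,2) pairs and excludes self-pairs", {
  mats <- stats::setNames(lapply(1:4, function(s)
    make_sep_matrix(K = 4, per = 6, q = 2, sep = 6, seed = s)), paste0("SA", 1:4))
  rep_ <- screen_combinations(mats)
  expect_identical(rep_$n_pairs, 6L)
  expect_false(any(rep_$pairs$array_a == rep_$pairs$array_b))
  expect_identical(anyDuplicated(paste(rep_$pairs$array_a, rep_$pairs$array_b)), 0L)
})

test_that("complementary confusions combine into a larger subset", {
  # array A separates classes 1-3 but collapses 4/5; array B the reverse
  set.seed(25)
  K <- 5; per <- 6
  cl <- rep(sprintf("c%d", 1:K), each = per)
  centers_a <- rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8), c(8, 8))
  centers_b <- rbind(c(0, 0), c(4, 4), c(4, 4), c(0, 8), c(8, 0))
  Xa <- centers_a[rep(1:K, each = per), ] + matrix(rnorm(K * per * 2, sd = 0.4),
                                                   ncol = 2)
  Xb <- centers_b[rep(1:K, each = per), ] + matrix(rnorm(K * per * 2, sd = 0.4),
                                                   ncol = 2)
  mk <- function(X, prefix) {
    colnames(X) <- paste0(prefix, 1:2)
    df <- cbind(data.frame(class = cl, stringsAsFactors = FALSE),
                as.data.frame(X))
    structure(df, class = c("response_matrix", "data.frame"))
  }
  rep_ <- screen_combinations(list(A = mk(Xa, "a"), B = mk(Xb, "b")))
  expect_identical(rep_$n_pairs, 1L)
  expect_lt(rep_$pairs$size_a, K)
  expect_lt(rep_$pairs$size_b, K)
  expect_identical(rep_$pairs$size_combined, 5L)
  expect_true(rep_$pairs$better)
  expect_identical(rep_$n_better, 1L)
})

test_that("combining arrays preserves separability; jackknife drops are reported", {
  # Feature concatenation cannot destroy the information a constituent used:
  # the combined responses must still separate the larger constituent's
  # retained subset at 100% resubstitution. The leave-one-out subset size
  # can occasionally dip below a constituent's (the LOO estimate moves when
  # noisy extra columns enter the fit); such dips are counted and reported,
  # not hidden.
  loo_drops <- character(0)
  for (s in 1:8) {
    spec <- scenario_spec(n_hosts = 4, n_dyes = 2, n_analytes = 6,
                          seed = 7000 + s)
    aff <- sample_affinity_panel(spec)
    ph <- scenario_photophysics(spec)
    a1 <- build_reporter_pair_array(list(list(hosts = c("H1", "H2"), dye = "D1"),
                                         list(hosts = c("H3", "H4"), dye = "D1")),
                                    affinities = aff, photophysics = ph, id = "A")
    a2 <- build_reporter_pair_array(list(list(hosts = c("H1", "H3"), dye = "D2"),
                                         list(hosts = c("H2", "H4"), dye = "D2")),
                                    affinities = aff, photophysics = ph, id = "B")
    doses <- fix_doses(6)
    m1 <- simulate_responses(a1, doses, replicates = 6, noise_cv = 0.02, seed = s)
    m2 <- simulate_responses(a2, doses, replicates = 6, noise_cv = 0.02,
                             seed = s + 500)
    rep_ <- screen_combinations(list(A = m1, B = m2))
    best <- if (rep_$pairs$size_a >= rep_$pairs$size_b) "A" else "B"
    best_sub <- max_discriminable_subset(if (best == "A") m1 else m2)$retained
    sel <- m1$class %in% best_sub
    comb <- cbind(response_values(m1), response_values(m2))
    colnames(comb) <- make.unique(colnames(comb))
    model <- fit_lda(comb[sel, , drop = FALSE], m1$class[sel])
    resub <- mean(classify(model, comb[sel, , drop = FALSE]) == m1$class[sel])
    expect_equal(resub, 1)
    if (rep_$pairs$size_combined < max(rep_$pairs$size_a, rep_$pairs$size_b)) {
      loo_drops <- c(loo_drops, sprintf("seed %d: %d,%d -> %d", s,
                                        rep_$pairs$size_a, rep_$pairs$size_b,
                                        rep_$pairs$size_combined))
    }
  }
  if (length(loo_drops)) {
    message("jackknife subset dips under combination: ",
            paste(loo_drops, collapse = "; "))
  }
})

test_that("inconsistent analyte panels across arrays are rejected", {
  a <- make_sep_matrix(K = 4, seed = 1)
  b <- make_sep_matrix(K = 4, seed = 2)
  b$class[1] <- "other"
  expect_error(screen_combinations(list(A = a, B = b)), "inconsistent")
})

test_that("array summaries carry provenance working principles", {
  aff <- affinity_table(data.frame(host = c("CA", "CD"), guest = "D1",
                                   Ka_per_M = c(1e6, 1e5)))
  arrays <- list(
    SA_ratio = build_pair_ratio_array(c("CA", "CD"), "D1", c(0.8, 1, 1.2),
                                      affinities = aff, id = "SA_ratio"),
    SA_dyes = build_dye_replacement_array(c("CA", "CD"), c("D1", "D2"),
                                          id = "SA_dyes"))
  results <- list(
    SA_ratio = structure(list(size = 3L), class = "discrimination_result"),
    SA_dyes = structure(list(size = 2L), class = "discrimination_result"))
  tab <- summarize_arrays(results, arrays)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$principle, c("pair_ratio", "dye_replacement"))
  expect_identical(tab$n_receptors, c(2L, 2L))
  expect_identical(tab$discriminated, c(3L, 2L))
  expect_identical(tab$n_dyes, c(1L, 2L))
})
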