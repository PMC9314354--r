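# Shared fixture builders; everything is generated in code at test time.

# one-host/one-dye/one-analyte affinity table
fix_triple_affinities <- function(ka_hd = 1e6, ka_ha = 1e7, condition = "default") {
  affinity_table(data.frame(
    host = "H1", guest = c("D1", "A1"), condition = condition,
    Ka_per_M = c(ka_hd, ka_ha)))
}

fix_unit <- function(host_total = 1e-6, dye_total = 1e-6) {
  sensor_unit("u1", c(H1 = host_total), "D1", dye_total)
}

# small reporter-pair array over a sampled panel; returns list(array, spec)
fix_panel_array <- function(n_analytes = 5, seed = 11, noise_cv = 0.02,
                            replicates = 6) {
  spec <- scenario_spec(n_hosts = 3, n_dyes = 2, n_analytes = n_analytes,
                        replicates = replicates, noise_cv = noise_cv,
                        seed = seed)
  aff <- sample_affinity_panel(spec)
  photo <- scenario_photophysics(spec)
  arr <- build_reporter_pair_array(
    pairs = list(list(hosts = c("H1", "H2"), dye = "D1"),
                 list(hosts = c("H1", "H3"), dye = "D1"),
                 list(hosts = c("H2", "H3"), dye = "D2")),
    affinities = aff, photophysics = photo, id = sprintf("fix%d", seed))
  list(array = arr, spec = spec, affinities = aff, photo = photo)
}

fix_doses <- function(n_analytes, dose = 2e-6) {
  stats::setNames(rep(dose, n_analytes), sprintf("A%d", seq_len(n_analytes)))
}

# well-separated Gaussian clusters in q dimensions
fix_clusters <- function(K = 3, per = 6, q = 4, sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(K * q), K, q) * sep
  X <- centers[rep(seq_len(K), each = per), ] +
    matrix(stats::rnorm(K * per * q, sd = sd), K * per, q)
  colnames(X) <- paste0("V", seq_len(q))
  list(X = X, classes = rep(sprintf("c%02d", seq_len(K)), each = per))
}
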