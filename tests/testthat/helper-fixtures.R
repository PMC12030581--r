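# Shared in-code fixtures: tiny datasets built programmatically.

tiny_samples <- function(n = 2L, descriptors = TRUE) {
  s <- data.frame(
    sample_id = seq_len(n),
    drug_name = rep(c("Ibuprofen", "Curcumin", "Dopamine"), length.out = n),
    smiles = NA_character_,
    polymer_mw = seq(20, 100, length.out = n),
    pdi = rep(0.2, n),
    particle_size = rep(150, n),
    zeta_potential = rep(-20, n),
    monomer_ratio = rep(0.5, n),
    encapsulation_efficiency = rep(80, n),
    source = "test",
    stringsAsFactors = FALSE)
  if (descriptors) {
    for (i in seq_along(descriptor_features())) {
      s[[descriptor_features()[i]]] <- i + seq_len(n) / 10
    }
  }
  s
}

tiny_obs <- function(sample_id, times, release) {
  data.frame(sample_id = sample_id, time_h = times, release_pct = release)
}

# A 2-sample dataset with 5 points each, exact Weibull/K-P curves and no
# descriptor columns filled (exercises the pre-featurization state).
tiny_dataset <- function() {
  t1 <- c(1, 2, 4, 8, 16)
  t2 <- c(0.5, 1, 2, 4, 8)
  release_dataset(
    tiny_samples(2, descriptors = FALSE),
    rbind(tiny_obs(1, t1, 100 * weibull_release(t1, tau = 4, beta = 1)),
          tiny_obs(2, t2, 100 * kp_release(t2, k = 0.2, n = 0.5))))
}

# Feature rows with descriptors filled by constants (no chemistry needed).
tiny_rows <- function(n_samples = 3L, n_points = 5L) {
  s <- tiny_samples(n_samples)
  obs <- do.call(rbind, lapply(seq_len(n_samples), function(id) {
    t <- seq(1, 24, length.out = n_points)
    tiny_obs(id, t, 100 * weibull_release(t, tau = 8, beta = 0.9))
  }))
  to_feature_rows(release_dataset(s, obs))
}
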