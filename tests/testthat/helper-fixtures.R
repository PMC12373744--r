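# Shared fixtures: all synthetic, built in code at test time.

small_atlas <- function() make_atlas(4, 25)

# A tiny but complete cohort spec for fast tests.
tiny_spec <- function(seed = 1, ...) {
  cohort_spec(n_td = 12, n_et = 12, n_hc = 12,
              atlas_spec = list(n_regions = 4, vertices_per_region = 25),
              seed = seed, ...)
}

tiny_cohort <- function(seed = 1, ...) simulate_cohort(tiny_spec(seed, ...))

# Hand-built 6-subject dataset: two groups of 3, constant-ish thickness.
toy_dataset <- function(values_a = c(2.1, 2.2, 2.3),
                        values_b = c(2.6, 2.7, 2.8)) {
  atl <- small_atlas()
  n <- length(values_a) + length(values_b)
  thick <- matrix(rep(c(values_a, values_b), length(atl$vertex_ids)),
                  nrow = n)
  meta <- data.frame(
    subject_id = sprintf("s%d", seq_len(n)),
    group = rep(c("TD", "HC"), c(length(values_a), length(values_b))),
    age = seq(60, by = 1, length.out = n),
    sex = rep(c("M", "F"), length.out = n),
    duration = c(rep(5, length(values_a)), rep(NA, length(values_b))))
  vols <- data.frame(Pallidum.L = rep(1900, n), Pallidum.R = rep(1870, n),
                     Thalamus.L = rep(7000, n), Thalamus.R = rep(7000, n))
  morphometry_dataset(thick, vols, subject_metadata(meta), atl)
}

# Brute-force normal-equations oracle for the first-order signed-path GC fit.
oracle_gc <- function(x, y) {
  T <- length(x)
  Z <- cbind(1, y[-T], x[-T])
  b <- solve(t(Z) %*% Z, t(Z) %*% y[-1])
  b[3]
}

sig_clusters <- function(cl) {
  Filter(function(c) isTRUE(c$significant), cl$clusters)
}
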