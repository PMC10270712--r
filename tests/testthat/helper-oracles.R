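# Independent oracles and shared fixtures for the test suite.
# These deliberately use different code paths (comparison-based binning,
# direct probability enumeration, explicit loops) than the package.

# Brute-force plug-in MI oracle: equal-width bins assigned by comparing
# against explicit edges, joint probabilities enumerated cell by cell,
# MI as sum p * log2(p / (px * py)).
oracle_mi <- function(x, y, bins) {
  assign_bins <- function(v) {
    edges <- seq(min(v), max(v), length.out = bins + 1)
    vapply(v, function(z) min(bins, sum(z >= edges[-(bins + 1)])), numeric(1))
  }
  bx <- assign_bins(x)
  by <- assign_bins(y)
  n <- length(x)
  mi <- 0
  for (a in unique(bx)) {
    for (b in unique(by)) {
      p <- sum(bx == a & by == b) / n
      if (p > 0) mi <- mi + p * log2(p / ((sum(bx == a) / n) * (sum(by == b) / n)))
    }
  }
  mi
}

# Direct-summation lag-k sample autocorrelation.
oracle_acf <- function(x, k) {
  xc <- x - mean(x)
  sum(xc[(k + 1):length(x)] * xc[1:(length(x) - k)]) / sum(xc^2)
}

# Spearman rho by explicit average-rank arithmetic.
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  num / sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Small coupled/uncoupled datasets shared across gradient tests.
coupled_pairs_mixed <- function() {
  c(lapply(1:5, function(i) c(i, i + 5)),    # reciprocal, fast half
    lapply(1:5, function(i) c(i + 5, i)),
    lapply(11:15, function(i) c(i, i + 5)))  # unidirectional, slow sources
}

coupled_edge_rows <- function(idx) {
  vapply(c(1:5, 11:15), function(i) edge_lookup(idx, i, i + 5), integer(1))
}

make_coupled_config <- function(seed, n_regions = 20L, strength = 0.4) {
  simulation_config(n_subjects = 1L, n_epochs_per_subject = 10L,
                    n_regions = n_regions,
                    phi = gradient_phi(n_regions, 0.3, 0.95),
                    coupling_strength = strength,
                    coupling_pairs = coupled_pairs_mixed(),
                    coupling_epochs = 6:10, seed = seed)
}

make_uncoupled_config <- function(seed, n_regions = 20L,
                                  n_epochs = 10L, duration = 10) {
  simulation_config(n_subjects = 1L, n_epochs_per_subject = n_epochs,
                    n_regions = n_regions, epoch_duration = duration,
                    phi = gradient_phi(n_regions, 0.3, 0.95), seed = seed)
}

random_epoch <- function(n_regions, n_samples, fs = 256) {
  epoched_ts(matrix(rnorm(n_regions * n_samples), n_regions), fs)
}
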