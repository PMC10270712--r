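test_that("gaussian surrogates preserve amplitude spectra and break cross-correlation", {
  set.seed(3)
  shared <- rnorm(1024)
  ep <- epoched_ts(rbind(shared + 0.3 * rnorm(1024),
                         shared + 0.3 * rnorm(1024),
                         rnorm(1024)), 256)
  g <- gaussian_surrogate(ep, seed = 11)
  for (r in 1:3) {
    a <- Mod(fft(ep$data[r, ])); b <- Mod(fft(g$data[r, ]))
    expect_lt(max(abs(a - b) / pmax(a, 1e-12)), 1e-8)
    # Parseval: variance preserved
    expect_equal(mean(g$data[r, ]^2), mean(ep$data[r, ]^2), tolerance = 1e-8)
  }
  expect_gt(cor(ep$data[1, ], ep$data[2, ]), 0.8)
  # strongly correlated parent -> decorrelated surrogates (median over seeds)
  rs <- vapply(1:20, function(s) {
    gs <- gaussian_surrogate(ep, seed = s)
    abs(cor(gs$data[1, ], gs$data[2, ]))
  }, numeric(1))
  expect_lt(median(rs), 0.1)
  # pure sinusoid parent: surrogate concentrates energy in the same bin
  s <- sin(2 * pi * 8 * (0:255) / 256)
  eps <- epoched_ts(rbind(s, rnorm(256)), 256)
  gs <- gaussian_surrogate(eps, seed = 2)
  amp <- Mod(fft(gs$data[1, ]))
  expect_equal(which.max(amp[1:128]), 9)  # bin of 8 cycles (1-based)
  expect_lt(sum(amp[-c(9, 256 - 7)]), 1e-6 * sum(amp))
})

test_that("phase surrogates preserve spectra and the static correlation matrix", {
  set.seed(13)
  for (T in c(512, 513)) {  # even and odd lengths
    shared <- rnorm(T)
    ep <- epoched_ts(rbind(shared + 0.5 * rnorm(T), shared + 0.5 * rnorm(T),
                           rnorm(T), cumsum(rnorm(T))), 256)
    p <- phase_surrogate(ep, seed = 7)
    expect_lt(max(abs(cor(t(ep$data)) - cor(t(p$data)))), 1e-8)
    for (r in 1:4) {
      a <- Mod(fft(ep$data[r, ])); b <- Mod(fft(p$data[r, ]))
      expect_lt(max(abs(a - b) / pmax(a, 1e-12)), 1e-8)
    }
    # forcing zero phases reproduces the parent exactly
    p0 <- phase_surrogate(ep, phases = rep(0, (T - 1) %/% 2))
    expect_equal(p0$data, ep$data, tolerance = 1e-12)
  }
})

test_that("phase surrogates keep stationary cross-structure but break edge dynamics", {
  cfg <- simulation_config(n_subjects = 1, n_epochs_per_subject = 1,
                           n_regions = 2, phi = c(0.5, 0.5),
                           coupling_strength = 0.8, bandpass = NULL,
                           coupling_pairs = list(c(1, 2)),
                           coupling_epochs = 1L, coupling_lag = 3L, seed = 4)
  ep <- generate_dataset(cfg)$epochs[[1]]
  p <- phase_surrogate(ep, seed = 9)
  # the shared rotation preserves the full cross-spectrum, hence circular
  # lagged cross-correlations are reproduced exactly ...
  circ <- function(x, k) {
    T <- ncol(x)
    cor(x[1, ], c(x[2, (k + 1):T], x[2, 1:k]))
  }
  for (k in c(1, 3, 5))
    expect_equal(circ(p$data, k), circ(ep$data, k), tolerance = 1e-10)
  expect_lt(abs(cor(ep$data[1, ], ep$data[2, ]) -
                cor(p$data[1, ], p$data[2, ])), 1e-8)  # zero-lag preserved
  # ... while the temporal structure of the co-activation signal changes
  e_par <- drop(edge_time_series(ep)$data)
  e_sur <- drop(edge_time_series(p)$data)
  a_par <- acf(e_par, 10, plot = FALSE)$acf[-1]
  a_sur <- acf(e_sur, 10, plot = FALSE)$acf[-1]
  expect_gt(max(abs(a_par - a_sur)), 0.02)
})

test_that("regional null is the geometric mean of nodal decay times", {
  rn <- regional_null_fid(c(4, 9))
  expect_equal(rn$matrix[1, 2], 6)
  expect_equal(regional_null_fid(c(3, 3, 3))$matrix, matrix(3, 3, 3))
  taus <- c(3, 5, 7)
  rn3 <- regional_null_fid(taus)
  for (i in 1:3) for (j in 1:3)
    expect_equal(rn3$matrix[i, j], sqrt(taus[i] * taus[j]))
  expect_true(all(rn3$matrix >= min(taus) & rn3$matrix <= max(taus)))
  expect_equal(diag(rn3$matrix), taus)
  expect_error(regional_null_fid(c(2, 0)), "positive")
})

test_that("null decay tables align with trials and are seed-deterministic", {
  cfg <- simulation_config(n_subjects = 1, n_epochs_per_subject = 3,
                           n_regions = 5, epoch_duration = 3,
                           phi = gradient_phi(5, 0.4, 0.9), seed = 21)
  ds <- generate_dataset(cfg)
  reg <- null_decay_tables(ds, "regional", max_delay = 63, tail_points = 40)
  # regional rows are the pairwise geometric means of the nodal decays
  idx <- reg$edge_index
  nodal <- trial_decay_table(ds, "node", max_delay = 63,
                             tail_points = 40)$values
  for (q in seq_len(nrow(idx)))
    expect_equal(reg$values[1, q],
                 sqrt(nodal[1, idx[q, 1]] * nodal[1, idx[q, 2]]))
  g1 <- null_decay_tables(ds, "gaussian", max_delay = 63, tail_points = 40, seed = 5)
  g2 <- null_decay_tables(ds, "gaussian", max_delay = 63, tail_points = 40, seed = 5)
  expect_identical(g1$values, g2$values)
  expect_identical(g1$trial_ids, reg$trial_ids)
  expect_equal(dim(g1$values), c(3L, 10L))
})

test_that("with no coupling the regional null reproduces the trial-averaged edge decays", {
  devs <- vapply(1:5, function(s) {
    ds <- generate_dataset(simulation_config(n_subjects = 1,
      n_epochs_per_subject = 6, n_regions = 8, epoch_duration = 5,
      phi = gradient_phi(8, 0.3, 0.95), seed = s))
    emp <- standardize_within_trial(
      trial_decay_table(ds, "edge", max_delay = 63, tail_points = 40))
    nul <- standardize_within_trial(
      null_decay_tables(ds, "regional", max_delay = 63, tail_points = 40))
    median(abs(colMeans(emp$values) - colMeans(nul$values)))
  }, numeric(1))
  expect_lt(median(devs), 0.35)
})
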