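test_that("toy leadfield geometry is deterministic with distance-decaying gain", {
  h1 <- toy_leadfield(8, 20, seed = 3)
  h2 <- toy_leadfield(8, 20, seed = 3)
  expect_identical(h1$leadfield, h2$leadfield)
  expect_equal(dim(h1$leadfield), c(20L, 8L))
  # the sensor nearest a source carries its largest leadfield entry
  for (s in 1:8) {
    d <- sqrt(colSums((t(h1$sensor_positions) - h1$source_positions[s, ])^2))
    expect_equal(which.max(h1$leadfield[, s]), which.min(d))
    # entries match direct 1/d^2 evaluation
    expect_equal(h1$leadfield[, s], 1 / d^2, tolerance = 1e-12)
  }
  # column-normalized leadfield invariant under global geometry scaling
  h_s <- h1
  h_s$source_positions <- 2 * h1$source_positions
  h_s$sensor_positions <- 2 * h1$sensor_positions
  d2 <- function(h) t(apply(h$sensor_positions, 1, function(p)
    colSums((t(h$source_positions) - p)^2)))
  L2 <- 1 / d2(h_s)
  cn <- function(L) sweep(L, 2, sqrt(colSums(L^2)), "/")
  expect_equal(cn(L2), cn(h1$leadfield), tolerance = 1e-10)
})

test_that("forward projection realizes the requested SNR with distance-correlated noise", {
  set.seed(6)
  h <- toy_leadfield(6, 24, seed = 1)
  src <- matrix(rnorm(6 * 2560), 6)
  y <- forward_noise_project(src, h, snr = 12, seed = 4)
  sig <- h$leadfield %*% src
  noise <- y - sig
  snr_hat <- mean(sig^2) / mean(noise^2)
  expect_lt(abs(snr_hat - 12) / 12, 0.05)
  # adjacent sensors carry more correlated noise than distant ones
  dist <- as.matrix(dist(h$sensor_positions))
  nc <- cor(t(noise))
  ut <- upper.tri(dist)
  expect_lt(cor(dist[ut], nc[ut], method = "spearman"), 0)
  # snr -> infinity limit approaches pure projection
  y_inf <- forward_noise_project(src, h, snr = 1e12, seed = 4)
  expect_lt(max(abs(y_inf - sig)) / max(abs(sig)), 1e-4)
})

test_that("LCMV beamformer satisfies unit gain and recovers a single active source", {
  h <- toy_leadfield(6, 24, seed = 2)
  set.seed(8)
  src <- matrix(0, 6, 2000)
  src[3, ] <- as.numeric(arima.sim(list(ar = 0.8), 2000))
  y <- h$leadfield %*% src + 1e-6 * matrix(rnorm(24 * 2000), 24)
  rec <- inverse_reconstruct(y, h, regularization = 1e-8)
  expect_gt(cor(rec[3, ], src[3, ]), 0.99)
  # unit-gain constraint w_i' l_i = 1
  yc <- y - rowMeans(y)
  C <- tcrossprod(yc) / ncol(y)
  Creg <- C + 1e-8 * mean(diag(C)) * diag(24)
  Ci <- solve(Creg)
  for (i in 1:6) {
    w <- (Ci %*% h$leadfield[, i]) /
      drop(crossprod(h$leadfield[, i], Ci %*% h$leadfield[, i]))
    expect_equal(drop(crossprod(w, h$leadfield[, i])), 1, tolerance = 1e-10)
  }
  # beamformer output invariant to overall leadfield scaling
  h_s <- h; h_s$leadfield <- 3.7 * h$leadfield
  rec_s <- inverse_reconstruct(y, h_s, regularization = 1e-8)
  expect_equal(rec_s, rec / 3.7, tolerance = 1e-8)
})

test_that("linear mixing inflates zero-lag correlations that fall off with separation", {
  h <- toy_leadfield(10, 30, seed = 5)
  set.seed(10)
  src <- matrix(rnorm(10 * 2560), 10)
  y <- forward_noise_project(src, h, snr = 12, seed = 11)
  rec <- inverse_reconstruct(y, h)
  ut <- upper.tri(diag(10))
  r_true <- abs(cor(t(src))[ut])
  r_rec <- abs(cor(t(rec))[ut])
  expect_gt(mean(r_rec), mean(r_true))
  sep <- as.matrix(dist(h$source_positions))[ut]
  expect_lt(cor(sep, r_rec, method = "spearman"), 0)
})

test_that("linear mixing alone does not reproduce the empirical decay topography", {
  cfg <- simulation_config(n_subjects = 1, n_epochs_per_subject = 6,
    n_regions = 10, epoch_duration = 5, phi = gradient_phi(10, 0.3, 0.95),
    coupling_strength = 0.4,
    coupling_pairs = list(c(1, 6), c(6, 1), c(2, 7), c(7, 2), c(3, 8), c(8, 3)),
    coupling_epochs = 4:6, seed = 3)
  ds <- generate_dataset(cfg)
  emp_fid <- fid_matrix(trial_decay_table(ds, "edge", max_delay = 63,
                                          tail_points = 40))
  null_fid <- fid_matrix(null_decay_tables(ds, "regional", max_delay = 63,
                                           tail_points = 40))
  h <- toy_leadfield(10, 30, seed = 2)
  leak <- leakage_fid(cfg, h, max_delay = 63, tail_points = 40, seed = 5,
                      standardized = FALSE)
  ut <- upper.tri(emp_fid$matrix)
  r_null <- cor(emp_fid$matrix[ut], null_fid$matrix[ut], method = "spearman")
  r_leak <- cor(emp_fid$matrix[ut], leak$fid$matrix[ut], method = "spearman")
  expect_gt(r_null, r_leak)
  expect_gt(r_null, 0.5)   # nodal structure explains the average topography
  expect_lt(r_leak, 0.5)   # volume conduction alone does not
})

test_that("leakage FID pipeline is deterministic and structurally sane", {
  cfg <- simulation_config(n_subjects = 1, n_epochs_per_subject = 3,
                           n_regions = 6, epoch_duration = 3,
                           phi = gradient_phi(6, 0.4, 0.9), seed = 2)
  h <- toy_leadfield(6, 18, seed = 4)
  lf1 <- leakage_fid(cfg, h, max_delay = 63, tail_points = 40, seed = 9,
                     standardized = FALSE)
  lf2 <- leakage_fid(cfg, h, max_delay = 63, tail_points = 40, seed = 9,
                     standardized = FALSE)
  expect_identical(lf1$fid$matrix, lf2$fid$matrix)
  expect_equal(lf1$fid$matrix, t(lf1$fid$matrix))
  expect_equal(diag(lf1$fid$matrix), rep(0, 6))
  expect_equal(dim(lf1$table$values), c(3L, 15L))
})
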