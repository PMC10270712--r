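test_that("spearman distance matches direct rank arithmetic including ties", {
  a <- c(3, 1, 4, 1, 5)
  b <- c(2, 7, 1, 8, 2)   # ties in both vectors
  expect_equal(spearman_distance(a, b), 1 - oracle_spearman(a, b))
  expect_equal(spearman_distance(a, a), 0)
  expect_equal(spearman_distance(1:6, 6:1), 2)
  expect_error(spearman_distance(1:4, 1:5), "equal length")
  expect_error(spearman_distance(rep(2, 5), 1:5), "rank variance")
})

test_that("classify_trials produces zero distance for a self-null and 2 for rank reversal", {
  set.seed(17)
  idx <- edge_index(5)
  vals <- matrix(rnorm(3 * 10), 3)
  mk <- function(v) structure(list(values = v,
    trial_ids = data.frame(subject = 1L, epoch = 1:3), edge_index = idx,
    fs = 256, level = "edge", standardized = FALSE),
    class = "trial_decay_table")
  emp <- mk(vals)
  fid <- fid_matrix(emp, standardized = TRUE)
  cls_same <- classify_trials(emp, mk(vals), fid)
  expect_equal(cls_same$table$nonlocality, rep(0, 3), tolerance = 1e-12)
  expect_equal(max(abs(cls_same$deviation)), 0, tolerance = 1e-12)
  # deviation rows of standardized tables have ~zero mean
  cls_rev <- classify_trials(emp, mk(t(apply(vals, 1, function(r)
    -rank(r)))), fid)
  expect_equal(cls_rev$table$nonlocality, rep(2, 3), tolerance = 1e-12)
  expect_lt(max(abs(rowMeans(cls_rev$deviation))), 1e-10)
  expect_true(all(cls_rev$table$nonlocality >= 0 &
                    cls_rev$table$nonlocality <= 2))
  bad <- mk(vals[1:2, ]); bad$trial_ids <- bad$trial_ids[1:2, ]
  expect_error(classify_trials(emp, bad, fid), "misaligned")
})

test_that("deviation matrix averages trials and tracks added coupling", {
  set.seed(23)
  idx <- edge_index(4)
  mk <- function(v, n) structure(list(values = v,
    trial_ids = data.frame(subject = 1L, epoch = seq_len(n)),
    edge_index = idx, fs = 256, level = "edge", standardized = FALSE),
    class = "trial_decay_table")
  vals <- matrix(rnorm(2 * 6) + 5, 2)
  emp <- mk(vals, 2)
  cls <- classify_trials(emp, mk(vals, 2), fid_matrix(emp))
  dm <- deviation_matrix(cls)
  expect_equal(dm$matrix, matrix(0, 4, 4), tolerance = 1e-12)
  # single trial: matrix is that trial's deviation unfolded
  emp1 <- mk(vals[1, , drop = FALSE], 1)
  nul1 <- mk(vals[1, , drop = FALSE] + c(2, -1, 0, 1, -2, 0), 1)
  cls1 <- classify_trials(emp1, nul1, fid_matrix(emp1))
  dm1 <- deviation_matrix(cls1)
  expect_equal(dm1$matrix[cbind(idx[, 1], idx[, 2])], cls1$deviation[1, ])
  expect_equal(dm1$matrix, t(dm1$matrix))
  expect_equal(dm1$per_trial_mad, mean(abs(cls1$deviation[1, ])))
})

test_that("nonlocality recovers the coupling schedule on synthetic data", {
  res <- lapply(1:3, function(s) {
    ds <- generate_dataset(make_coupled_config(s))
    emp <- trial_decay_table(ds, "edge", max_delay = 63, tail_points = 40)
    nul <- null_decay_tables(ds, "regional", max_delay = 63, tail_points = 40)
    cls <- classify_trials(emp, nul, fid_matrix(emp))
    list(nl = cls$table$nonlocality, coupled = cls$table$epoch > 5)
  })
  nl <- unlist(lapply(res, `[[`, "nl"))
  cp <- unlist(lapply(res, `[[`, "coupled"))
  expect_gt(auroc(nl, cp), 0.75)
  # coupled epochs have higher median nonlocality in every seed
  for (r in res)
    expect_gt(median(r$nl[r$coupled]), median(r$nl[!r$coupled]))
})

test_that("nodal gradient analysis recovers the imposed phi gradient", {
  ds <- generate_dataset(simulation_config(n_subjects = 1,
    n_epochs_per_subject = 8, n_regions = 10,
    phi = gradient_phi(10, 0.3, 0.95), seed = 2))
  ng <- nodal_gradient_analysis(ds)
  top <- ng$order[1:3]
  for (t in top)
    expect_gt(cor(ng$nodal[t, ], 1:10, method = "spearman"), 0.9)
  # all-identical trials give similarity 1
  one <- ds$epochs[[1]]
  ng_same <- nodal_gradient_analysis(list(one, one, one),
                                     max_delay = 63, tail_points = 40)
  expect_equal(ng_same$table$similarity, rep(1, 3), tolerance = 1e-12)
})

test_that("cross-trial correlation separates standard and inverse gradients", {
  set.seed(19)
  base <- (1:12 - mean(1:12)) / sqrt(mean((1:12 - mean(1:12))^2))
  nodal <- rbind(base, base + rnorm(12, sd = 0.05), rev(base),
                 rev(base) + rnorm(12, sd = 0.05))
  ct <- cross_trial_correlation(nodal, extreme_fraction = 0.26)
  expect_equal(diag(ct$matrix), rep(1, 4))
  expect_equal(ct$matrix, t(ct$matrix))
  expect_gt(ct$matrix[1, 2], 0.9)
  expect_lt(ct$matrix[1, 3], -0.9)
  expect_equal(ct$labels[1], "standard")
  expect_equal(ct$labels[3], "inverse")
  # identical pair and exact reversal
  two <- cross_trial_correlation(rbind(base, base))
  expect_equal(two$matrix, matrix(1, 2, 2))
  expect_warning(rev2 <- cross_trial_correlation(rbind(base, rev(base))),
                 "degenerate average")
  expect_equal(rev2$matrix[1, 2], -1)
  # matches a pairwise spearman oracle
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(ct$matrix[i, j], oracle_spearman(nodal[i, ], nodal[j, ]),
                 tolerance = 1e-12)
})

test_that("nonlocality-gradient association detects the planted relationship", {
  set.seed(29)
  idx <- edge_index(5)
  n_tr <- 12
  vals <- matrix(rnorm(n_tr * 10), n_tr)
  mk <- function(v) structure(list(values = v,
    trial_ids = data.frame(subject = 1L, epoch = seq_len(n_tr)),
    edge_index = idx, fs = 256, level = "edge", standardized = FALSE),
    class = "trial_decay_table")
  emp <- mk(vals)
  nul <- mk(vals + matrix(rnorm(n_tr * 10, sd = rep(seq(0.1, 3, length.out = n_tr), 10)), n_tr))
  nodal <- list(table = data.frame(subject = 1L, epoch = seq_len(n_tr),
                                   similarity = seq(0.9, -0.9, length.out = n_tr)))
  cls <- classify_trials(emp, nul, fid_matrix(emp), nodal = nodal)
  # identical vectors give rho 1
  cls1 <- cls
  cls1$table$gradient_similarity <- 1 - cls1$table$nonlocality
  a1 <- nonlocality_gradient_association(cls1, n_perm = 500, seed = 3)
  expect_equal(a1$rho, 1)
  expect_lt(a1$p_value, 0.01)
  # independent vectors: small |rho|, non-significant
  cls2 <- cls
  set.seed(31)
  cls2$table$gradient_similarity <- rnorm(n_tr)
  a2 <- nonlocality_gradient_association(cls2, n_perm = 500, seed = 3)
  expect_lt(abs(a2$rho), 0.9)
  expect_gt(a2$p_value, 0.001)
})
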