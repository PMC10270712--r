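# Trial classification along the local-to-nonlocal axis, deviation
# matrices, nodal timescale gradients and cross-trial similarity structure.
#
# All comparisons are rank-based: distances are 1 minus the Spearman
# correlation (range [0, 2]), so every quantity here is invariant under
# strictly monotone transforms of the decay times.

#' Spearman distance between two vectors
#'
#' `1 - Spearman rank correlation`, with average-rank tie handling.
#' 0 for identically ranked vectors, 2 for perfectly anti-ranked ones.
#'
#' @param a,b equal-length numeric vectors (length >= 3).
#' @return distance in \[0, 2\].
#' @export
spearman_distance <- function(a, b) {
  if (length(a) != length(b)) stop_data("vectors must have equal length")
  if (length(a) < 3L) stop_data("need at least 3 values")
  if (sd(rank(a)) == 0 || sd(rank(b)) == 0)
    stop_data("zero rank variance: Spearman correlation undefined")
  1 - cor(a, b, method = "spearman")
}

#' Classify trials by their distance from a null model
#'
#' Per trial: `nonlocality` = 1 - Spearman correlation between the
#' empirical and null standardized edge decays (a trial far from its
#' purely local prediction has prominent nonlocal features);
#' `distance_from_fid` = 1 - Spearman correlation with the trial-averaged
#' FID pattern; `deviation` = null minus empirical standardized decays
#' (flip with `deviation_sign = -1`). Optionally attaches the nodal
#' gradient similarity and standard/inverse/intermediate labels from
#' [nodal_gradient_analysis()].
#'
#' @param empirical,null edge-level [trial_decay_table()]s with aligned
#'   trials and edges (standardized within trial; raw tables are
#'   standardized automatically).
#' @param fid a [fid_matrix()] (trial-averaged empirical FID).
#' @param nodal optional result of [nodal_gradient_analysis()] on the same
#'   trials.
#' @param deviation_sign +1 for null - empirical (default), -1 to flip.
#' @param extreme_fraction cutoff for standard/inverse labels
#'   (default 0.10).
#' @return object of class `trial_classification`: list with `table`
#'   (data.frame subject, epoch, nonlocality, distance_from_fid,
#'   gradient_similarity, label), `deviation` (trials x edges),
#'   `edge_index`, `order` (trials sorted local to nonlocal).
#' @export
classify_trials <- function(empirical, null, fid, nodal = NULL,
                            deviation_sign = 1, extreme_fraction = 0.10) {
  stopifnot(inherits(empirical, "trial_decay_table"),
            inherits(null, "trial_decay_table"),
            inherits(fid, "fid_matrix"))
  if (!identical(dim(empirical$values), dim(null$values)))
    stop_data("empirical and null tables are misaligned (different dimensions)")
  if (!identical(empirical$trial_ids, null$trial_ids))
    stop_data("empirical and null tables are misaligned (different trials)")
  empirical <- standardize_within_trial(empirical)
  null <- standardize_within_trial(null)
  idx <- empirical$edge_index
  fid_vec <- fid$matrix[cbind(idx[, 1], idx[, 2])]
  n_trial <- nrow(empirical$values)
  nonlocality <- distance_fid <- numeric(n_trial)
  for (t in seq_len(n_trial)) {
    nonlocality[t] <- spearman_distance(empirical$values[t, ], null$values[t, ])
    distance_fid[t] <- spearman_distance(empirical$values[t, ], fid_vec)
  }
  deviation <- deviation_sign * (null$values - empirical$values)
  tab <- data.frame(subject = empirical$trial_ids$subject,
                    epoch = empirical$trial_ids$epoch,
                    nonlocality = nonlocality,
                    distance_from_fid = distance_fid,
                    gradient_similarity = NA_real_,
                    label = NA_character_)
  if (!is.null(nodal)) {
    if (nrow(nodal$table) != n_trial) stop_data("nodal analysis trial count mismatch")
    tab$gradient_similarity <- nodal$table$similarity
    tab$label <- label_by_similarity(tab$gradient_similarity, extreme_fraction)
  }
  structure(list(table = tab, deviation = deviation, edge_index = idx,
                 order = order(nonlocality), deviation_sign = deviation_sign),
            class = "trial_classification")
}

label_by_similarity <- function(sim, extreme_fraction) {
  lo <- stats::quantile(sim, extreme_fraction, names = FALSE)
  hi <- stats::quantile(sim, 1 - extreme_fraction, names = FALSE)
  ifelse(sim >= hi, "standard", ifelse(sim <= lo, "inverse", "intermediate"))
}

#' Trial-averaged deviation matrix
#'
#' Mean over trials of the per-edge deviation (null minus empirical
#' standardized decays), unfolded to a symmetric region x region matrix;
#' also the per-trial mean absolute deviation, which grows as nonlocal
#' interactions become prominent.
#'
#' @param classification a [classify_trials()] result.
#' @return list with `matrix` (N x N), `per_trial_mad` (mean |deviation|
#'   per trial).
#' @export
deviation_matrix <- function(classification) {
  stopifnot(inherits(classification, "trial_classification"))
  idx <- classification$edge_index
  mean_dev <- colMeans(classification$deviation)
  list(matrix = unfold_edges(mean_dev, idx, max(idx)),
       per_trial_mad = rowMeans(abs(classification$deviation)))
}

#' Nodal timescale gradient analysis
#'
#' Estimates nodal decay times per trial with the same AMI estimator used
#' for edges, standardizes them across nodes within each trial, and
#' measures each trial's Spearman similarity to the trial-average nodal
#' pattern. Trials with high similarity express the dataset's standard
#' gradient of timescales; strongly negative similarity marks
#' inverse-gradient trials.
#'
#' @param dataset an `epoch_set` or list of [epoched_ts()].
#' @param max_delay,bins,tail_points,k_sd,sd_mode AMI parameters.
#' @return list with `nodal` (trials x regions standardized decays),
#'   `average_gradient` (per-region mean pattern), `table` (data.frame
#'   subject, epoch, similarity), `order` (trials sorted by decreasing
#'   similarity).
#' @export
nodal_gradient_analysis <- function(dataset, max_delay = 127L, bins = 64L,
                                    tail_points = 80L, k_sd = 1,
                                    sd_mode = c("residual", "raw")) {
  sd_mode <- match.arg(sd_mode)
  tab <- trial_decay_table(dataset, level = "node", max_delay = max_delay,
                           bins = bins, tail_points = tail_points,
                           k_sd = k_sd, sd_mode = sd_mode)
  tab <- standardize_within_trial(tab)
  avg <- colMeans(tab$values)
  sim <- apply(tab$values, 1L, function(v) cor(v, avg, method = "spearman"))
  list(nodal = tab$values, average_gradient = avg,
       table = data.frame(subject = tab$trial_ids$subject,
                          epoch = tab$trial_ids$epoch, similarity = sim),
       order = order(sim, decreasing = TRUE))
}

#' Cross-trial correlation matrix of nodal decay patterns
#'
#' Spearman correlation between the standardized nodal decay vectors of
#' every pair of trials, plus standard/inverse/intermediate labels from
#' the extreme fractions of the gradient similarity. Standard- and
#' inverse-gradient trials appear as two anticorrelated blocks.
#'
#' @param nodal_decays trials x regions matrix of standardized nodal
#'   decays (e.g. `nodal_gradient_analysis(...)$nodal`).
#' @param gradient_similarity optional per-trial similarity used for
#'   labels; computed from the trial average if missing.
#' @param extreme_fraction label cutoff (default 0.10).
#' @return list with `matrix` (trials x trials, unit diagonal) and
#'   `labels`.
#' @export
cross_trial_correlation <- function(nodal_decays, gradient_similarity = NULL,
                                    extreme_fraction = 0.10) {
  nodal_decays <- as.matrix(nodal_decays)
  if (nrow(nodal_decays) < 2L) stop_data("need at least 2 trials")
  m <- cor(t(nodal_decays), method = "spearman")
  diag(m) <- 1
  dimnames(m) <- NULL
  if (is.null(gradient_similarity)) {
    avg <- colMeans(nodal_decays)
    gradient_similarity <- apply(nodal_decays, 1L, function(v)
      suppressWarnings(cor(v, avg, method = "spearman")))
  }
  labels <- if (any(!is.finite(gradient_similarity))) {
    warning("gradient similarity undefined (degenerate average pattern); labels set to NA")
    rep(NA_character_, nrow(nodal_decays))
  } else {
    unname(label_by_similarity(unname(gradient_similarity), extreme_fraction))
  }
  list(matrix = m, labels = labels)
}

#' Association between nonlocality and nodal-gradient distance
#'
#' Spearman rank correlation between the per-trial nonlocality score (edge
#' analysis) and the distance from the average nodal gradient
#' (1 - gradient similarity), with a two-sided permutation p-value.
#'
#' @param classification a [classify_trials()] result carrying
#'   `gradient_similarity`.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return list with `rho`, `p_value`, `n_perm`.
#' @export
nonlocality_gradient_association <- function(classification, n_perm = 10000L,
                                             seed = 1L) {
  stopifnot(inherits(classification, "trial_classification"))
  tab <- classification$table
  if (any(is.na(tab$gradient_similarity)))
    stop_data("classification lacks gradient_similarity; pass nodal analysis to classify_trials")
  x <- tab$nonlocality
  y <- 1 - tab$gradient_similarity
  rho <- cor(x, y, method = "spearman")
  set.seed(seed)
  perm <- replicate(n_perm, cor(x, sample(y), method = "spearman"))
  p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p_value = p, n_perm = n_perm)
}
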