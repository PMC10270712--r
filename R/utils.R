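# Internal helpers shared across modules.

stop_config <- function(...) {
  stop(structure(class = c("edgefid_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("edgefid_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
    stop_config(name, " must be a single positive integer")
  as.integer(x)
}

#' Area under the ROC curve for a score discriminating two classes
#'
#' Rank-based (Mann-Whitney) AUROC of `score` for predicting `label == TRUE`.
#' Used to quantify how well the per-trial nonlocality score separates
#' coupled from uncoupled epochs in simulations.
#'
#' @param score numeric vector of scores (higher = more likely positive).
#' @param label logical (or 0/1) vector of true classes, same length.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(score, label) {
  label <- as.logical(label)
  if (length(score) != length(label)) stop_data("score and label lengths differ")
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) stop_data("both classes must be present")
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Population (1/T) standard deviation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Strict upper-triangle vectorization in lexicographic (i, j), i < j order;
# matches the row order of edge_index().
upper_tri_vec <- function(m) t(m)[lower.tri(t(m))]

# Fold an edge vector (lexicographic i < j) back into a symmetric matrix
# with zero diagonal.
unfold_edges <- function(v, edge_index, n_regions) {
  m <- matrix(0, n_regions, n_regions)
  m[cbind(edge_index[, 1], edge_index[, 2])] <- v
  m[cbind(edge_index[, 2], edge_index[, 1])] <- v
  m
}
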