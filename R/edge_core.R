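# Edge co-activation signals: z-scored nodal signals and their pairwise
# element-wise products. The time average of each edge series equals the
# Pearson correlation of the two regional signals (with 1/T normalization),
# which is why the z-score uses the population standard deviation.

#' Construct an epoched time-series object
#'
#' One trial's worth of source-level data: a regions x samples real matrix
#' plus sampling metadata. This is the unit of analysis for everything
#' downstream (edge construction, AMI decay estimation, surrogates).
#'
#' @param data numeric matrix, regions x samples.
#' @param fs sampling frequency in Hz.
#' @param subject_id,epoch_id identifiers carried through to output tables.
#' @param region_labels optional character vector of region names.
#' @return An object of class `epoched_ts`.
#' @export
epoched_ts <- function(data, fs, subject_id = 1L, epoch_id = 1L,
                       region_labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data)))
    stop_data("epoch data must be a finite numeric matrix")
  if (nrow(data) < 2L) stop_data("an epoch needs at least 2 regions")
  if (ncol(data) < 2L) stop_data("an epoch needs at least 2 samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_config("fs must be a single positive number")
  if (is.null(region_labels))
    region_labels <- paste0("R", seq_len(nrow(data)))
  if (length(region_labels) != nrow(data))
    stop_data("region_labels length must match the number of regions")
  structure(list(data = data, fs = fs, subject_id = subject_id,
                 epoch_id = epoch_id, region_labels = region_labels),
            class = "epoched_ts")
}

#' @export
print.epoched_ts <- function(x, ...) {
  cat(sprintf("<epoched_ts> subject %s, epoch %s: %d regions x %d samples @ %g Hz\n",
              x$subject_id, x$epoch_id, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Z-score a signal with population normalization
#'
#' Centers and scales to mean 0 and population (1/T) standard deviation 1.
#' The 1/T convention makes the time average of a product of two z-scored
#' signals exactly their Pearson correlation.
#'
#' @param x numeric vector.
#' @return z-scored vector.
#' @export
zscore <- function(x) {
  s <- pop_sd(x)
  if (s == 0) stop_data("degenerate signal: zero variance, cannot z-score")
  (x - mean(x)) / s
}

#' Lexicographic edge index for N regions
#'
#' All unordered region pairs (i, j) with i < j, in lexicographic order.
#' This row order is shared by every edge-indexed object in the package.
#'
#' @param n_regions number of regions N.
#' @return integer matrix with N(N-1)/2 rows and columns `i`, `j` (1-based).
#' @export
edge_index <- function(n_regions) {
  n_regions <- check_scalar_count(n_regions, "n_regions")
  if (n_regions < 2L) stop_config("need at least 2 regions for edges")
  idx <- t(combn(n_regions, 2L))
  colnames(idx) <- c("i", "j")
  idx
}

#' Row position of an edge in the lexicographic edge order
#'
#' Symmetric lookup: `edge_lookup(idx, i, j)` equals `edge_lookup(idx, j, i)`.
#'
#' @param edge_index matrix from [edge_index()].
#' @param i,j region indices (1-based), `i != j`.
#' @return integer row position.
#' @export
edge_lookup <- function(edge_index, i, j) {
  if (i == j) stop_data("no self-edges: i must differ from j")
  lo <- min(i, j); hi <- max(i, j)
  pos <- which(edge_index[, 1] == lo & edge_index[, 2] == hi)
  if (length(pos) != 1L) stop_data("edge (", i, ",", j, ") not in index")
  pos
}

#' Edge co-activation time series for all region pairs
#'
#' For every pair i < j, the edge signal is the element-wise product of the
#' two z-scored regional signals, E_ij(t) = z(X_i)(t) * z(X_j)(t). Its time
#' mean is the pairwise Pearson correlation, so the edge series can be read
#' as the unfolding in time of static functional connectivity.
#'
#' @param epoch an [epoched_ts()].
#' @return An object of class `edge_ts`: list with `data`
#'   (N(N-1)/2 x samples), `edge_index`, `fs`, `subject_id`, `epoch_id`.
#' @export
edge_time_series <- function(epoch) {
  stopifnot(inherits(epoch, "epoched_ts"))
  x <- epoch$data
  sds <- apply(x, 1L, pop_sd)
  bad <- which(sds == 0)
  if (length(bad))
    stop_data("degenerate signal: region ", bad[1L], " is constant in epoch ",
              epoch$epoch_id, " (subject ", epoch$subject_id, ")")
  z <- (x - rowMeans(x)) / sds
  idx <- edge_index(nrow(x))
  e <- z[idx[, 1L], , drop = FALSE] * z[idx[, 2L], , drop = FALSE]
  structure(list(data = e, edge_index = idx, fs = epoch$fs,
                 subject_id = epoch$subject_id, epoch_id = epoch$epoch_id),
            class = "edge_ts")
}

#' @export
print.edge_ts <- function(x, ...) {
  cat(sprintf("<edge_ts> subject %s, epoch %s: %d edges x %d samples @ %g Hz\n",
              x$subject_id, x$epoch_id, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}
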