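# Trial decay tables and the functional information decay (FID) matrix:
# per-trial edge decay times, standardized across edges within each trial,
# averaged across trials into a region x region matrix, plus extraction of
# the short- and long-storage subnetworks from its tails.

#' Trial-by-edge (or trial-by-node) decay table for a dataset
#'
#' Runs the edge construction and AMI decay estimation for every epoch of a
#' dataset and collects tau* into a trials x edges (or trials x regions)
#' matrix aligned with the lexicographic edge index.
#'
#' @param dataset an `epoch_set` (or plain list of [epoched_ts()]).
#' @param level `"edge"` (decays of edge co-activation signals, default) or
#'   `"node"` (decays of the regional signals themselves).
#' @param max_delay,bins,tail_points,k_sd,sd_mode AMI parameters, see
#'   [batch_decay()].
#' @return object of class `trial_decay_table`: list with `values`
#'   (trials x columns matrix of tau* in samples), `trial_ids` (data.frame
#'   subject/epoch), `edge_index` (NULL at node level), `fs`, `level`,
#'   `standardized` (FALSE).
#' @export
trial_decay_table <- function(dataset, level = c("edge", "node"),
                              max_delay = 127L, bins = 64L,
                              tail_points = 80L, k_sd = 1,
                              sd_mode = c("residual", "raw")) {
  level <- match.arg(level)
  sd_mode <- match.arg(sd_mode)
  epochs <- if (inherits(dataset, "epoch_set")) dataset$epochs else dataset
  stopifnot(length(epochs) >= 1L, inherits(epochs[[1L]], "epoched_ts"))
  fs <- epochs[[1L]]$fs
  idx <- if (level == "edge") edge_index(nrow(epochs[[1L]]$data)) else NULL
  rows <- lapply(epochs, function(ep) {
    m <- if (level == "edge") edge_time_series(ep)$data else ep$data
    batch_decay(m, max_delay, bins, tail_points, k_sd, fs, sd_mode)$tau_star
  })
  values <- do.call(rbind, rows)
  trial_ids <- data.frame(
    subject = vapply(epochs, function(e) as.integer(e$subject_id), integer(1)),
    epoch = vapply(epochs, function(e) as.integer(e$epoch_id), integer(1)))
  structure(list(values = values, trial_ids = trial_ids, edge_index = idx,
                 fs = fs, level = level, standardized = FALSE),
            class = "trial_decay_table")
}

#' @export
print.trial_decay_table <- function(x, ...) {
  cat(sprintf("<trial_decay_table> %d trials x %d %ss%s\n", nrow(x$values),
              ncol(x$values), x$level,
              if (x$standardized) " (standardized within trial)" else ""))
  invisible(x)
}

#' Standardize decay times across edges within each trial
#'
#' Each trial (row) is z-scored across its edges: mean 0, population (1/n)
#' SD 1. This is the
#' standardization used before averaging trials into the FID matrix, so
#' that trials with globally slow or fast decays contribute their pattern,
#' not their offset.
#'
#' @param table a [trial_decay_table()].
#' @return the table with standardized `values` and `standardized = TRUE`.
#' @export
standardize_within_trial <- function(table) {
  stopifnot(inherits(table, "trial_decay_table"))
  if (table$standardized) return(table)
  v <- table$values
  if (ncol(v) < 2L) stop_data("need at least 2 columns per trial to standardize")
  for (r in seq_len(nrow(v))) {
    s <- pop_sd(v[r, ])
    if (is.na(s) || s == 0)
      stop_data("zero spread in trial ", r, " (subject ",
                table$trial_ids$subject[r], ", epoch ",
                table$trial_ids$epoch[r], "): cannot standardize")
    v[r, ] <- (v[r, ] - mean(v[r, ])) / s
  }
  table$values <- v
  table$standardized <- TRUE
  table
}

#' Trial-averaged FID matrix
#'
#' Element (i, j) is the mean over trials of the (optionally standardized)
#' decay time of edge (i, j); symmetric by construction with zero diagonal.
#'
#' @param table an edge-level [trial_decay_table()].
#' @param standardized standardize within trial before averaging (default
#'   TRUE, the canonical pipeline); FALSE averages raw tau* and reports ms.
#' @return object of class `fid_matrix`: list with `matrix` (N x N),
#'   `units` (`"z"` or `"ms"`), `edge_index`, `fs`.
#' @export
fid_matrix <- function(table, standardized = TRUE) {
  stopifnot(inherits(table, "trial_decay_table"))
  if (table$level != "edge") stop_data("fid_matrix needs an edge-level table")
  idx <- table$edge_index
  n <- max(idx)
  if (ncol(table$values) != nrow(idx)) stop_data("table/edge_index mismatch")
  if (standardized) {
    table <- standardize_within_trial(table)
    vals <- colMeans(table$values)
    units <- "z"
  } else {
    vals <- colMeans(table$values) * 1000 / table$fs
    units <- "ms"
  }
  structure(list(matrix = unfold_edges(vals, idx, n), units = units,
                 edge_index = idx, fs = table$fs),
            class = "fid_matrix")
}

#' @export
print.fid_matrix <- function(x, ...) {
  cat(sprintf("<fid_matrix> %d x %d regions, units: %s\n",
              nrow(x$matrix), ncol(x$matrix), x$units))
  invisible(x)
}

#' Short- and long-storage subnetworks from the FID tails
#'
#' SSN: edges at or below the `tail_fraction` quantile of FID values
#' (fastest information loss); LSN: edges at or above the
#' `1 - tail_fraction` quantile (slowest). Ties straddling a cutoff are
#' all included and the realized fractions are reported.
#'
#' @param fid a [fid_matrix()].
#' @param tail_fraction proportion in (0, 0.5], default 0.10.
#' @return list with `ssn` and `lsn` (data.frames i, j, value),
#'   `ssn_fraction`, `lsn_fraction`.
#' @export
extract_subnetworks <- function(fid, tail_fraction = 0.10) {
  stopifnot(inherits(fid, "fid_matrix"))
  if (!(tail_fraction > 0 && tail_fraction <= 0.5))
    stop_config("tail_fraction must be in (0, 0.5]")
  idx <- fid$edge_index
  vals <- fid$matrix[cbind(idx[, 1], idx[, 2])]
  lo <- stats::quantile(vals, tail_fraction, names = FALSE)
  hi <- stats::quantile(vals, 1 - tail_fraction, names = FALSE)
  ssn <- vals <= lo
  lsn <- vals >= hi
  if (all(ssn & lsn)) {  # fully degenerate (all values equal)
    warning("all FID values tied: subnetworks are empty")
    ssn[] <- FALSE; lsn[] <- FALSE
  }
  mk <- function(sel) data.frame(i = idx[sel, 1], j = idx[sel, 2],
                                 value = vals[sel])
  list(ssn = mk(ssn), lsn = mk(lsn),
       ssn_fraction = mean(ssn), lsn_fraction = mean(lsn))
}

#' Summary of decay-time distributions in milliseconds
#'
#' Reports the single-trial range and the trial-averaged (per-edge mean)
#' range of decay times, converted at 1000/fs ms per sample.
#'
#' @param table a raw (unstandardized) [trial_decay_table()].
#' @param fs sampling frequency; defaults to the table's.
#' @return list with `trial_level` and `edge_average` (each min/max/mean in
#'   ms) and `ms_per_step`.
#' @export
decay_distribution <- function(table, fs = NULL) {
  stopifnot(inherits(table, "trial_decay_table"))
  if (table$standardized)
    stop_data("decay_distribution needs raw (unstandardized) decay times")
  if (is.null(fs)) fs <- table$fs
  step <- 1000 / fs
  v_ms <- table$values * step
  per_edge <- colMeans(v_ms)
  list(trial_level = list(min = min(v_ms), max = max(v_ms), mean = mean(v_ms)),
       edge_average = list(min = min(per_edge), max = max(per_edge),
                           mean = mean(per_edge)),
       ms_per_step = step)
}
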