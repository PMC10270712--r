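# Auto-mutual information (AMI) profiles and the tail-fit decay-time rule.
#
# MI is the histogram plug-in estimate in bits from an equal-width
# contingency table (64 x 64 by default). The AMI profile of a signal is
# MI between the signal and its tau-delayed copy for tau = 0..max_delay;
# the decay time tau* is the first delay at which the profile falls within
# k standard deviations of the stable minimum, the latter estimated by a
# straight-line fit to the profile's tail.

#' Joint contingency table of two signals
#'
#' Equal-width binning over each variable's own observed range; bin index
#' `floor((v - min) * bins / (max - min))`, top edge inclusive. Marginals of
#' the joint table equal the univariate histograms by construction.
#'
#' @param x,y equal-length numeric vectors.
#' @param bins number of bins per axis (default 64).
#' @return list with `counts` (bins x bins, rows = y, cols = x), `bins`,
#'   `edges_x`, `edges_y`.
#' @export
contingency_table <- function(x, y, bins = 64L) {
  if (length(x) != length(y)) stop_data("x and y must have equal length")
  bins <- check_scalar_count(bins, "bins")
  if (length(x) < bins)
    stop_data("need at least as many samples (", length(x), ") as bins (", bins, ")")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_data("non-finite values")
  bin_of <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi == lo) return(rep(1L, length(v)))
    pmin(as.integer((v - lo) * (bins / (hi - lo))), bins - 1L) + 1L
  }
  ix <- bin_of(x); iy <- bin_of(y)
  counts <- matrix(tabulate((iy - 1L) * bins + ix, nbins = bins * bins),
                   nrow = bins, byrow = TRUE)
  edges <- function(v) min(v) + (0:bins) * ((max(v) - min(v)) / bins)
  list(counts = counts, bins = bins, edges_x = edges(x), edges_y = edges(y))
}

#' Histogram plug-in mutual information in bits
#'
#' MI(X;Y) = H(X) + H(Y) - H(X,Y), with entropies computed from the
#' equal-width [contingency_table()]. Empty cells contribute zero
#' (0 log 0 = 0). Constant input yields MI = 0 with a degeneracy warning.
#'
#' @inheritParams contingency_table
#' @return mutual information in bits (non-negative up to rounding).
#' @export
histogram_mi <- function(x, y, bins = 64L) {
  if (length(x) != length(y)) stop_data("x and y must have equal length")
  if (min(x) == max(x) || min(y) == max(y)) {
    warning("degenerate (constant) input: MI set to 0")
    return(0)
  }
  ct <- contingency_table(x, y, bins)
  p <- ct$counts / sum(ct$counts)
  ent <- function(pr) { pr <- pr[pr > 0]; -sum(pr * log2(pr)) }
  ent(rowSums(p)) + ent(colSums(p)) - ent(p)
}

#' AMI profile of a signal
#'
#' `values[tau + 1] = histogram_mi(x[(tau+1):T], x[1:(T-tau)])` for
#' tau = 0..max_delay. The zero-delay value is the binned entropy of the
#' signal and is the profile's maximum.
#'
#' @param x numeric vector (one edge or nodal signal).
#' @param max_delay maximum delay in samples (default 127, i.e. 128 delays).
#' @param bins histogram bins (default 64).
#' @param fs sampling frequency in Hz (metadata for ms conversion).
#' @return object of class `ami_profile`: list with `values` (bits),
#'   `delays` (0..max_delay, samples), `fs`.
#' @export
ami_profile <- function(x, max_delay = 127L, bins = 64L, fs = 256) {
  max_delay <- check_scalar_count(max_delay, "max_delay")
  min_len <- max(max_delay + bins, max_delay + 2L)
  if (length(x) < min_len)
    stop_data("signal too short: length ", length(x),
              " but at least ", min_len, " samples are needed for max_delay = ",
              max_delay, " with ", bins, " bins")
  v <- drop(cpp_ami_profiles(matrix(x, nrow = 1L), max_delay, as.integer(bins)))
  structure(list(values = v, delays = 0:max_delay, fs = fs),
            class = "ami_profile")
}

#' Decay time of an AMI profile (tail-fit stopping rule)
#'
#' Fits a straight line by least squares to the last `tail_points` values of
#' the profile. The stable minimum is the mean fitted tail level; the
#' threshold is that level plus `k_sd` standard deviations of the tail
#' (residuals about the fit by default). tau* is the smallest delay >= 1
#' whose AMI value falls at or below the threshold; if no delay crosses,
#' tau* = max_delay and the result is flagged.
#'
#' @param profile an [ami_profile()].
#' @param tail_points number of trailing profile points in the fit
#'   (default 80 of 128).
#' @param k_sd threshold width in standard deviations (default 1).
#' @param sd_mode `"residual"` (SD of residuals about the fitted line,
#'   default) or `"raw"` (SD of the raw tail values).
#' @return object of class `decay_time`: list with `tau_star` (samples),
#'   `tau_star_ms`, `stable_min`, `threshold` (bits), `flagged`.
#' @export
decay_time <- function(profile, tail_points = 80L, k_sd = 1,
                       sd_mode = c("residual", "raw")) {
  stopifnot(inherits(profile, "ami_profile"))
  sd_mode <- match.arg(sd_mode)
  v <- profile$values
  L <- length(v)
  tail_points <- check_scalar_count(tail_points, "tail_points")
  if (tail_points >= L)
    stop_data("tail_points (", tail_points, ") must be smaller than the profile length (", L, ")")
  if (tail_points < 2L) stop_data("tail_points must be at least 2")
  ti <- (L - tail_points + 1L):L
  tx <- profile$delays[ti]
  ty <- v[ti]
  # closed-form simple least squares
  mx <- mean(tx); my <- mean(ty)
  slope <- sum((tx - mx) * (ty - my)) / sum((tx - mx)^2)
  fitted <- my + slope * (tx - mx)
  stable_min <- mean(fitted)
  s <- if (sd_mode == "residual") sd(ty - fitted) else sd(ty)
  if (is.na(s)) s <- 0
  threshold <- stable_min + k_sd * s
  cross <- which(v[-1L] <= threshold)
  if (length(cross)) {
    tau_star <- profile$delays[cross[1L] + 1L]
    flagged <- FALSE
  } else {
    tau_star <- profile$delays[L]
    flagged <- TRUE
  }
  structure(list(tau_star = tau_star,
                 tau_star_ms = tau_star * 1000 / profile$fs,
                 stable_min = stable_min, threshold = threshold,
                 flagged = flagged),
            class = "decay_time")
}

#' @export
print.decay_time <- function(x, ...) {
  cat(sprintf("<decay_time> tau* = %d samples (%.4g ms)%s\n", x$tau_star,
              x$tau_star_ms, if (x$flagged) " [no crossing: flagged]" else ""))
  invisible(x)
}

#' Decay times for every row of a signals matrix
#'
#' Applies [ami_profile()] + [decay_time()] independently to each row
#' (edges or nodes), order-preserving. The profiles are computed in
#' compiled code; results are identical to looping single calls.
#'
#' @param series numeric matrix, rows x samples.
#' @param max_delay,bins,tail_points,k_sd,sd_mode see [ami_profile()] and
#'   [decay_time()].
#' @param fs sampling frequency in Hz.
#' @return data.frame with one row per input row: `row`, `tau_star`,
#'   `tau_star_ms`, `stable_min`, `threshold`, `flagged`.
#' @export
batch_decay <- function(series, max_delay = 127L, bins = 64L,
                        tail_points = 80L, k_sd = 1, fs = 256,
                        sd_mode = c("residual", "raw")) {
  series <- as.matrix(series)
  if (nrow(series) < 1L) stop_data("series must have at least one row")
  sd_mode <- match.arg(sd_mode)
  max_delay <- check_scalar_count(max_delay, "max_delay")
  min_len <- max(max_delay + bins, max_delay + 2L)
  if (ncol(series) < min_len)
    stop_data("signals too short: ", ncol(series), " samples but at least ",
              min_len, " are needed")
  profiles <- cpp_ami_profiles(series, max_delay, as.integer(bins))
  out <- vector("list", nrow(series))
  for (r in seq_len(nrow(series))) {
    p <- structure(list(values = profiles[r, ], delays = 0:max_delay, fs = fs),
                   class = "ami_profile")
    d <- tryCatch(decay_time(p, tail_points, k_sd, sd_mode),
                  error = function(e)
                    stop_data("row ", r, ": ", conditionMessage(e)))
    out[[r]] <- data.frame(row = r, tau_star = d$tau_star,
                           tau_star_ms = d$tau_star_ms,
                           stable_min = d$stable_min,
                           threshold = d$threshold, flagged = d$flagged)
  }
  do.call(rbind, out)
}
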