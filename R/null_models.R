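# Null models isolating nonlocal dynamics.
#
# Gaussian surrogates impose each region's amplitude spectrum on
# independent white noise (nodal spectra preserved, all cross-region
# structure destroyed). Phase-randomized surrogates rotate every positive
# frequency of every region by one shared random phase (nodal spectra AND
# the static correlation matrix preserved, lagged dynamics destroyed).
# The regional null replaces each edge decay by the geometric mean of the
# two nodal decays, i.e. the best purely local prediction.

#' Spectrally matched Gaussian surrogate of an epoch
#'
#' Per region independently: draw white Gaussian noise, take its Fourier
#' phases, impose the parent region's amplitude spectrum, and invert. The
#' surrogate regions are mutually independent Gaussian processes with the
#' parent's per-region power spectra.
#'
#' @param epoch an [epoched_ts()].
#' @param seed RNG seed.
#' @return object of class `surrogate_epoch` (an `epoched_ts` with
#'   `kind = "gaussian"` and `parent` trial ids).
#' @export
gaussian_surrogate <- function(epoch, seed = 1L) {
  stopifnot(inherits(epoch, "epoched_ts"))
  x <- epoch$data
  T <- ncol(x)
  if (T < 4L) stop_data("need at least 4 samples")
  set.seed(seed)
  out <- x
  for (r in seq_len(nrow(x))) {
    amp <- Mod(fft(x[r, ]))
    ph <- Arg(fft(rnorm(T)))          # Hermitian phases of a real draw
    out[r, ] <- Re(fft(amp * exp(1i * ph), inverse = TRUE)) / T
  }
  sur <- epoched_ts(out, epoch$fs, epoch$subject_id, epoch$epoch_id,
                    epoch$region_labels)
  sur$kind <- "gaussian"
  sur$seed <- seed
  class(sur) <- c("surrogate_epoch", class(sur))
  sur
}

#' Phase-randomized surrogate preserving static correlations
#'
#' One random phase per positive frequency, drawn uniform on \[0, 2pi),
#' applied identically to every region and conjugate-mirrored for negative
#' frequencies (DC and Nyquist bins left untouched). Because every region
#' is rotated by the same phase at each frequency, all cross-spectra — and
#' hence the static Pearson correlation matrix — are preserved exactly,
#' while the time-resolved dynamics are destroyed.
#'
#' @param epoch an [epoched_ts()].
#' @param seed RNG seed (ignored when `phases` is given).
#' @param phases optional vector of phases (radians) for the positive
#'   frequencies, mainly for testing; all-zero phases reproduce the parent.
#' @return object of class `surrogate_epoch` with `kind = "phase"`.
#' @export
phase_surrogate <- function(epoch, seed = 1L, phases = NULL) {
  stopifnot(inherits(epoch, "epoched_ts"))
  x <- epoch$data
  T <- ncol(x)
  if (T < 4L) stop_data("need at least 4 samples")
  n_pos <- (T - 1L) %/% 2L          # strictly positive, non-Nyquist bins
  if (is.null(phases)) {
    set.seed(seed)
    phases <- runif(n_pos, 0, 2 * pi)
  }
  if (length(phases) != n_pos)
    stop_data("phases must have length ", n_pos)
  rot <- rep(1 + 0i, T)
  rot[1L + seq_len(n_pos)] <- exp(1i * phases)
  rot[T + 1L - seq_len(n_pos)] <- Conj(rot[1L + seq_len(n_pos)])
  out <- x
  for (r in seq_len(nrow(x)))
    out[r, ] <- Re(fft(fft(x[r, ]) * rot, inverse = TRUE)) / T
  sur <- epoched_ts(out, epoch$fs, epoch$subject_id, epoch$epoch_id,
                    epoch$region_labels)
  sur$kind <- "phase"
  sur$seed <- seed
  class(sur) <- c("surrogate_epoch", class(sur))
  sur
}

#' Regional (geometric-mean) null FID
#'
#' The purely local prediction for each edge decay: tau_ij =
#' sqrt(tau_i * tau_j) from the nodal decay times alone. Entries lie
#' between the smallest and largest nodal tau; the diagonal equals the
#' nodal values themselves.
#'
#' @param nodal_taus positive per-region decay times (samples or ms).
#' @return object of class `regional_null_fid`: list with `matrix`
#'   (N x N) and `nodal_taus`.
#' @export
regional_null_fid <- function(nodal_taus) {
  if (any(!is.finite(nodal_taus)) || any(nodal_taus <= 0))
    stop_data("all nodal decay times must be positive and finite")
  structure(list(matrix = sqrt(outer(nodal_taus, nodal_taus)),
                 nodal_taus = nodal_taus),
            class = "regional_null_fid")
}

#' Null-model decay tables aligned to the empirical table
#'
#' For `kind = "gaussian"` or `"phase"`: regenerates one surrogate per
#' trial (seeded per trial from `seed`) and runs the full edge + AMI
#' pipeline on it. For `kind = "regional"`: estimates nodal decay times
#' per trial with the same AMI estimator and predicts each edge decay as
#' the geometric mean of its two nodal decays. Rows and columns align
#' with the empirical [trial_decay_table()] for paired comparison.
#'
#' @param dataset an `epoch_set` or list of [epoched_ts()].
#' @param kind `"regional"`, `"gaussian"` or `"phase"`.
#' @param max_delay,bins,tail_points,k_sd,sd_mode AMI parameters.
#' @param seed base seed; trial t uses `seed + t - 1`.
#' @return a [trial_decay_table()] with an extra `kind` field.
#' @export
null_decay_tables <- function(dataset,
                              kind = c("regional", "gaussian", "phase"),
                              max_delay = 127L, bins = 64L,
                              tail_points = 80L, k_sd = 1, seed = 1L,
                              sd_mode = c("residual", "raw")) {
  kind <- match.arg(kind)
  sd_mode <- match.arg(sd_mode)
  epochs <- if (inherits(dataset, "epoch_set")) dataset$epochs else dataset
  stopifnot(length(epochs) >= 1L, inherits(epochs[[1L]], "epoched_ts"))
  fs <- epochs[[1L]]$fs
  n <- nrow(epochs[[1L]]$data)
  idx <- edge_index(n)
  rows <- vector("list", length(epochs))
  for (t in seq_along(epochs)) {
    ep <- epochs[[t]]
    if (kind == "regional") {
      nodal <- batch_decay(ep$data, max_delay, bins, tail_points, k_sd, fs,
                           sd_mode)$tau_star
      m <- regional_null_fid(as.numeric(nodal))$matrix
      rows[[t]] <- m[cbind(idx[, 1], idx[, 2])]
    } else {
      sur <- if (kind == "gaussian") gaussian_surrogate(ep, seed + t - 1L)
             else phase_surrogate(ep, seed + t - 1L)
      e <- edge_time_series(sur)
      rows[[t]] <- batch_decay(e$data, max_delay, bins, tail_points, k_sd,
                               fs, sd_mode)$tau_star
    }
  }
  trial_ids <- data.frame(
    subject = vapply(epochs, function(e) as.integer(e$subject_id), integer(1)),
    epoch = vapply(epochs, function(e) as.integer(e$epoch_id), integer(1)))
  structure(list(values = do.call(rbind, rows), trial_ids = trial_ids,
                 edge_index = idx, fs = fs, level = "edge",
                 standardized = FALSE, kind = kind),
            class = "trial_decay_table")
}
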