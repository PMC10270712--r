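# Toy forward/inverse (source-leakage) simulation: sources on a
# hemispherical grid, sensors on an enclosing sphere, a 1/distance^2
# leadfield, spatially correlated sensor noise, and an LCMV beamformer
# inverse. Used to test whether linear source mixing alone reproduces the
# empirical decay topography (it should not).

# Deterministic quasi-uniform points on a sphere (golden-spiral layout).
fibonacci_sphere <- function(n, hemisphere = FALSE) {
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 0.5
  z <- if (hemisphere) i / n else 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- golden * (seq_len(n) - 1)
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

#' Toy head model: hemispherical sources, spherical sensors, 1/d^2 leadfield
#'
#' Sources sit on a hemispherical grid of radius 0.8 (inside the unit
#' sphere), sensors on an enclosing sphere of radius 1.2; a small seeded
#' jitter breaks grid symmetries. Leadfield entries decay as the inverse
#' squared source-sensor distance.
#'
#' @param n_sources,n_sensors counts (>= 2); default more sensors than
#'   sources.
#' @param seed RNG seed for the jitter.
#' @return object of class `toy_head_model`: list with `source_positions`
#'   (N x 3), `sensor_positions` (M x 3), `leadfield` (M x N).
#' @export
toy_leadfield <- function(n_sources, n_sensors = 2L * n_sources, seed = 1L) {
  n_sources <- check_scalar_count(n_sources, "n_sources")
  n_sensors <- check_scalar_count(n_sensors, "n_sensors")
  if (n_sources < 2L || n_sensors < 2L) stop_config("counts must be >= 2")
  set.seed(seed)
  src <- 0.8 * fibonacci_sphere(n_sources, hemisphere = TRUE)
  src <- src + matrix(rnorm(3 * n_sources, sd = 0.01), ncol = 3)
  sens <- 1.2 * fibonacci_sphere(n_sensors)
  d <- sqrt(outer(rowSums(sens^2), rep(1, n_sources)) +
            outer(rep(1, n_sensors), rowSums(src^2)) -
            2 * sens %*% t(src))
  structure(list(source_positions = src, sensor_positions = sens,
                 leadfield = 1 / d^2),
            class = "toy_head_model")
}

#' Project sources to sensors and add distance-correlated noise
#'
#' Sensor data = leadfield x sources + noise. The noise spatial covariance
#' is proportional to 1/(sensor distance) with the diagonal set to the
#' largest off-diagonal entry, projected to the nearest positive
#' semidefinite matrix (negative eigenvalues clipped), and scaled so that
#' total signal power / total noise power equals `snr`.
#'
#' @param sources regions x samples matrix.
#' @param head a [toy_leadfield()] model.
#' @param snr signal-to-noise power ratio (> 0, default 12).
#' @param seed RNG seed for the noise draw.
#' @return sensors x samples matrix.
#' @export
forward_noise_project <- function(sources, head, snr = 12, seed = 1L) {
  stopifnot(inherits(head, "toy_head_model"))
  if (snr <= 0) stop_config("snr must be > 0")
  sources <- as.matrix(sources)
  L <- head$leadfield
  if (ncol(L) != nrow(sources))
    stop_data("sources rows must match the number of leadfield sources")
  signal <- L %*% sources
  sens <- head$sensor_positions
  dist <- as.matrix(stats::dist(sens))
  cov_n <- 1 / dist
  diag(cov_n) <- max(cov_n[upper.tri(cov_n)])
  eig <- eigen(cov_n, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  if (all(vals == 0)) stop_data("noise covariance projection failed: all eigenvalues nonpositive")
  root <- eig$vectors %*% (sqrt(vals) * t(eig$vectors))
  set.seed(seed)
  noise <- root %*% matrix(rnorm(nrow(L) * ncol(sources)), nrow = nrow(L))
  scale <- sqrt(mean(signal^2) / (snr * mean(noise^2)))
  signal + scale * noise
}

#' LCMV beamformer reconstruction of source time series
#'
#' Linearly constrained minimum-variance spatial filter per source with
#' unit gain at the target (w_i' l_i = 1), using the regularized sensor
#' covariance C + reg * mean(eig(C)) * I.
#'
#' @param sensor_data sensors x samples matrix.
#' @param head a [toy_leadfield()] model.
#' @param regularization diagonal loading as a proportion of the mean
#'   sensor-covariance eigenvalue (default 0.05).
#' @return regions x samples matrix of reconstructed sources.
#' @export
inverse_reconstruct <- function(sensor_data, head, regularization = 0.05) {
  stopifnot(inherits(head, "toy_head_model"))
  if (regularization < 0) stop_config("regularization must be >= 0")
  y <- as.matrix(sensor_data)
  L <- head$leadfield
  if (nrow(y) != nrow(L)) stop_data("sensor_data rows must match sensors")
  yc <- y - rowMeans(y)
  C <- tcrossprod(yc) / ncol(y)
  mean_eig <- mean(diag(C))          # trace/M = mean eigenvalue
  Creg <- C + regularization * mean_eig * diag(nrow(C))
  Cinv <- tryCatch(solve(Creg), error = function(e)
    stop_data("sensor covariance is singular; increase regularization"))
  CiL <- Cinv %*% L
  gains <- colSums(L * CiL)          # l_i' C^-1 l_i
  W <- sweep(CiL, 2L, gains, "/")    # columns: w_i = C^-1 l_i / gain
  t(W) %*% y
}

#' FID matrix of beamformed independent-noise surrogates
#'
#' Full leakage pipeline: independent Gaussian white sources per trial,
#' forward projection through the toy leadfield, distance-correlated
#' sensor noise at the configured SNR, LCMV inverse, then edge
#' construction and AMI decay estimation. The resulting FID reflects
#' linear mixing alone and serves as the volume-conduction control.
#'
#' @param config a [simulation_config()] (region count, trial count, fs,
#'   epoch length are taken from it).
#' @param head a [toy_leadfield()] with `n_sources = config$n_regions`.
#' @param snr sensor signal-to-noise power ratio (default 12).
#' @param regularization LCMV diagonal loading (default 0.05).
#' @param max_delay,bins,tail_points,k_sd AMI parameters.
#' @param seed RNG seed.
#' @param standardized passed to [fid_matrix()].
#' @return list with `fid` (a [fid_matrix()]) and `table` (the raw
#'   [trial_decay_table()]).
#' @export
leakage_fid <- function(config, head, snr = 12, regularization = 0.05,
                        max_delay = 127L, bins = 64L, tail_points = 80L,
                        k_sd = 1, seed = 1L, standardized = TRUE) {
  stopifnot(inherits(config, "sim_config"), inherits(head, "toy_head_model"))
  if (ncol(head$leadfield) != config$n_regions)
    stop_data("head model source count must equal config$n_regions")
  n_trials <- config$n_subjects * config$n_epochs_per_subject
  epochs <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    set.seed(seed + t - 1L)
    src <- matrix(rnorm(config$n_regions * config$n_samples),
                  nrow = config$n_regions)
    y <- forward_noise_project(src, head, snr = snr, seed = seed + 10000L + t)
    rec <- inverse_reconstruct(y, head, regularization)
    epochs[[t]] <- epoched_ts(rec, config$fs,
                              subject_id = (t - 1L) %/% config$n_epochs_per_subject + 1L,
                              epoch_id = (t - 1L) %% config$n_epochs_per_subject + 1L)
  }
  tab <- trial_decay_table(epochs, level = "edge", max_delay = max_delay,
                           bins = bins, tail_points = tail_points, k_sd = k_sd)
  list(fid = fid_matrix(tab, standardized = standardized), table = tab)
}
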