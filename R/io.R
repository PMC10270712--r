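# Plain-text I/O: CSV-per-epoch datasets with a JSON manifest, decay
# tables, FID matrices and classification tables as CSV. Formats are
# deterministic so that identically seeded runs produce byte-identical
# files.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

write_matrix_csv <- function(m, path, col_prefix = "V") {
  df <- as.data.frame(apply(m, 2L, fmt_num))  # %.17g: doubles round-trip exactly
  names(df) <- paste0(col_prefix, seq_len(ncol(df)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write an epoched dataset as CSV files plus a JSON manifest
#'
#' One CSV per epoch (`sub<S>_ep<E>.csv`, regions in rows), a
#' `region_labels.csv` table and a `manifest.json` holding fs, epoch
#' shapes and (for synthetic sets) the generating configuration.
#'
#' @param dataset an `epoch_set` or list of [epoched_ts()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(dataset, path) {
  epochs <- if (inherits(dataset, "epoch_set")) dataset$epochs else dataset
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(epochs))
  for (k in seq_along(epochs)) {
    ep <- epochs[[k]]
    files[k] <- sprintf("sub%03d_ep%03d.csv", as.integer(ep$subject_id),
                        as.integer(ep$epoch_id))
    write_matrix_csv(ep$data, file.path(path, files[k]), col_prefix = "t")
  }
  ep1 <- epochs[[1L]]
  labels <- data.frame(index = seq_along(ep1$region_labels),
                       label = ep1$region_labels, lobe = NA_character_)
  write.csv(labels, file.path(path, "region_labels.csv"), row.names = FALSE)
  manifest <- list(fs = ep1$fs, n_regions = nrow(ep1$data),
                   n_samples = ncol(ep1$data), files = files,
                   subjects = vapply(epochs, function(e) as.integer(e$subject_id), integer(1)),
                   epoch_ids = vapply(epochs, function(e) as.integer(e$epoch_id), integer(1)))
  if (inherits(dataset, "epoch_set"))
    manifest$config <- unclass(dataset$config)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load an epoched dataset written by [write_epochs()]
#'
#' @param path dataset directory.
#' @param format only `"csv"` is supported; `"hdf5"` and `"npz"` are
#'   recognized names but raise an unsupported-format error.
#' @return list of [epoched_ts()].
#' @export
load_epochs <- function(path, format = c("csv", "hdf5", "npz")) {
  format <- match.arg(format)
  if (format != "csv")
    stop_config("format '", format, "' is not supported by this build; use 'csv'")
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop_data("schema error: manifest.json missing in ", path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  for (field in c("fs", "n_regions", "n_samples", "files"))
    if (is.null(mf[[field]])) stop_data("schema error: manifest field '", field, "' missing")
  labels <- NULL
  lab_path <- file.path(path, "region_labels.csv")
  if (file.exists(lab_path)) labels <- read.csv(lab_path)$label
  lapply(seq_along(mf$files), function(k) {
    m <- as.matrix(read.csv(file.path(path, mf$files[k])))
    dimnames(m) <- NULL
    if (!identical(dim(m), c(as.integer(mf$n_regions), as.integer(mf$n_samples))))
      stop_data("schema error: ", mf$files[k], " has shape ", nrow(m), "x",
                ncol(m), ", manifest says ", mf$n_regions, "x", mf$n_samples)
    epoched_ts(m, mf$fs, subject_id = mf$subjects[k],
               epoch_id = mf$epoch_ids[k], region_labels = labels)
  })
}

#' Write a decay table as CSV
#'
#' Long format: subject, epoch, i, j (or node), tau_star, tau_star_ms,
#' plus a `kind` column for null-model tables.
#'
#' @param table a [trial_decay_table()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_decay_table <- function(table, path) {
  stopifnot(inherits(table, "trial_decay_table"))
  n_col <- ncol(table$values)
  n_tr <- nrow(table$values)
  base <- data.frame(subject = rep(table$trial_ids$subject, each = n_col),
                     epoch = rep(table$trial_ids$epoch, each = n_col))
  if (table$level == "edge") {
    base$i <- rep(table$edge_index[, 1], times = n_tr)
    base$j <- rep(table$edge_index[, 2], times = n_tr)
  } else {
    base$node <- rep(seq_len(n_col), times = n_tr)
  }
  base$tau_star <- fmt_num(as.vector(t(table$values)))
  if (!table$standardized)
    base$tau_star_ms <- fmt_num(as.vector(t(table$values)) * 1000 / table$fs)
  base$kind <- if (is.null(table$kind)) "empirical" else table$kind
  write.csv(base, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a FID (or deviation) matrix as labeled CSV
#'
#' @param fid a [fid_matrix()] or plain square matrix.
#' @param path output CSV file.
#' @param labels optional region labels for row/column names.
#' @return `path`, invisibly.
#' @export
write_fid <- function(fid, path, labels = NULL) {
  m <- if (inherits(fid, "fid_matrix")) fid$matrix else as.matrix(fid)
  if (is.null(labels)) labels <- paste0("R", seq_len(nrow(m)))
  df <- as.data.frame(apply(m, 2L, fmt_num))
  names(df) <- labels
  df <- cbind(region = labels, df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
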