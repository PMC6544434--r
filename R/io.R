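# On-disk layouts: HDF5 container for traces and ground truth
# (/traces/F, /traces/Fnp, /truth/rates, /truth/labels), CSV trial table,
# CSV pupil track, YAML run configuration.

#' Write a synthetic dataset to an HDF5 container + CSV sidecars
#'
#' Layout: `/traces/F`, `/traces/Fnp` (ROI x time), `/truth/rates`,
#' `/truth/labels`, `/meta/frame_rate`; trial table and pupil track go to
#' `<stem>_trials.csv` and `<stem>_pupil.csv` next to the HDF5 file.
#'
#' @param dataset a `SyntheticDataset`.
#' @param path output `.h5` path.
#' @return `path`, invisibly.
#' @export
write_dataset_h5 <- function(dataset, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "traces")
  rhdf5::h5createGroup(path, "truth")
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5write(dataset$traces$F, path, "traces/F")
  rhdf5::h5write(dataset$traces$F_np, path, "traces/Fnp")
  rhdf5::h5write(dataset$truth_rates, path, "truth/rates")
  rhdf5::h5write(dataset$truth_labels, path, "truth/labels")
  rhdf5::h5write(dataset$traces$frame_rate, path, "meta/frame_rate")
  rhdf5::h5write(dataset$seed, path, "meta/seed")
  rhdf5::h5closeAll()
  stem <- sub("\\.h5$", "", path)
  write_trials_csv(dataset$trials, paste0(stem, "_trials.csv"))
  write_pupil_csv(dataset$pupil, paste0(stem, "_pupil.csv"))
  invisible(path)
}

#' Read a dataset written by [write_dataset_h5()]
#' @param path `.h5` path.
#' @return list with `traces` (RoiTraceSet), `truth_rates`, `truth_labels`,
#'   `trials`, `pupil`, `seed`.
#' @export
read_dataset_h5 <- function(path) {
  fr <- as.numeric(rhdf5::h5read(path, "meta/frame_rate"))
  traces <- roi_trace_set(rhdf5::h5read(path, "traces/F"),
                          rhdf5::h5read(path, "traces/Fnp"), fr)
  out <- list(traces = traces,
              truth_rates = rhdf5::h5read(path, "truth/rates"),
              truth_labels = as.character(rhdf5::h5read(path, "truth/labels")),
              seed = as.integer(rhdf5::h5read(path, "meta/seed")))
  rhdf5::h5closeAll()
  stem <- sub("\\.h5$", "", path)
  tpath <- paste0(stem, "_trials.csv")
  ppath <- paste0(stem, "_pupil.csv")
  if (file.exists(tpath)) out$trials <- read_trials_csv(tpath)
  if (file.exists(ppath)) out$pupil <- read_pupil_csv(ppath)
  out
}

#' @rdname write_dataset_h5
#' @param trials trial table.
#' @export
write_trials_csv <- function(trials, path) {
  df <- as.data.frame(trials)
  utils::write.csv(cbind(df, frame_rate = attr(trials, "frame_rate"),
                         block_len = attr(trials, "block_len"),
                         stim_onset = attr(trials, "stim_onset")),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_h5
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- df[1, c("frame_rate", "block_len", "stim_onset")]
  df <- df[, setdiff(names(df), c("frame_rate", "block_len", "stim_onset"))]
  structure(df, frame_rate = meta$frame_rate, block_len = meta$block_len,
            stim_onset = meta$stim_onset)
}

#' @rdname write_dataset_h5
#' @param pupil pupil track.
#' @export
write_pupil_csv <- function(pupil, path) {
  utils::write.csv(cbind(as.data.frame(pupil),
                         sample_rate = attr(pupil, "sample_rate")),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_h5
#' @export
read_pupil_csv <- function(path) {
  df <- utils::read.csv(path)
  sr <- df$sample_rate[1]
  df <- df[, setdiff(names(df), "sample_rate")]
  structure(df, sample_rate = sr, class = c("PupilTrack", "data.frame"))
}
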