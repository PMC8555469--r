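#' Epoched multichannel EEG container
#'
#' Bundles a trials x channels x samples array with its channel geometry,
#' sampling rate, trial-relative time origin and per-trial metadata
#' (condition label, run and trial indices, subject id).
#'
#' @param data Numeric array, trials x channels x samples (microvolts, or
#'   current-source-density units after the surface Laplacian).
#' @param channels Character vector of channel names, one per array column.
#' @param positions Numeric matrix (channels x 3) of unit-sphere electrode
#'   coordinates, rows aligned with `channels`.
#' @param sfreq Sampling rate in Hz.
#' @param t0 Time of the first sample relative to trial start, in seconds.
#' @param labels Character/factor vector of per-trial condition labels
#'   ("left"/"right").
#' @param subject_id Subject identifier (scalar).
#' @param run Integer vector of per-trial run indices.
#' @param trial Integer vector of per-trial within-run trial indices.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, channels, positions, sfreq, t0 = 0,
                       labels = NULL, subject_id = NA_character_,
                       run = NULL, trial = NULL) {
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (trials x channels x samples)")
  }
  if (dim(data)[2] != length(channels)) {
    stop("channel dimension (", dim(data)[2], ") does not match ",
         length(channels), " channel names")
  }
  positions <- as.matrix(positions)
  if (nrow(positions) != length(channels) || ncol(positions) != 3L) {
    stop("`positions` must be a channels x 3 matrix")
  }
  nrm <- sqrt(rowSums(positions^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("electrode positions must lie on the unit sphere")
  }
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0) {
    stop("`sfreq` must be a positive scalar sampling rate")
  }
  n_trials <- dim(data)[1]
  if (is.null(labels)) labels <- rep(NA_character_, n_trials)
  labels <- as.character(labels)
  if (length(labels) != n_trials) {
    stop("`labels` must have one entry per trial")
  }
  if (is.null(run)) run <- rep(1L, n_trials)
  if (is.null(trial)) trial <- seq_len(n_trials)
  structure(
    list(data = data, channels = as.character(channels),
         positions = positions, sfreq = sfreq, t0 = t0,
         labels = labels, subject_id = subject_id,
         run = as.integer(run), trial = as.integer(trial)),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  sprintf("<eeg_epochs> subject %s: %d trials x %d channels x %d samples @ %g Hz (%s)",
          as.character(x$subject_id), d[1], d[2], d[3], x$sfreq,
          paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                collapse = ", "))
}

#' Number of trials / channels / samples of an epoch set
#' @param x An `eeg_epochs` object.
#' @return Named integer vector (trials, channels, samples).
#' @export
epoch_dims <- function(x) {
  stopifnot(inherits(x, "eeg_epochs"))
  d <- dim(x$data)
  c(trials = d[1], channels = d[2], samples = d[3])
}

#' Trial-relative sample times of an epoch set
#' @param x An `eeg_epochs` object.
#' @return Numeric vector of times (s) for each sample.
#' @export
epoch_times <- function(x) {
  stopifnot(inherits(x, "eeg_epochs"))
  x$t0 + (seq_len(dim(x$data)[3]) - 1L) / x$sfreq
}

#' Subset trials of an epoch set
#' @param x An `eeg_epochs` object.
#' @param idx Logical or integer trial index.
#' @return An `eeg_epochs` with the selected trials.
#' @export
subset_trials <- function(x, idx) {
  stopifnot(inherits(x, "eeg_epochs"))
  eeg_epochs(x$data[idx, , , drop = FALSE], x$channels, x$positions,
             x$sfreq, x$t0, x$labels[idx], x$subject_id,
             x$run[idx], x$trial[idx])
}
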