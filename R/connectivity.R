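#' Frequency band specification for wavelet phase extraction
#'
#' Defaults follow the two sensorimotor bands used throughout the package:
#' alpha with center frequency fc = 10.5 Hz and bandwidth parameter
#' fb = 0.3 s^2, beta with fc = 21.5 Hz and fb = 0.13 s^2.
#'
#' @param name Band name.
#' @param fc Center frequency (Hz), > 0.
#' @param fb Bandwidth parameter of the Gaussian envelope (s^2), > 0.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(name, fc, fb) {
  if (fc <= 0 || fb <= 0) stop("fc and fb must be positive")
  structure(list(name = name, fc = fc, fb = fb), class = "band_spec")
}

#' Default alpha and beta analysis bands
#' @return Named list of [band_spec()]s.
#' @export
default_bands <- function() {
  list(alpha = band_spec("alpha", fc = 10.5, fb = 0.3),
       beta = band_spec("beta", fc = 21.5, fb = 0.13))
}

#' Complex Morlet wavelet kernel
#'
#' Samples psi(t) = (pi * fb)^(-1/2) * exp(j 2 pi fc t) * exp(-t^2 / fb)
#' on a symmetric grid at the given rate, extended until the envelope at
#' the ends falls below 1e-6 of its peak. The kernel has odd length with
#' its peak at the center sample (t = 0).
#'
#' @param band A [band_spec()].
#' @param sample_rate_hz Sampling rate (Hz); must exceed 2 * fc.
#' @return Complex vector with attributes `times` and `half_len`.
#' @export
cmw_kernel <- function(band, sample_rate_hz) {
  stopifnot(inherits(band, "band_spec"))
  if (sample_rate_hz <= 2 * band$fc) {
    stop("sample rate must exceed twice the center frequency")
  }
  half <- ceiling(sqrt(band$fb * log(1e6)) * sample_rate_hz)
  if (2 * half + 1 < 3) stop("fb too small: kernel shorter than 3 samples")
  t <- (-half:half) / sample_rate_hz
  psi <- (pi * band$fb)^(-0.5) *
    exp(1i * 2 * pi * band$fc * t) * exp(-t^2 / band$fb)
  attr(psi, "times") <- t
  attr(psi, "half_len") <- half
  psi
}

#' Instantaneous phase via complex Morlet wavelet convolution
#'
#' Convolves every trial/channel with the band's complex Morlet kernel
#' (FFT-based, same-length centered output) and takes the argument of the
#' complex result. `valid_mask` marks the samples at least half a kernel
#' length away from both trial edges; samples outside it carry phase
#' estimates contaminated by the convolution boundary and are dropped from
#' window averages downstream.
#'
#' @param epochs An [eeg_epochs()] object (already preprocessed).
#' @param band A [band_spec()].
#' @return A `phase_tensor`: list with `phase` (trials x channels x
#'   samples, radians in (-pi, pi]), `valid_mask`, `times`, `band`,
#'   `channels`, `labels`, `subject_id`, `sfreq`.
#' @export
extract_phase <- function(epochs, band) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  psi <- cmw_kernel(band, epochs$sfreq)
  half <- attr(psi, "half_len")
  L <- length(psi)
  d <- dim(epochs$data)
  n <- d[3]
  if (n < L) stop("trial shorter than the wavelet kernel (", L, " samples)")
  nfft <- 2^ceiling(log2(n + L - 1))
  K <- stats::fft(c(psi, rep(0, nfft - L)))
  # all trial/channel series as columns for one batched FFT
  X <- matrix(0, nfft, d[1] * d[2])
  X[seq_len(n), ] <- t(matrix(epochs$data, d[1] * d[2], n))
  Y <- stats::mvfft(stats::mvfft(X) * K, inverse = TRUE) / nfft
  centered <- Y[half + seq_len(n), , drop = FALSE]   # "same" alignment
  ph <- array(t(Arg(centered)), dim = d)
  valid <- rep(FALSE, n)
  valid[(half + 1):(n - half)] <- TRUE
  structure(
    list(phase = ph, valid_mask = valid, times = epoch_times(epochs),
         band = band, channels = epochs$channels, labels = epochs$labels,
         subject_id = epochs$subject_id, sfreq = epochs$sfreq),
    class = "phase_tensor")
}

#' @export
print.phase_tensor <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf("<phase_tensor> %s band: %d trials x %d channels x %d samples (%d valid)\n",
              x$band$name, d[1], d[2], d[3], sum(x$valid_mask)))
  invisible(x)
}

# window sample selector: half-open [start, end) intersected with the
# convolution-valid region
window_samples <- function(phases, window) {
  keep <- phases$times >= window$start_s & phases$times < window$end_s
  if (!any(keep)) stop("window '", window$name, "' contains no samples")
  keep_valid <- keep & phases$valid_mask
  if (!any(keep_valid)) {
    stop("window '", window$name,
         "' has no samples clear of the wavelet edge region")
  }
  keep_valid
}

#' Inter-trial phase-locking value of one electrode pair
#'
#' For each window sample t, computes the resultant length
#' R(t) = (1/N) |sum_n exp(j (phi_i(t, n) - phi_j(t, n)))| across the N
#' trials, then returns the mean of R(t) over the window's samples
#' (samples within half a kernel length of a trial edge are excluded).
#' `agg = "pooled"` instead treats the whole window as a single bin,
#' pooling trials and samples into one resultant.
#'
#' @param phases A `phase_tensor` from [extract_phase()].
#' @param i,j Channel names or indices; must differ.
#' @param window A [window_def()].
#' @param agg "samplewise" (default) or "pooled".
#' @return PLV in [0, 1].
#' @export
plv_pair <- function(phases, i, j, window,
                     agg = c("samplewise", "pooled")) {
  stopifnot(inherits(phases, "phase_tensor"))
  agg <- match.arg(agg)
  if (is.character(i)) i <- match(i, phases$channels)
  if (is.character(j)) j <- match(j, phases$channels)
  if (is.na(i) || is.na(j)) stop("unknown channel name")
  if (i == j) stop("self-pair PLV is undefined")
  N <- dim(phases$phase)[1]
  if (N < 2) stop("need at least 2 trials for an inter-trial PLV")
  keep <- window_samples(phases, window)
  dphi <- phases$phase[, i, keep, drop = TRUE] -
    phases$phase[, j, keep, drop = TRUE]
  z <- exp(1i * dphi)
  if (agg == "pooled") return(Mod(mean(z)))
  mean(Mod(colMeans(z)))
}

#' PLV for every unordered electrode pair
#'
#' @param phases A `phase_tensor`.
#' @param window A [window_def()].
#' @param trial_subset Optional condition label ("left"/"right"); restricts
#'   to trials with that label.
#' @param agg Aggregation mode, see [plv_pair()].
#' @return Tibble with columns subject_id, condition, window, band,
#'   channel_i, channel_j (i before j in montage order), plv.
#' @export
plv_matrix <- function(phases, window, trial_subset = NULL,
                       agg = c("samplewise", "pooled")) {
  stopifnot(inherits(phases, "phase_tensor"))
  agg <- match.arg(agg)
  if (!is.null(trial_subset)) {
    sel <- phases$labels == trial_subset
    if (!any(sel)) stop("no trials with label '", trial_subset, "'")
    ph <- phases$phase[sel, , , drop = FALSE]
  } else {
    sel <- rep(TRUE, length(phases$labels))
    ph <- phases$phase
  }
  N <- dim(ph)[1]
  if (N < 2) stop("need at least 2 trials for an inter-trial PLV")
  keep <- window_samples(phases, window)
  nch <- length(phases$channels)
  S <- sum(keep)
  Z <- exp(1i * ph[, , keep, drop = FALSE])
  pairs <- utils::combn(nch, 2)
  plv <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    z <- Z[, pairs[1, p], , drop = TRUE] *
      Conj(Z[, pairs[2, p], , drop = TRUE])
    if (agg == "pooled") {
      plv[p] <- Mod(mean(z))
    } else {
      plv[p] <- mean(Mod(colMeans(z)))
    }
  }
  tibble::tibble(
    subject_id = phases$subject_id,
    condition = if (is.null(trial_subset)) "all" else trial_subset,
    window = window$name,
    band = phases$band$name,
    channel_i = phases$channels[pairs[1, ]],
    channel_j = phases$channels[pairs[2, ]],
    plv = plv)
}

#' Task-induced connectivity change (delta PLV)
#'
#' Joins motor-imagery and rest PLV rows on (subject_id, condition, band,
#' channel_i, channel_j) and returns rows with window = "delta" and
#' value = PLV_mi - PLV_rest.
#'
#' @param mi_rows,rest_rows PLV tables as returned by [plv_matrix()].
#' @return Tibble of delta rows (plv in [-1, 1]).
#' @export
delta_plv <- function(mi_rows, rest_rows) {
  keys <- c("subject_id", "condition", "band", "channel_i", "channel_j")
  a <- mi_rows[, c(keys, "plv")]
  b <- rest_rows[, c(keys, "plv")]
  merged <- dplyr::inner_join(a, b, by = keys, suffix = c("_mi", "_rest"))
  if (nrow(merged) != nrow(a) || nrow(merged) != nrow(b)) {
    ka <- do.call(paste, c(a[keys], sep = "|"))
    kb <- do.call(paste, c(b[keys], sep = "|"))
    miss <- c(setdiff(ka, kb), setdiff(kb, ka))
    stop("mi/rest key mismatch; unmatched keys: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  tibble::tibble(
    subject_id = merged$subject_id,
    condition = merged$condition,
    window = "delta",
    band = merged$band,
    channel_i = merged$channel_i,
    channel_j = merged$channel_j,
    plv = merged$plv_mi - merged$plv_rest)
}

#' Full per-subject PLV table across conditions, windows and bands
#'
#' Runs [extract_phase()] once per band on the full trials, then
#' [plv_matrix()] for each condition and window, and appends the delta
#' (mi - rest) rows per condition/band.
#'
#' @param epochs Preprocessed [eeg_epochs()].
#' @param bands List of [band_spec()]s (default [default_bands()]).
#' @param windows Named list with `rest` and `mi` [window_def()]s.
#' @param conditions Condition labels to process (default left and right).
#' @param agg Aggregation mode, see [plv_pair()].
#' @return Tidy tibble of PLV rows (windows rest, mi, delta).
#' @export
compute_plv_table <- function(epochs, bands = default_bands(),
                              windows = default_windows(),
                              conditions = c("left", "right"),
                              agg = "samplewise") {
  out <- list()
  for (band in bands) {
    phases <- extract_phase(epochs, band)
    for (cond in conditions) {
      rest <- plv_matrix(phases, windows$rest, cond, agg = agg)
      mi <- plv_matrix(phases, windows$mi, cond, agg = agg)
      out[[length(out) + 1L]] <- rest
      out[[length(out) + 1L]] <- mi
      out[[length(out) + 1L]] <- delta_plv(mi, rest)
    }
  }
  dplyr::bind_rows(out)
}
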