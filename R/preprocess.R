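#' Analysis window definition
#'
#' The default analysis windows are the 3 s pre-cue rest period [0, 3) and
#' the 3.5 s motor-imagery segment from 1 s to 4.5 s after the 3 s cue,
#' i.e. [4, 7.5) trial-relative. Windows are half-open [start, end).
#'
#' @param name Window name ("rest" or "mi", free-form allowed).
#' @param start_s,end_s Trial-relative start/end times in seconds.
#' @return An object of class `window_def`.
#' @export
window_def <- function(name, start_s, end_s) {
  if (end_s <= start_s) stop("window end must be after start")
  structure(list(name = name, start_s = start_s, end_s = end_s),
            class = "window_def")
}

#' Default rest / motor-imagery windows
#' @param cue_onset_s Cue time (s), default 3.
#' @return Named list of two [window_def()]s: rest = [0, cue), mi =
#'   [cue + 1, cue + 4.5).
#' @export
default_windows <- function(cue_onset_s = 3) {
  list(rest = window_def("rest", 0, cue_onset_s),
       mi = window_def("mi", cue_onset_s + 1, cue_onset_s + 4.5))
}

#' Common average reference
#'
#' Subtracts, at every sample of every trial, the instantaneous mean across
#' channels from each channel. After CAR the channel-mean is exactly zero
#' at every sample; applying CAR twice equals applying it once.
#'
#' @param epochs An [eeg_epochs()] object with >= 2 channels.
#' @return Re-referenced `eeg_epochs`.
#' @export
common_average_reference <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  if (d[2] < 2L) stop("CAR is undefined for a single channel")
  out <- epochs
  for (tr in seq_len(d[1])) {
    x <- epochs$data[tr, , ]
    out$data[tr, , ] <- sweep(x, 2, colMeans(x))
  }
  out
}

#' Zero-phase band-pass filter
#'
#' Filters every channel of every trial forward and backward so the net
#' phase response is zero — a requirement for downstream phase estimation.
#' The default is a 4th-order Butterworth band-pass applied with
#' `signal::filtfilt`; a linear-phase FIR (Hamming window, ~1 Hz transition)
#' is available via `method = "fir"`.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param lo_hz,hi_hz Band edges in Hz (defaults 8 and 30).
#' @param method "butter" (default) or "fir".
#' @param order Filter order: Butterworth section order (default 4) or FIR
#'   length - 1 (default 824, giving a ~1 Hz transition at 250 Hz).
#' @return Filtered `eeg_epochs`.
#' @export
bandpass <- function(epochs, lo_hz = 8, hi_hz = 30,
                     method = c("butter", "fir"), order = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  method <- match.arg(method)
  fs <- epochs$sfreq
  if (hi_hz >= fs / 2) stop("hi_hz must be below the Nyquist frequency")
  if (lo_hz <= 0 || lo_hz >= hi_hz) stop("need 0 < lo_hz < hi_hz")
  if (method == "butter") {
    if (is.null(order)) order <- 4
    flt <- signal::butter(order, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  } else {
    if (is.null(order)) order <- 824
    flt <- signal::fir1(order, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  }
  d <- dim(epochs$data)
  out <- epochs
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      out$data[tr, ch, ] <- signal::filtfilt(flt, epochs$data[tr, ch, ])
    }
  }
  out
}

# Legendre polynomials P_1..P_nmax evaluated at each entry of x
# returns list of matrices (or vectors) indexed by degree
legendre_series <- function(x, nmax) {
  P <- vector("list", nmax)
  Pm1 <- x * 0 + 1   # P_0
  P[[1]] <- x        # P_1
  for (n in 2:nmax) {
    P[[n]] <- ((2 * n - 1) * x * P[[n - 1]] - (n - 1) *
                 (if (n == 2) Pm1 else P[[n - 2]])) / n
  }
  P
}

# Perrin spherical-spline G and H matrices for unit-sphere positions
csd_gh <- function(positions, m = 4, nterms = 50) {
  cosang <- tcrossprod(positions)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  P <- legendre_series(cosang, nterms)
  G <- matrix(0, nrow(cosang), ncol(cosang))
  H <- matrix(0, nrow(cosang), ncol(cosang))
  for (n in seq_len(nterms)) {
    gden <- (n * (n + 1))^m
    hden <- (n * (n + 1))^(m - 1)
    G <- G + (2 * n + 1) / gden * P[[n]]
    H <- H + (2 * n + 1) / hden * P[[n]]
  }
  list(G = G / (4 * pi), H = H / (4 * pi))
}

#' Spherical-spline surface Laplacian (current source density)
#'
#' Perrin-style spherical-spline interpolation of the scalp potential with
#' spline stiffness `stiffness` (default 4) and ridge regularization
#' `lambda` (default 1e-5) added to the diagonal of the interpolation
#' matrix, followed by analytic evaluation of the surface Laplacian of the
#' interpolant at the electrodes. The Legendre series is truncated at
#' `nterms` terms. A spatially constant potential maps to exactly zero
#' (the spline's constant offset is absorbed by the solver's zero-sum
#' constraint on the coefficients).
#'
#' @param epochs An [eeg_epochs()] object (>= 6 channels recommended for a
#'   stable solve).
#' @param stiffness Spline stiffness m (default 4).
#' @param lambda Regularization added to diag(G) (default 1e-5).
#' @param nterms Legendre series truncation (default 50).
#' @return `eeg_epochs` in current-source-density scale.
#' @export
surface_laplacian <- function(epochs, stiffness = 4, lambda = 1e-5,
                              nterms = 50) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  pos <- epochs$positions
  nch <- nrow(pos)
  if (nch < 4L) stop("too few channels for a stable spherical-spline solve")
  dup <- duplicated(round(pos, 10))
  if (any(dup)) {
    stop("duplicate electrode positions: ",
         paste(epochs$channels[dup], collapse = ", "))
  }
  gh <- csd_gh(pos, m = stiffness, nterms = nterms)
  Gs <- gh$G + diag(lambda, nch)
  Ginv <- solve(Gs)
  rs <- rowSums(Ginv)
  sgi <- sum(rs)
  out <- epochs
  for (tr in seq_len(dim(epochs$data)[1])) {
    V <- epochs$data[tr, , ]                    # channels x samples
    D <- Ginv %*% V
    c0 <- colSums(D) / sgi
    C <- D - outer(rs, c0)
    out$data[tr, , ] <- gh$H %*% C
  }
  out
}

#' Cut trial-relative analysis windows
#'
#' Extracts the samples with time in [start_s, end_s) (half-open; sample
#' index = floor(t * rate)) for each window.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param windows A single [window_def()] or list of them.
#' @return A single `eeg_epochs` (if one window) or named list of them.
#' @export
cut_windows <- function(epochs, windows) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (inherits(windows, "window_def")) {
    return(cut_one_window(epochs, windows))
  }
  out <- lapply(windows, function(w) cut_one_window(epochs, w))
  names(out) <- vapply(windows, function(w) w$name, character(1))
  out
}

cut_one_window <- function(epochs, w) {
  times <- epoch_times(epochs)
  keep <- times >= w$start_s & times < w$end_s
  if (!any(keep)) stop("window '", w$name, "' contains no samples")
  eeg_epochs(epochs$data[, , keep, drop = FALSE], epochs$channels,
             epochs$positions, epochs$sfreq, t0 = min(times[keep]),
             labels = epochs$labels, subject_id = epochs$subject_id,
             run = epochs$run, trial = epochs$trial)
}
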