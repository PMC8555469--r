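#' Source specification for synthetic phase-coupled EEG
#'
#' Describes the generative model for one latent aptitude class: a set of
#' narrow-band cortical oscillators (one per channel) at `band_center_hz`,
#' a directed phase-coupling graph, and a 1/f^beta background noise floor.
#'
#' Coupling model: for a coupled pair (src, dst) with concentration kappa,
#' the destination channel's oscillator carries the source channel's
#' instantaneous phase plus a von Mises(mu = 0, kappa) offset redrawn once
#' per trial (and, independently, per trial segment). The expected
#' inter-trial phase-locking value of the pair is then the mean resultant
#' length of the von Mises distribution, I1(kappa)/I0(kappa), which the
#' recovery tests use as a closed-form oracle. kappa = 0 means no coupling,
#' kappa = Inf perfect locking.
#'
#' @param band_center_hz Oscillator frequency in Hz (default 10.5, the
#'   alpha-band center used for analysis).
#' @param coupling Data frame with columns `src`, `dst` (channel names) and
#'   `kappa_rest`, `kappa_mi_left`, `kappa_mi_right` (concentrations >= 0,
#'   one per trial condition/segment). NULL means no coupling anywhere.
#' @param amplitude Oscillator amplitude in microvolts.
#' @param noise_exponent Spectral slope beta of the 1/f^beta background.
#' @param snr Ratio of oscillator RMS to noise RMS; Inf disables noise.
#' @param freq_jitter_hz Half-width of the uniform per-trial frequency
#'   jitter applied to each independent oscillator, so uncoupled phase
#'   differences decorrelate across trials.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(band_center_hz = 10.5, coupling = NULL,
                        amplitude = 10, noise_exponent = 1, snr = 3,
                        freq_jitter_hz = 0.5) {
  if (band_center_hz <= 0) stop("band_center_hz must be positive")
  if (!is.null(coupling)) {
    coupling <- as.data.frame(coupling)
    need <- c("src", "dst", "kappa_rest", "kappa_mi_left", "kappa_mi_right")
    if (!all(need %in% names(coupling))) {
      stop("coupling needs columns: ", paste(need, collapse = ", "))
    }
    kap <- unlist(coupling[, c("kappa_rest", "kappa_mi_left", "kappa_mi_right")])
    if (any(kap < 0)) stop("coupling concentrations kappa must be >= 0")
  }
  if (snr <= 0) stop("snr must be positive (use Inf for noiseless)")
  structure(list(band_center_hz = band_center_hz, coupling = coupling,
                 amplitude = amplitude, noise_exponent = noise_exponent,
                 snr = snr, freq_jitter_hz = freq_jitter_hz),
            class = "source_spec")
}

#' Session specification (trial bookkeeping)
#'
#' Defaults reproduce the feedback phase of a two-class motor-imagery BCI
#' session: 3 runs of 40 trials (20 left- and 20 right-hand cues), 8 s
#' trials at 250 Hz with a 3 s pre-cue rest period and the cue at 3 s.
#'
#' @param n_runs Number of feedback runs.
#' @param trials_per_run Trials per run; must be even (balanced hands).
#' @param trial_length_s Trial duration in seconds.
#' @param rest_end_s End of the pre-cue rest period (s).
#' @param cue_onset_s Cue time (s), >= rest_end_s.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param montage Data frame of channel positions as from [montage_1020()].
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(n_runs = 3, trials_per_run = 40, trial_length_s = 8,
                         rest_end_s = 3, cue_onset_s = 3,
                         sample_rate_hz = 250, montage = montage_1020()) {
  if (trials_per_run %% 2 != 0) stop("trials_per_run must be even")
  if (!(0 < rest_end_s && rest_end_s <= cue_onset_s &&
        cue_onset_s < trial_length_s)) {
    stop("need 0 < rest_end_s <= cue_onset_s < trial_length_s")
  }
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  structure(list(n_runs = n_runs, trials_per_run = trials_per_run,
                 trial_length_s = trial_length_s, rest_end_s = rest_end_s,
                 cue_onset_s = cue_onset_s, sample_rate_hz = sample_rate_hz,
                 montage = montage),
            class = "session_spec")
}

#' Cohort specification
#'
#' @param n_subjects Number of subjects (>= 2; 55 matches the reference
#'   study population).
#' @param acc_high_mean,acc_high_sd Mean/SD (percent) of the online BCI
#'   accuracy distribution for the high-aptitude latent class (defaults
#'   77.17 / 5.44).
#' @param acc_low_mean,acc_low_sd Same for the low-aptitude class
#'   (defaults 67.19 / 2.96). Draws are truncated to [0, 100].
#' @param prop_high Proportion of subjects in the high class.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 55, acc_high_mean = 77.17,
                        acc_high_sd = 5.44, acc_low_mean = 67.19,
                        acc_low_sd = 2.96, prop_high = 0.5) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  structure(list(n_subjects = n_subjects,
                 acc_high_mean = acc_high_mean, acc_high_sd = acc_high_sd,
                 acc_low_mean = acc_low_mean, acc_low_sd = acc_low_sd,
                 prop_high = prop_high),
            class = "cohort_spec")
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) wrapped-Cauchy rejection sampler. kappa = 0 returns
#' uniform angles; kappa = Inf returns mu exactly.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0, may be Inf).
#' @return Numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (is.infinite(kappa)) return(rep(wrap_angle(mu), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- wrap_angle(mu + sign(u3 - 0.5) * acos(f))
      i <- i + 1L
    }
  }
  out
}

# wrap angle(s) to (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# 1/f^beta Gaussian noise with unit RMS, length n, sampling rate fs
pink_noise <- function(n, beta, fs) {
  w <- stats::rnorm(n)
  if (beta == 0) {
    x <- w
  } else {
    W <- stats::fft(w)
    f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
    f[f > fs / 2] <- fs - f[f > fs / 2]  # fold to physical frequency
    amp <- c(0, f[-1]^(-beta / 2))       # kill DC
    x <- Re(stats::fft(W * amp, inverse = TRUE)) / n
  }
  x / sqrt(mean(x^2))
}

#' Generate one synthetic motor-imagery trial
#'
#' Each channel carries a narrow-band oscillator at the [source_spec()]'s
#' center frequency with a random per-trial initial phase and frequency
#' jitter.
#' For each coupled pair, the destination oscillator replaces its own phase
#' with the source's phase plus a von Mises offset: one offset for the
#' pre-cue rest segment, one for the post-cue segment of the active
#' condition, blended over a short 0.25 s ramp at the cue so the waveform
#' stays continuous. 1/f^beta noise is added at the [source_spec()]'s SNR.
#'
#' @param spec A [source_spec()].
#' @param session A [session_spec()].
#' @param condition "left" or "right".
#' @param seed Optional integer seed for this trial.
#' @return Numeric matrix, channels x samples.
#' @export
generate_trial <- function(spec, session, condition, seed = NULL) {
  stopifnot(inherits(spec, "source_spec"), inherits(session, "session_spec"))
  if (!condition %in% c("left", "right")) {
    stop("condition must be 'left' or 'right'")
  }
  if (!is.null(seed)) set.seed(seed)
  chans <- session$montage$channel
  if (!is.null(spec$coupling)) {
    bad <- setdiff(unique(c(spec$coupling$src, spec$coupling$dst)), chans)
    if (length(bad) > 0L) {
      stop("coupling references unknown channel(s): ",
           paste(bad, collapse = ", "))
    }
  }
  fs <- session$sample_rate_hz
  n <- round(session$trial_length_s * fs)
  t <- (seq_len(n) - 1L) / fs
  nch <- length(chans)

  # independent oscillator phases
  fjit <- stats::runif(nch, -spec$freq_jitter_hz, spec$freq_jitter_hz)
  phi0 <- stats::runif(nch, 0, 2 * pi)
  theta <- outer(2 * pi * (spec$band_center_hz + fjit), t) + phi0

  # impose coupling: dst phase = src phase + per-trial von Mises offset,
  # rest-segment offset before the cue, condition offset after, short ramp
  if (!is.null(spec$coupling) && nrow(spec$coupling) > 0L) {
    kcol <- paste0("kappa_mi_", condition)
    ramp_s <- 0.25
    w <- pmin(pmax((t - session$cue_onset_s) / ramp_s, 0), 1)
    for (k in seq_len(nrow(spec$coupling))) {
      src <- match(spec$coupling$src[k], chans)
      dst <- match(spec$coupling$dst[k], chans)
      d_rest <- rvonmises(1, 0, spec$coupling$kappa_rest[k])
      d_task <- rvonmises(1, 0, spec$coupling[[kcol]][k])
      # interpolate along the shortest angular arc
      step <- wrap_angle(d_task - d_rest)
      theta[dst, ] <- theta[src, ] + d_rest + w * step
    }
  }

  sig <- spec$amplitude * cos(theta)
  if (is.finite(spec$snr)) {
    src_rms <- spec$amplitude / sqrt(2)
    noise_rms <- src_rms / spec$snr
    for (ch in seq_len(nch)) {
      sig[ch, ] <- sig[ch, ] +
        noise_rms * pink_noise(n, spec$noise_exponent, fs)
    }
  }
  rownames(sig) <- chans
  sig
}

#' Generate one subject's full epoched session
#'
#' @param spec A [source_spec()] for the subject's latent class.
#' @param session A [session_spec()].
#' @param subject_id Subject identifier.
#' @param seed Integer seed; the subject's trials are drawn from this
#'   RNG stream (per-run hand order is shuffled within the same stream).
#' @return An [eeg_epochs()] object with n_runs x trials_per_run trials.
#' @export
generate_subject <- function(spec, session, subject_id = "S01", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- session$sample_rate_hz
  n_samp <- round(session$trial_length_s * fs)
  n_per_run <- session$trials_per_run
  n_trials <- session$n_runs * n_per_run
  chans <- session$montage$channel
  dat <- array(NA_real_, c(n_trials, length(chans), n_samp))
  labels <- character(n_trials)
  run_idx <- integer(n_trials)
  trial_idx <- integer(n_trials)
  i <- 0L
  for (r in seq_len(session$n_runs)) {
    hands <- sample(rep(c("left", "right"), each = n_per_run / 2))
    for (j in seq_len(n_per_run)) {
      i <- i + 1L
      dat[i, , ] <- generate_trial(spec, session, hands[j])
      labels[i] <- hands[j]
      run_idx[i] <- r
      trial_idx[i] <- j
    }
  }
  eeg_epochs(dat, chans,
             as.matrix(session$montage[, c("x", "y", "z")]),
             fs, t0 = 0, labels = labels, subject_id = subject_id,
             run = run_idx, trial = trial_idx)
}

#' Draw per-subject online BCI accuracies
#'
#' Assigns each subject a latent aptitude class (high/low, balanced to
#' `prop_high`, order shuffled) and draws its accuracy from the class's
#' Gaussian truncated to [0, 100].
#'
#' @param cohort A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return A tibble: subject_id, latent_class, accuracy_percent.
#' @export
draw_accuracies <- function(cohort, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- cohort$n_subjects
  n_high <- round(n * cohort$prop_high)
  cls <- sample(c(rep("high", n_high), rep("low", n - n_high)))
  rtruncnorm01 <- function(m, s) {
    repeat {
      x <- stats::rnorm(1, m, s)
      if (x >= 0 && x <= 100) return(x)
    }
  }
  acc <- vapply(cls, function(cl) {
    if (cl == "high") rtruncnorm01(cohort$acc_high_mean, cohort$acc_high_sd)
    else rtruncnorm01(cohort$acc_low_mean, cohort$acc_low_sd)
  }, numeric(1))
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    latent_class = cls,
    accuracy_percent = unname(acc))
}

#' Generate a synthetic cohort
#'
#' Draws latent classes and accuracies, then generates each subject's
#' epoched session from the class's source specification.
#'
#' @param cohort A [cohort_spec()].
#' @param session A [session_spec()].
#' @param high_spec,low_spec [source_spec()]s for the two latent classes.
#' @param seed Integer seed (reproducible: same seed, same cohort).
#' @return List with `accuracy` (tibble as [draw_accuracies()]) and
#'   `subjects` (named list of [eeg_epochs()]).
#' @export
generate_cohort <- function(cohort, session, high_spec, low_spec,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  acc <- draw_accuracies(cohort)
  subject_seeds <- sample.int(.Machine$integer.max, cohort$n_subjects)
  subjects <- vector("list", cohort$n_subjects)
  names(subjects) <- acc$subject_id
  for (i in seq_len(cohort$n_subjects)) {
    sp <- if (acc$latent_class[i] == "high") high_spec else low_spec
    subjects[[i]] <- generate_subject(sp, session, acc$subject_id[i],
                                      seed = subject_seeds[i])
  }
  list(accuracy = acc, subjects = subjects)
}
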