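#' Qualitative replication scenario: right-hemisphere MI coupling
#'
#' Simulates a cohort in which high-aptitude subjects have elevated phase
#' coupling between C4 and its surrounding right-hub electrodes during the
#' motor-imagery segment (both hands), runs the full preprocessing +
#' connectivity + scale aggregation + median split + permutation ANOVA
#' chain, and returns the group/hand/interaction p-values per network
#' scale for the motor-imagery window in the alpha band.
#'
#' Besides the class-specific coupling, every subject receives an
#' idiosyncratic baseline coupling level (a per-subject concentration
#' drawn uniformly from `kappa_base_range`, applied to a ring of
#' neighbouring-electrode pairs spanning the montage, identically at rest
#' and during MI and identically for both classes). This emulates the
#' stable individual differences in overall synchronization seen in real
#' cohorts; without it the global-scale mean would have unrealistically
#' little between-subject variance.
#'
#' @param seed Integer seed.
#' @param n_subjects Cohort size (odd, so the median subject is excluded;
#'   default 17 giving an 8/8 comparison).
#' @param trials_per_run,n_runs Session size (defaults 24 trials x 1 run,
#'   12 per hand).
#' @param kappa_high MI-segment concentration of the high class's
#'   right-hub pairs (default 1.2).
#' @param kappa_base Concentration of those pairs otherwise (default 0.2).
#' @param kappa_base_range Range of the per-subject baseline ring
#'   concentration (default c(0.05, 2)).
#' @param snr Source-to-noise ratio (default 3).
#' @param n_perm Permutations for the ANOVA (default 999).
#' @return Tibble: scale, effect, F_obs, p_perm (window mi, band alpha).
#' @export
run_group_replication <- function(seed, n_subjects = 17,
                                  trials_per_run = 24, n_runs = 1,
                                  kappa_high = 1.2, kappa_base = 0.2,
                                  kappa_base_range = c(0.05, 2),
                                  snr = 3, n_perm = 999) {
  set.seed(seed)
  session <- session_spec(n_runs = n_runs, trials_per_run = trials_per_run)
  cohort <- cohort_spec(n_subjects = n_subjects)
  acc <- draw_accuracies(cohort)
  subject_seeds <- sample.int(.Machine$integer.max, n_subjects)
  kappa_subj <- stats::runif(n_subjects, kappa_base_range[1],
                             kappa_base_range[2])

  # baseline coupling ring over neighbouring montage channels, bypassing
  # C4 and its hub neighbours so the ring shares no oscillator with the
  # class-specific right neighbourhood (otherwise left-hub channels would
  # inherit part of the class effect through the chain)
  nb <- c("FC6", "FC2", "CP6", "CP2")
  ring_chans <- setdiff(session$montage$channel, c("C4", nb))
  ring <- data.frame(src = ring_chans[-length(ring_chans)],
                     dst = ring_chans[-1], stringsAsFactors = FALSE)
  band <- band_spec("alpha", 10.5, 0.3)
  windows <- default_windows()

  scale_rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    k_task <- if (acc$latent_class[i] == "high") kappa_high else kappa_base
    # ring first, class-specific C4 neighbourhood last: coupling rows are
    # applied in order and a later row overrides its destination's phase
    coupling <- rbind(
      data.frame(src = ring$src, dst = ring$dst,
                 kappa_rest = kappa_subj[i],
                 kappa_mi_left = kappa_subj[i],
                 kappa_mi_right = kappa_subj[i],
                 stringsAsFactors = FALSE),
      data.frame(src = "C4", dst = nb, kappa_rest = kappa_base,
                 kappa_mi_left = k_task, kappa_mi_right = k_task,
                 stringsAsFactors = FALSE))
    spec <- source_spec(coupling = coupling, snr = snr)
    ep <- generate_subject(spec, session, acc$subject_id[i],
                           seed = subject_seeds[i])
    ep <- preprocess_epochs(ep)
    phases <- extract_phase(ep, band)
    tabs <- list()
    for (cond in c("left", "right")) {
      tabs[[cond]] <- plv_matrix(phases, windows$mi, cond)
    }
    scale_rows[[i]] <- scale_average(dplyr::bind_rows(tabs),
                                     default_scales())
  }
  scales_tab <- dplyr::bind_rows(scale_rows)
  groups <- median_split(acc)
  set.seed(seed + 1L)
  res <- group_scale_anova(scales_tab, groups, n_perm = n_perm)
  res[, c("scale", "effect", "F_obs", "p_perm")]
}

#' Closed-form recovery of von Mises coupling as PLV
#'
#' Validation harness for the generator + phase-estimation path: simulates
#' `n_trials` noiseless trials per concentration kappa with a single
#' coupled pair (C4 driving FC6), band-pass filters, extracts alpha-band
#' Morlet phase and computes the pair's inter-trial PLV over a mid-trial
#' window. The estimate is compared against the von Mises mean resultant
#' length I1(kappa)/I0(kappa), the analytic expectation of the PLV under
#' the coupling model. Spatial filters (CAR, Laplacian) are deliberately
#' not applied: they remix sources across channels and so test a different
#' property.
#'
#' @param kappas Concentrations to probe (default c(0.5, 1, 2, 4)).
#' @param n_trials Trials per concentration (default 200).
#' @param seed Integer seed.
#' @return Tibble: kappa, plv_est, plv_expected.
#' @export
plv_recovery <- function(kappas = c(0.5, 1, 2, 4), n_trials = 200,
                         seed = 1) {
  set.seed(seed)
  mont <- montage_1020(c("C3", "C4", "FC6", "CP6"))
  session <- session_spec(n_runs = 1, trials_per_run = 2, montage = mont)
  band <- band_spec("alpha", 10.5, 0.3)
  w <- window_def("mid", 2.5, 5.5)
  n_samp <- round(session$trial_length_s * session$sample_rate_hz)
  out <- lapply(kappas, function(k) {
    spec <- source_spec(
      coupling = data.frame(src = "C4", dst = "FC6", kappa_rest = k,
                            kappa_mi_left = k, kappa_mi_right = k),
      snr = Inf)
    dat <- array(0, c(n_trials, nrow(mont), n_samp))
    for (tr in seq_len(n_trials)) {
      dat[tr, , ] <- generate_trial(spec, session, "left")
    }
    ep <- eeg_epochs(dat, mont$channel, as.matrix(mont[, c("x", "y", "z")]),
                     session$sample_rate_hz,
                     labels = rep("left", n_trials))
    ep <- bandpass(ep)
    phases <- extract_phase(ep, band)
    tibble::tibble(kappa = k,
                   plv_est = plv_pair(phases, "C4", "FC6", w),
                   plv_expected = besselI(k, 1) / besselI(k, 0))
  })
  dplyr::bind_rows(out)
}
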