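test_that("session bookkeeping matches the session_spec for every generated subject", {
  sess <- session_spec(n_runs = 2, trials_per_run = 8)
  spec <- source_spec(snr = 5)
  ep <- generate_subject(spec, sess, "S01", seed = 3)
  d <- epoch_dims(ep)
  expect_equal(unname(d["trials"]), 16L)
  expect_equal(unname(d["samples"]), 2000L)
  expect_equal(sum(ep$labels == "left"), 8L)
  expect_equal(sum(ep$labels == "right"), 8L)
  expect_equal(ep$run, rep(1:2, each = 8L))
  # hands balanced within each run
  for (r in 1:2) {
    expect_equal(sum(ep$labels[ep$run == r] == "left"), 4L)
  }
  expect_true(all(is.finite(ep$data)))
})

test_that("identical seeds give bit-identical output", {
  sess <- session_spec(n_runs = 1, trials_per_run = 4)
  spec <- source_spec()
  a <- generate_subject(spec, sess, "S01", seed = 11)
  b <- generate_subject(spec, sess, "S01", seed = 11)
  expect_identical(a$data, b$data)
  expect_identical(a$labels, b$labels)
})

test_that("generated band power concentrates near the oscillator frequency", {
  sess <- session_spec(n_runs = 1, trials_per_run = 2)
  spec <- source_spec(band_center_hz = 10.5, snr = 3)
  ep <- generate_subject(spec, sess, "S01", seed = 4)
  n <- 2000
  freqs <- (0:(n - 1)) * 250 / n
  for (ch in c(1, 8, 16)) {
    pw <- Mod(fft(ep$data[1, ch, ]))^2
    half <- freqs <= 125
    peak <- freqs[half][which.max(pw[half])]
    expect_lt(abs(peak - 10.5), 3)
  }
})

test_that("session and source configuration errors are caught", {
  expect_error(session_spec(trials_per_run = 5), "even")
  expect_error(session_spec(sample_rate_hz = -1), "positive")
  expect_error(session_spec(rest_end_s = 5, cue_onset_s = 3), "cue_onset")
  expect_error(source_spec(coupling = data.frame(
    src = "C3", dst = "C4", kappa_rest = -1,
    kappa_mi_left = 0, kappa_mi_right = 0)), "kappa")
  bad <- source_spec(coupling = data.frame(
    src = "C3", dst = "NOPE", kappa_rest = 1,
    kappa_mi_left = 1, kappa_mi_right = 1))
  expect_error(generate_trial(bad, session_spec(), "left"), "NOPE")
  expect_error(generate_trial(source_spec(), session_spec(), "up"),
               "left|right")
})

test_that("von Mises draws have the Bessel-ratio mean resultant length", {
  set.seed(9)
  for (k in c(0.5, 2)) {
    th <- rvonmises(20000, 0, k)
    expect_true(all(abs(th) <= pi))
    expect_lt(abs(Mod(mean(exp(1i * th))) - besselI(k, 1) / besselI(k, 0)),
              0.02)
  }
  expect_identical(rvonmises(3, 0.5, Inf), rep(0.5, 3))
  set.seed(10)
  u <- rvonmises(20000, 0, 0)
  expect_lt(Mod(mean(exp(1i * u))), 0.02)
})

test_that("perfect coupling yields PLV 1 and no coupling stays at the noise floor", {
  sess <- session_spec(n_runs = 1, trials_per_run = 2,
                       montage = montage_1020(c("C3", "C4", "FC6", "CP6")))
  lock <- source_spec(coupling = data.frame(
    src = "C4", dst = "FC6", kappa_rest = Inf,
    kappa_mi_left = Inf, kappa_mi_right = Inf), snr = Inf)
  n_tr <- 30
  dat <- array(0, c(n_tr, 4, 2000))
  set.seed(21)
  for (tr in seq_len(n_tr)) dat[tr, , ] <- generate_trial(lock, sess, "left")
  ep <- eeg_epochs(dat, sess$montage$channel,
                   as.matrix(sess$montage[, c("x", "y", "z")]), 250,
                   labels = rep("left", n_tr))
  phases <- extract_phase(bandpass(ep), band_spec("alpha", 10.5, 0.3))
  w <- window_def("mid", 2.5, 5.5)
  expect_gt(plv_pair(phases, "C4", "FC6", w), 0.99)
  # uncoupled channels: near the small-sample Rayleigh floor, far from 1
  floor_expect <- sqrt(pi / (4 * n_tr))
  expect_lt(plv_pair(phases, "C3", "CP6", w), floor_expect + 0.25)
})

test_that("cohort accuracies follow the latent classes and trial sets are complete", {
  acc <- draw_accuracies(cohort_spec(n_subjects = 40), seed = 2)
  expect_equal(nrow(acc), 40L)
  expect_true(all(acc$accuracy_percent >= 0 & acc$accuracy_percent <= 100))
  expect_equal(sum(acc$latent_class == "high"), 20L)
  expect_gt(mean(acc$accuracy_percent[acc$latent_class == "high"]),
            mean(acc$accuracy_percent[acc$latent_class == "low"]))
  # minimal two-subject cohort with full (tiny) trial sets
  sess <- session_spec(n_runs = 1, trials_per_run = 2)
  co <- generate_cohort(cohort_spec(n_subjects = 2), sess,
                        source_spec(), source_spec(), seed = 5)
  expect_length(co$subjects, 2L)
  for (s in co$subjects) {
    expect_equal(unname(epoch_dims(s)["trials"]), 2L)
  }
})
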