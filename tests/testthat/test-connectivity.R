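test_that("Morlet kernel matches its closed form and peaks at fc", {
  alpha <- band_spec("alpha", 10.5, 0.3)
  psi <- cmw_kernel(alpha, 250)
  n <- length(psi)
  expect_true(n %% 2 == 1)
  center <- (n + 1) / 2
  expect_equal(Mod(psi[center]), (pi * 0.3)^(-0.5), tolerance = 1e-12)
  # Gaussian envelope symmetry
  expect_equal(as.numeric(Mod(psi)), rev(as.numeric(Mod(psi))),
               tolerance = 1e-12)
  # ends below 1e-6 of the peak
  expect_lt(Mod(psi[1]) / Mod(psi[center]), 1e-6)
  # spectrum peaks at fc within one FFT bin
  nfft <- 8192
  spec <- Mod(fft(c(unclass(psi), rep(0, nfft - n))))
  freqs <- (0:(nfft - 1)) * 250 / nfft
  peak <- freqs[which.max(spec)]
  expect_lt(abs(peak - 10.5), 250 / nfft + 1e-9)
  expect_error(cmw_kernel(alpha, 20), "twice")
})

test_that("extracted phase tracks an analytic tone and preserves offsets", {
  alpha <- band_spec("alpha", 10.5, 0.3)
  ph <- extract_phase(tone_epochs(10.5), alpha)
  v <- which(ph$valid_mask)
  inst <- ph$phase[1, 1, v]
  slope <- mean(diff(inst) %% (2 * pi)) * 250 / (2 * pi)
  expect_lt(abs(slope / 10.5 - 1), 0.01)
  # quarter-cycle offset between two recordings
  ph2 <- extract_phase(tone_epochs(10.5, phase = pi / 2), alpha)
  dphi <- Arg(exp(1i * (ph2$phase[1, 1, v] - ph$phase[1, 1, v])))
  expect_lt(max(abs(dphi - pi / 2)), 0.02)
  # trial shorter than the kernel
  short <- eeg_epochs(array(rnorm(2 * 16 * 100), c(2, 16, 100)),
                      montage_channels(), pos16, 250)
  expect_error(extract_phase(short, alpha), "shorter")
})

test_that("PLV matches a naive loop implementation to 1e-10", {
  set.seed(33)
  phase <- array(runif(5 * 3 * 50, -pi, pi), c(5, 3, 50))
  pt <- make_phase_tensor(phase)
  w <- window_def("all", 0, 1)
  naive_plv <- function(ph, i, j) {
    S <- dim(ph)[3]; N <- dim(ph)[1]
    r <- numeric(S)
    for (s in seq_len(S)) {
      acc <- 0 + 0i
      for (n in seq_len(N)) acc <- acc + exp(1i * (ph[n, i, s] - ph[n, j, s]))
      r[s] <- Mod(acc) / N
    }
    mean(r)
  }
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_lt(abs(naive_plv(phase, pair[1], pair[2]) -
                    plv_pair(pt, pair[1], pair[2], w)), 1e-10)
  }
})

test_that("PLV hits its analytic anchors: locked = 1, antiphase-balanced = 0, uniform = Rayleigh floor", {
  w <- window_def("all", 0, 2)
  # identical phase sequences
  base <- array(runif(4 * 2 * 30, -pi, pi), c(4, 2, 30))
  base[, 2, ] <- base[, 1, ]
  expect_equal(plv_pair(make_phase_tensor(base), 1, 2, w), 1)
  # differences alternating 0, pi across an even number of trials
  alt <- array(0, c(4, 2, 30))
  alt[c(1, 3), 1, ] <- pi
  expect_equal(plv_pair(make_phase_tensor(alt), 1, 2, w), 0,
               tolerance = 1e-12)
  # iid uniform differences, N = 100: E[PLV] = sqrt(pi / (4 * 100))
  set.seed(44)
  unif <- array(runif(100 * 2 * 200, -pi, pi), c(100, 2, 200))
  est <- plv_pair(make_phase_tensor(unif), 1, 2, w)
  expect_lt(abs(est - sqrt(pi / 400)), 0.01)
})

test_that("PLV is amplitude-invariant and symmetric in the pair", {
  alpha <- band_spec("alpha", 10.5, 0.3)
  ep <- noise_epochs(n_trials = 6, seed = 7)
  w <- window_def("mid", 2.5, 5.5)
  ph <- extract_phase(ep, alpha)
  scaled <- ep; scaled$data[, 3, ] <- 17 * scaled$data[, 3, ]
  ph_s <- extract_phase(scaled, alpha)
  expect_equal(plv_pair(ph, 3, 5, w), plv_pair(ph_s, 3, 5, w),
               tolerance = 1e-9)
  expect_equal(plv_pair(ph, 3, 5, w), plv_pair(ph, 5, 3, w),
               tolerance = 1e-12)
  expect_error(plv_pair(ph, 3, 3, w), "self-pair")
})

test_that("plv_matrix covers all 120 pairs once, honoring trial labels", {
  alpha <- band_spec("alpha", 10.5, 0.3)
  ep <- noise_epochs(n_trials = 6, seed = 8)
  ph <- extract_phase(ep, alpha)
  w <- window_def("mid", 2.5, 5.5)
  tab <- plv_matrix(ph, w, "left")
  expect_equal(nrow(tab), choose(16, 2))
  expect_true(all(tab$plv >= 0 & tab$plv <= 1))
  idx_i <- match(tab$channel_i, montage_channels())
  idx_j <- match(tab$channel_j, montage_channels())
  expect_true(all(idx_i < idx_j))
  expect_false(any(duplicated(paste(tab$channel_i, tab$channel_j))))
  ph_left <- extract_phase(subset_trials(ep, ep$labels == "left"), alpha)
  expect_equal(tab$plv[tab$channel_i == "C3" & tab$channel_j == "C4"],
               plv_pair(ph_left, "C3", "C4", w), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(plv_matrix(ph, w, "up"), "no trials")
})

test_that("delta rows are mi minus rest, matched on keys", {
  alpha <- band_spec("alpha", 10.5, 0.3)
  ep <- noise_epochs(n_trials = 6, seed = 9)
  ph <- extract_phase(ep, alpha)
  w <- default_windows()
  rest <- plv_matrix(ph, w$rest, "left")
  mi <- plv_matrix(ph, w$mi, "left")
  d <- delta_plv(mi, rest)
  expect_equal(nrow(d), 120L)
  expect_true(all(d$window == "delta"))
  expect_equal(d$plv, mi$plv - rest$plv, tolerance = 1e-12)
  expect_equal(delta_plv(mi, mi)$plv, rep(0, 120L))
  broken <- rest[-5, ]
  expect_error(delta_plv(mi, broken), "mismatch")
})
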