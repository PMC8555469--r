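test_that("CAR removes the instantaneous channel mean and is idempotent", {
  ep <- noise_epochs(n_trials = 3, seed = 2)
  out <- common_average_reference(ep)
  for (tr in 1:3) {
    expect_lt(max(abs(colMeans(out$data[tr, , ]))), 1e-12)
  }
  twice <- common_average_reference(out)
  expect_equal(twice$data, out$data, tolerance = 1e-12)
  # all-equal channels become zero
  flat <- ep; flat$data[] <- 7
  expect_equal(max(abs(common_average_reference(flat)$data)), 0)
  # an already zero-mean pair is unchanged
  two <- eeg_epochs(array(rep(c(1, -1), 10), c(1, 2, 10)),
                    c("C3", "C4"),
                    as.matrix(montage_1020(c("C3", "C4"))[, c("x", "y", "z")]),
                    250)
  expect_equal(common_average_reference(two)$data, two$data)
  one <- eeg_epochs(array(1, c(1, 1, 10)), "Cz",
                    matrix(c(0, 0, 1), 1, 3), 250)
  expect_error(common_average_reference(one), "single channel")
})

test_that("band-pass keeps in-band tones, rejects 2 Hz and DC", {
  mid <- 500:1500  # clear of filtfilt edge transients
  tone20 <- bandpass(tone_epochs(20))
  in_rms <- sqrt(mean(tone_epochs(20)$data[1, 1, mid]^2))
  out_rms <- sqrt(mean(tone20$data[1, 1, mid]^2))
  expect_lt(abs(out_rms / in_rms - 1), 0.05)

  tone2 <- bandpass(tone_epochs(2))
  att <- sqrt(mean(tone2$data[1, 1, mid]^2)) /
    sqrt(mean(tone_epochs(2)$data[1, 1, mid]^2))
  expect_lt(20 * log10(att), -20)

  dc <- tone_epochs(20); dc$data <- dc$data + 3
  expect_lt(abs(mean(bandpass(dc)$data[1, 1, mid])), 0.05)

  expect_error(bandpass(tone_epochs(20), hi_hz = 130), "Nyquist")
})

test_that("band-pass FIR design attenuates like the IIR default", {
  ep <- tone_epochs(2, n_trials = 1)
  mid <- 500:1500
  out <- bandpass(ep, method = "fir")
  att <- sqrt(mean(out$data[1, 1, mid]^2)) / sqrt(mean(ep$data[1, 1, mid]^2))
  expect_lt(20 * log10(att), -20)
})

test_that("surface Laplacian nulls constant fields and localizes focal sources", {
  ep <- noise_epochs(n_trials = 1, seed = 3)
  flat <- ep; flat$data[] <- 4.2
  expect_lt(max(abs(surface_laplacian(flat)$data)), 1e-9)

  # Gaussian spatial profile centred on C4
  m <- montage_1020()
  c4 <- as.numeric(m[m$channel == "C4", c("x", "y", "z")])
  ang <- acos(pmin(1, as.matrix(m[, c("x", "y", "z")]) %*% c4))
  prof <- exp(-(ang / 0.5)^2)
  foc <- ep
  foc$data[1, , ] <- matrix(prof, 16, dim(ep$data)[3])
  lap <- surface_laplacian(foc)
  expect_equal(which.max(abs(lap$data[1, , 100])),
               which(montage_channels() == "C4"))

  # regularization strength changes the solution measurably
  a <- surface_laplacian(ep, lambda = 1e-5)
  b <- surface_laplacian(ep, lambda = 1e-2)
  expect_gt(max(abs(a$data - b$data)), 1e-3 * max(abs(a$data)))

  dup <- ep
  dup$positions[2, ] <- dup$positions[1, ]
  expect_error(surface_laplacian(dup), "duplicate")
})

test_that("preprocessing stages are linear and preserve trial metadata", {
  x <- noise_epochs(n_trials = 2, seed = 4)
  y <- noise_epochs(n_trials = 2, seed = 5)
  for (stage in list(common_average_reference,
                     function(e) bandpass(e),
                     function(e) surface_laplacian(e))) {
    mix <- x; mix$data <- 2 * x$data - 3 * y$data
    lhs <- stage(mix)$data
    rhs <- 2 * stage(x)$data - 3 * stage(y)$data
    expect_equal(lhs, rhs, tolerance = 1e-8)
    out <- stage(x)
    expect_identical(out$labels, x$labels)
    expect_identical(out$run, x$run)
    expect_identical(dim(out$data), dim(x$data))
  }
})

test_that("windows cut half-open sample ranges of the documented lengths", {
  ep <- noise_epochs(n_trials = 2, seed = 6)
  w <- default_windows()
  cut <- cut_windows(ep, w)
  expect_equal(unname(epoch_dims(cut$rest)["samples"]), 750L)   # 3 s
  expect_equal(unname(epoch_dims(cut$mi)["samples"]), 875L)     # 3.5 s
  full <- cut_windows(ep, window_def("all", 0, 8))
  expect_equal(unname(epoch_dims(full)["samples"]), 2000L)
  expect_identical(cut$rest$labels, ep$labels)
  expect_error(cut_windows(ep, window_def("late", 9, 10)), "no samples")
  expect_error(window_def("bad", 3, 3))
})
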