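# fixtures built in code: small epoch sets for unit tests

mont16 <- montage_1020()
pos16 <- as.matrix(mont16[, c("x", "y", "z")])

# epochs where every trial/channel carries the same deterministic signal
tone_epochs <- function(freq_hz, n_trials = 2, sfreq = 250, dur_s = 8,
                        phase = 0, amp = 1) {
  t <- (seq_len(dur_s * sfreq) - 1) / sfreq
  x <- amp * cos(2 * pi * freq_hz * t + phase)
  dat <- array(rep(x, each = n_trials * 16),
               c(n_trials, 16, length(t)))
  eeg_epochs(dat, montage_channels(), pos16, sfreq,
             labels = rep(c("left", "right"), length.out = n_trials))
}

# epochs filled with N(0, 1) noise
noise_epochs <- function(n_trials = 4, sfreq = 250, dur_s = 8, seed = 1) {
  set.seed(seed)
  n <- dur_s * sfreq
  dat <- array(rnorm(n_trials * 16 * n), c(n_trials, 16, n))
  eeg_epochs(dat, montage_channels(), pos16, sfreq,
             labels = rep(c("left", "right"), length.out = n_trials))
}

# phase tensor wrapping an explicit phase array (trials x channels x samples)
make_phase_tensor <- function(phase, sfreq = 250,
                              labels = rep("left", dim(phase)[1]),
                              channels = paste0("ch", seq_len(dim(phase)[2]))) {
  structure(
    list(phase = phase, valid_mask = rep(TRUE, dim(phase)[3]),
         times = (seq_len(dim(phase)[3]) - 1) / sfreq,
         band = band_spec("alpha", 10.5, 0.3),
         channels = channels, labels = labels,
         subject_id = "T01", sfreq = sfreq),
    class = "phase_tensor")
}
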