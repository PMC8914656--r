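test_that("zero-phase band-pass keeps the passband and kills the stopband", {
  fs <- 200
  t <- seq(0, 60, by = 1 / fs)
  rec <- eeg_recording(cbind(sin(2 * pi * 20 * t)), fs, "x")
  out <- fir_bandpass(rec)
  mid <- (10 * fs):(50 * fs)
  expect_rel(sqrt(mean(out$data[mid, 1]^2)), sqrt(0.5), 0.01)
  # 0.25 Hz sine attenuated by at least 40 dB
  slow <- eeg_recording(cbind(sin(2 * pi * 0.25 * t)), fs, "x")
  outs <- fir_bandpass(slow)
  expect_lt(sqrt(mean(outs$data[mid, 1]^2)) / sqrt(0.5), 10^(-40 / 20))
  # impulse response is symmetric about the impulse (zero phase)
  n <- 2^15
  imp <- numeric(n); imp[n / 2] <- 1
  oi <- fir_bandpass(eeg_recording(cbind(imp), fs, "x"))$data[, 1]
  k <- 2000
  expect_equal(oi[(n / 2 - k):(n / 2 - 1)], rev(oi[(n / 2 + 1):(n / 2 + k)]),
               tolerance = 1e-9)
  expect_error(fir_bandpass(eeg_recording(cbind(rnorm(100)), fs, "x")),
               "too short")
})

test_that("artifact-subspace reconstruction is conservative on clean data", {
  rec <- generate_recording(duration = 120, seed = 8)
  res <- asr_clean(rec)
  # nothing exceeds the threshold: output equals input within 1% RMS
  expect_lt(sqrt(mean((res$recording$data - rec$data)^2)) /
              sqrt(mean(rec$data^2)), 0.01)
  # infinite cutoff: identity transform, zero reconstructed fraction
  resi <- asr_clean(rec, cutoff_k = Inf)
  expect_equal(resi$reconstructed_fraction, 0)
  short <- eeg_recording(matrix(rnorm(200 * 6), 200, 6), 200,
                         headband_channels())
  expect_error(asr_clean(short), "calibration")
})

test_that("artifact-subspace reconstruction suppresses motion bursts", {
  rec <- generate_recording(duration = 120, seed = 9)
  inj <- inject_artifacts(rec, blink_rate = 0, motion_rate = 3,
                          line_amp = 0, seed = 10)
  res <- asr_clean(inj$recording)
  expect_gt(res$reconstructed_fraction, 0)
  bg <- apply(rec$data, 2, sd)
  ev <- inj$events[inj$events$type == "motion", ]
  fs <- rec$fs
  for (r in seq_len(nrow(ev))) {
    idx <- round(ev$onset_s[r] * fs) + seq_len(round(ev$duration_s[r] * fs))
    rms <- sqrt(colMeans(res$recording$data[idx, ]^2))
    expect_true(all(rms <= 2 * bg))
  }
})

test_that("ICA separates non-Gaussian sources and is deterministic", {
  fs <- 200
  t <- seq(0, 40, by = 1 / fs)
  s1 <- sin(2 * pi * 7 * t)
  s2 <- 2 * (2 * ((5 * t) %% 1) - 1)              # sawtooth
  set.seed(12)
  A <- matrix(rnorm(4), 2, 2)
  X <- cbind(s1, s2) %*% t(A)
  ica <- ica_unmix(X, seed = 3, fs = fs)
  cors <- abs(cor(t(ica$components), cbind(s1, s2)))
  # each true source matched by some component up to sign/permutation
  expect_gt(max(cors[, 1]), 0.95)
  expect_gt(max(cors[, 2]), 0.95)
  # unmixing inverts mixing
  expect_equal(ica$unmixing %*% ica$mixing, diag(2), tolerance = 1e-6)
  # fixed seed -> identical decomposition
  ica2 <- ica_unmix(X, seed = 3, fs = fs)
  expect_identical(ica$components, ica2$components)
  # rank-deficient data rejected with advice
  Xr <- cbind(s1, s1)
  expect_error(ica_unmix(Xr, seed = 1, fs = fs), "rank-deficient")
})

test_that("component classification follows the frontal/low-frequency rules", {
  fs <- 200
  dur <- 60
  n <- dur * fs
  # constructed decomposition: blink-like, line, and beta components
  blink <- generate_band_signal(c(1, 4), 1, dur, fs, seed = 1)
  line <- sin(2 * pi * 50 * seq(0, dur, length.out = n))
  beta <- generate_band_signal("beta", 1, dur, fs, seed = 2)
  comps <- rbind(blink / sd(blink), line / sd(line), beta / sd(beta))
  mixing <- cbind(c(1, 0.9, 0.2, 0.2, 0.05, 0.05),   # frontal loading
                  rep(1, 6),
                  rep(1, 6))
  ica <- structure(list(components = comps, mixing = mixing,
                        unmixing = t(mixing),   # unused by the classifier
                        means = rep(0, 6), channels = headband_channels(),
                        fs = fs, converged = TRUE, iterations = 1L),
                   class = "ica_decomposition")
  labels <- classify_components(ica)
  expect_equal(unclass(labels)[1:3], c("ocular", "line", "brain"))
})

test_that("component removal reprojects exactly", {
  rec <- generate_recording(duration = 60, seed = 14)
  ica <- ica_unmix(rec, seed = 4)
  all_brain <- rep("brain", 6)
  out <- remove_components(rec, ica, all_brain)
  expect_lt(max(abs(out$data - rec$data)), 1e-9)
  none <- remove_components(rec, ica, rep("ocular", 6))
  expect_lt(max(abs(sweep(none$data, 2, colMeans(rec$data)))), 1e-9)
})

test_that("blink components are found and removed when ASR leaves them", {
  rec <- generate_recording(duration = 90, seed = 15)
  inj <- inject_artifacts(rec, blink_rate = 15, motion_rate = 0,
                          line_amp = 0, seed = 16)
  filtered <- fir_bandpass(inj$recording)
  ica <- ica_unmix(filtered, seed = 6)
  labels <- classify_components(ica)
  expect_true("ocular" %in% labels)
  clean <- remove_components(filtered, ica, labels)
  fs <- rec$fs
  ev <- inj$events
  idx <- unlist(lapply(seq_len(nrow(ev)), function(r)
    round(ev$onset_s[r] * fs) + seq_len(round(0.4 * fs))))
  rms_before <- sqrt(mean(filtered$data[idx, "Fp1"]^2))
  rms_after <- sqrt(mean(clean$data[idx, "Fp1"]^2))
  expect_lt(rms_after, 0.3 * rms_before)
})

test_that("the full pipeline barely moves band powers of clean data", {
  rec <- generate_recording(duration = 240, seed = 17)
  truth <- attr(rec, "true_band_powers")
  pp <- preprocess_recording(rec, seed = 18)
  tab <- session_band_table(pp$recording)
  rel <- abs(tab / truth - 1)
  expect_lt(max(rel), 0.10)
  expect_lt(max(rel[, "beta"]), 0.05)
})
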