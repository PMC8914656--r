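cfg <- sensor_config()

test_that("analog transfer function matches the band-pass model", {
  # double zero at DC
  expect_equal(Mod(analog_transfer(0, cfg)), 0)
  # mid-band magnitude, frozen from an independent magnitude-formula
  # evaluation with the default constants
  expect_rel(Mod(analog_transfer(5, cfg)), 4399.07, 1e-4)
  expect_equal(Mod(analog_transfer(5, cfg)), href_mag(5), tolerance = 1e-12)
  # +40 dB/decade low-frequency slope
  slope <- 20 * log10(Mod(analog_transfer(0.01, cfg)) /
                      Mod(analog_transfer(0.001, cfg)))
  expect_lt(abs(slope - 40), 0.1)
  # -60 dB/decade high-frequency slope
  slope_hi <- 20 * log10(Mod(analog_transfer(1e5, cfg)) /
                         Mod(analog_transfer(1e4, cfg)))
  expect_lt(abs(slope_hi + 60), 0.2)
  # exactly one interior maximum in (0, 60) Hz
  f <- seq(0.05, 60, by = 0.05)
  m <- Mod(analog_transfer(f, cfg))
  d <- diff(m)
  expect_equal(sum(d[-length(d)] > 0 & d[-1] <= 0), 1L)
  expect_error(analog_transfer(-1, cfg))
})

test_that("front-end simulation reproduces the analog gain and offset", {
  quiet <- sensor_config(noise_density = 0)
  fs <- quiet$fs_over
  # zero input, no noise: settles to the reference voltage
  out <- simulate_front_end(numeric(fs * 5), quiet)
  expect_lt(max(abs(out[(3 * fs):(5 * fs)] - quiet$v_ref)), 1e-9)
  # a 10 Hz, 100 uV sine comes out scaled by |H(10)| within 1%
  t <- seq(0, 10, by = 1 / fs)
  out <- simulate_front_end(1e-4 * sin(2 * pi * 10 * t), quiet)
  amp <- (max(out[t > 5]) - min(out[t > 5])) / 2
  expect_rel(amp, 1e-4 * Mod(analog_transfer(10, cfg)), 0.01)
  expect_error(simulate_front_end(numeric(50), quiet), "too short")
})

test_that("simulated amplifier noise matches the chain's noise bandwidth", {
  # analytic equivalent noise bandwidth of |H|^2 (normalized to G)
  enbw <- integrate(function(f) (href_mag(f) / sensor_gain(cfg))^2,
                    0, Inf, rel.tol = 1e-9)$value
  pred <- cfg$noise_density * sqrt(enbw)
  fs <- cfg$fs_over
  out <- simulate_front_end(numeric(fs * 60), cfg, seed = 3)
  measured <- sd(out[(5 * fs):(fs * 60)]) / sensor_gain(cfg)
  expect_rel(measured, pred, 0.05)
  # the budget's rectangular-band sigma_a is a slight overestimate of the
  # realized chain noise; they agree to ~15%
  sig_a <- noise_budget(cfg)$sigma_a
  expect_rel(measured, sig_a, 0.15)
})

test_that("quantization and block summing preserve scale and conserve means", {
  fs <- cfg$fs_over
  # constant reference input -> mid-scale datum 16 x 2048
  cs <- quantize_and_oversample(rep(cfg$v_ref, fs), cfg)
  expect_true(all(cs$data == 16 * 2048))
  # all-zero input -> all-zero data
  cs0 <- quantize_and_oversample(numeric(fs), cfg)
  expect_true(all(cs0$data == 0))
  # block means conserved exactly for constant blocks
  v <- rep(runif(50, 0, cfg$v_supply), each = cfg$oversample_factor)
  cs2 <- quantize_and_oversample(v, cfg)
  lsb <- cfg$v_supply / 2^cfg$adc_bits
  codes <- pmin(round(unique(v) / lsb), 2^cfg$adc_bits - 1)
  expect_equal(cs2$data / cfg$oversample_factor, codes)
  # trailing remainder dropped with a warning
  expect_warning(quantize_and_oversample(numeric(33), cfg), "remainder")
  # out-of-range samples clipped and counted
  cs3 <- suppressWarnings(
    quantize_and_oversample(c(rep(-1, 16), rep(cfg$v_ref, 16)), cfg))
  expect_equal(cs3$clip_fraction, 0.5)
})

test_that("block summing improves the SNR by sqrt(k)", {
  r <- snr_improvement_experiment(seed = 1, n_blocks = 2e4)
  expect_lt(abs(r$ratio - 4), 0.1)
  for (k in c(4L, 9L, 25L)) {
    rk <- snr_improvement_experiment(seed = k, n_blocks = 2e4, k = k)
    expect_lt(abs(rk$ratio - sqrt(k)), 0.1)
  }
  expect_true(is.infinite(
    snr_improvement_experiment(1, 1e4, noise_sd = 0)$ratio))
})

test_that("count conversion inverts the wire encoding", {
  rec <- counts_to_input_microvolts(rep(32768, 10), cfg)
  expect_equal(unname(rec$data[, 1]), rep(0, 10))
  rec2 <- counts_to_input_microvolts(rep(0, 5), cfg, gain = 4488)
  expect_rel(rec2$data[1, 1], -367.6, 1e-3)
  expect_error(counts_to_input_microvolts(c(-1, 3), cfg), "non-negative")
  expect_error(counts_to_input_microvolts(c(0.5, 3), cfg), "integer")
})

test_that("simulate -> quantize -> convert round trip recovers a sine", {
  quiet <- sensor_config(noise_density = 0)
  fs <- quiet$fs_over
  t <- seq(0, 12, by = 1 / fs)[seq_len(12 * fs)]
  out <- simulate_front_end(1e-4 * sin(2 * pi * 10 * t), quiet)
  cs <- quantize_and_oversample(out, quiet)
  rec <- counts_to_input_microvolts(cs, quiet,
                                    gain = Mod(analog_transfer(10, quiet)))
  x <- rec$data[(4 * quiet$fs_out):(12 * quiet$fs_out), 1]
  expect_rel(sqrt(mean(x^2)), 100 / sqrt(2), 0.02)
})

test_that("noise budget reproduces the design arithmetic", {
  nb <- noise_budget(cfg, band = c(0.8, 44))
  expect_equal(round(nb$sigma_a * 1e9), 230)
  # formula quantization noise is ~52 nV at the nominal gain
  expect_rel(nb$sigma_q, 51.8e-9, 0.01)
  nb60 <- noise_budget(cfg, band = c(0.8, 44), sigma_q_override = 60e-9)
  expect_equal(signif(nb60$sigma_total, 2), 240e-9)
  expect_equal(nb60$sigma_oversampled * 4, nb60$sigma_total)
  expect_equal(round(nb60$lsb_14bit * 1e9), 43)
  # monotone in each component
  expect_gte(nb60$sigma_total, max(nb60$sigma_a, nb60$sigma_q))
  # zero-noise configuration: unbounded effective resolution
  z <- noise_budget(sensor_config(noise_density = 0), sigma_q_override = 0)
  expect_true(is.infinite(z$enob))
  expect_equal(z$sigma_total, 0)
})

test_that("configuration invariants are enforced", {
  expect_error(sensor_config(fs_over = 1000), "fs_out")
  expect_error(sensor_config(v_ref = 1), "v_supply / 2")
  expect_error(sensor_config(g1 = -1), "positive")
  # key-value config file round trip
  path <- tempfile()
  writeLines(c("g1 680", "g2: 6.6", "noise_density 35e-9"), path)
  cfg2 <- read_sensor_config(path)
  expect_equal(cfg2$g1, 680)
  expect_equal(cfg2$noise_density, 35e-9)
})
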