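test_that("input uncertainty propagates stimulus and attenuator terms", {
  expect_equal(input_uncertainty(2.4, 0, 0.303e-3, 0), 0)
  expect_rel(input_uncertainty(2.4, 1e-3, 0.303e-3, 3e-6), 7.206e-6, 1e-3)
  # Monte-Carlo oracle
  set.seed(42)
  vg <- 1.7; u_vg <- 5e-3; alpha <- 0.303e-3; u_alpha <- 3e-6
  draws <- rnorm(1e6, vg, u_vg) * rnorm(1e6, alpha, u_alpha)
  expect_rel(input_uncertainty(vg, u_vg, alpha, u_alpha), sd(draws), 0.02)
})

test_that("least-squares gain is exact, offset-invariant and scale-equivariant", {
  vin <- seq(30e-6, 730e-6, length.out = 47)
  expect_equal(fit_gain(vin, 4488 * vin), 4488)
  expect_equal(fit_gain(vin, 4488 * vin + 0.3), 4488)
  # independent normal-equations oracle on perturbed data
  for (s in 1:5) {
    set.seed(s)
    vad <- 4488 * vin + rnorm(47, 0, 1e-3)
    expect_rel(fit_gain(vin, vad),
               unname(coef(lm(vad ~ vin))["vin"]), 1e-9)
    # scaling the output scales the slope
    expect_equal(fit_gain(vin, 2 * vad), 2 * fit_gain(vin, vad))
  }
  expect_error(fit_gain(rep(1e-3, 5), 1:5), "distinct")
})

test_that("output uncertainty combines type A and type B in quadrature", {
  expect_equal(output_uncertainty(rep(1.3, 20), u_b = 2e-3), 2e-3)
  set.seed(7)
  r <- rnorm(20, 1, 0.01)
  expect_equal(output_uncertainty(r, 0), sd(r) / sqrt(20))
  expect_equal(output_uncertainty(r, 3e-3),
               sqrt((sd(r) / sqrt(20))^2 + 9e-6))
  expect_error(output_uncertainty(1.5, 1e-3), ">= 2")
})

test_that("gain uncertainty is first-order linear and matches Monte Carlo", {
  vin <- seq(30e-6, 730e-6, length.out = 47)
  vad <- 4488 * vin
  u_vin <- rep(2e-7, 47)
  u_vad <- rep(1e-3, 47)
  expect_equal(gain_uncertainty(vin, vad, rep(0, 47), rep(0, 47))$u_gain, 0)
  u1 <- gain_uncertainty(vin, vad, u_vin, u_vad)$u_gain
  u2 <- gain_uncertainty(vin, vad, 2 * u_vin, 2 * u_vad)$u_gain
  expect_rel(u2, 2 * u1, 1e-6)
  # MC oracle: perturb every input and output, refit
  B <- 5e4
  set.seed(11)
  gs <- numeric(B)
  for (b in seq_len(B)) {
    gs[b] <- fit_gain(vin + rnorm(47, 0, u_vin[1]),
                      vad + rnorm(47, 0, u_vad[1]))
  }
  expect_rel(u1, sd(gs), 0.05)
})

test_that("linearity error recovers injected distortion", {
  vin <- seq(30e-6, 730e-6, length.out = 47)
  lin <- linearity_error(vin, 4488 * vin, 4488)
  expect_equal(lin$residual_v, rep(0, 47))
  # 0.8% of a 750 uV full scale is 6 uV
  expect_equal(0.8 / 100 * 750e-6, 6e-6)
  # injected cubic distortion of known input-referred peak
  d <- 5e-6
  disto <- d * (2 * (vin - min(vin)) / diff(range(vin)) - 1)^3
  vad <- 4488 * (vin + disto)
  slope <- fit_gain(vin, vad)
  res <- linearity_error(vin, vad, slope)$residual_v
  expect_rel(max(abs(res)), d, 0.1)
})

test_that("bandwidth estimation reproduces closed-form cutoffs and slopes", {
  # single-pole low-pass sampled analytically
  f <- 10^seq(-1, 3, length.out = 200)
  tau <- 5e-3
  g <- 1 / sqrt(1 + (2 * pi * f * tau)^2)
  bw <- estimate_bandwidth(f, g)
  expect_rel(bw$f_hi_3db, 1 / (2 * pi * tau), 0.01)
  expect_true(is.na(bw$f_lo_3db))
  # front-end response on the 81-point characterization grid
  cfg <- sensor_config()
  gg <- Mod(analog_transfer(bandwidth_grid(), cfg))
  bwn <- estimate_bandwidth(bandwidth_grid(), gg, ref = "nominal",
                            nominal_gain = sensor_gain(cfg))
  expect_lt(abs(bwn$f_lo_3db - 0.75), 0.01)
  bwp <- estimate_bandwidth(bandwidth_grid(), gg)
  expect_lt(bwp$f_lo_3db, bwn$f_lo_3db)  # peak reference cuts in lower
  # asymptotic slopes, measured where the response is on its asymptotes
  fa <- c(1e-3, 2e-3, 0.5, 30, 1e4, 2e4)
  bwa <- estimate_bandwidth(fa, Mod(analog_transfer(fa, cfg)))
  expect_lt(abs(bwa$slope_lo - 40), 0.5)
  expect_lt(abs(bwa$slope_hi + 60), 0.5)
  expect_error(estimate_bandwidth(c(1, 2), c(1, 1)), "two decades")
})

test_that("the 50 Hz notch meets its attenuation and passband spec", {
  nf <- design_notch(50, 200)
  expect_gte(nf$attenuation_db, 30)
  # unit gain at DC
  expect_lt(abs(nf$response_db[1]), 0.1)
  # passband deviation below 1 dB outside f0 +/- 5 Hz
  pass <- abs(nf$frequencies - 50) > 5
  expect_lt(max(abs(nf$response_db[pass])), 1)
  # time-domain: a pure 50 Hz sine is attenuated at least as designed
  t <- seq(0, 20, by = 1 / 200)
  x <- sin(2 * pi * 50 * t)
  y <- apply_notch(nf, x)[2000:4001]
  atten_td <- -20 * log10(sqrt(mean(y^2)) / sqrt(0.5))
  expect_gte(atten_td, nf$attenuation_db - 0.5)
  expect_error(design_notch(150, 200), "f0 < fs/2")
})

test_that("synthetic characterization recovers the stimulus-frequency gain", {
  cfg <- sensor_config()
  run <- synth_characterization_run(cfg, seed = 21)
  fit <- characterize_gain(run)
  expect_rel(fit$gain, attr(run, "true_gain"), 0.005)
  expect_gt(fit$u_gain, 0)
  expect_lt(fit$linearity_pct_fs, 0.2)
})
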