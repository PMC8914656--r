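#' Characterization run container
#'
#' Holds one gain/linearity characterization protocol: a sinusoidal stimulus
#' stepped through `length(vg_amplitudes)` amplitudes, fed to the sensor
#' through a resistive attenuator, with `ncol(rms_matrix)` repeated RMS
#' readings of the amplified output per amplitude.  The reference protocol
#' uses 47 amplitudes from 0.1 to 2.4 V peak-to-peak and 20 readings each
#' (a 47 x 20 matrix), an attenuation of 0.303e-3 with standard uncertainty
#' 3e-6, and instrument (type B) uncertainty from the oscilloscope manual.
#'
#' @param vg_amplitudes Stimulus amplitudes (V peak-to-peak).
#' @param u_vg Standard uncertainty of the stimulus amplitude (V).
#' @param alpha Attenuation factor (dimensionless).
#' @param u_alpha Standard uncertainty of `alpha`.
#' @param rms_matrix Matrix of output RMS readings (V), one row per
#'   amplitude.
#' @param u_b Instrument type-B standard uncertainty of a reading (V).
#' @return An object of class `characterization_run`.
#' @export
characterization_run <- function(vg_amplitudes, u_vg, alpha, u_alpha,
                                 rms_matrix, u_b) {
  rms_matrix <- as.matrix(rms_matrix)
  if (nrow(rms_matrix) != length(vg_amplitudes))
    stop("characterization_run: one rms_matrix row per stimulus amplitude")
  if (any(rms_matrix <= 0))
    stop("characterization_run: all RMS readings must be positive")
  structure(list(vg_amplitudes = vg_amplitudes, u_vg = u_vg,
                 alpha = alpha, u_alpha = u_alpha,
                 rms_matrix = rms_matrix, u_b = u_b),
            class = "characterization_run")
}

#' Uncertainty of the attenuated input voltage
#'
#' First-order (GUM) propagation through `VIN = alpha * VG`:
#' `u(VIN) = sqrt((alpha u(VG))^2 + (VG u(alpha))^2)`.
#'
#' @param vg Stimulus amplitude(s) (V).
#' @param u_vg Standard uncertainty of `vg` (V).
#' @param alpha Attenuation factor.
#' @param u_alpha Standard uncertainty of `alpha`.
#' @return `u(VIN)` in volts, vectorized over the inputs.
#' @export
input_uncertainty <- function(vg, u_vg, alpha, u_alpha) {
  stopifnot(all(u_vg >= 0), all(u_alpha >= 0))
  sqrt((alpha * u_vg)^2 + (vg * u_alpha)^2)
}

#' Least-squares gain
#'
#' Slope of the output-vs-input line by the moment form of least squares,
#' `G = cov(vin, vad) / var(vin)` with population moments, which is the
#' ordinary least-squares slope and is invariant to a constant offset in the
#' output.
#'
#' @param vin Input amplitude vector (V).
#' @param vad_mean Mean output reading per amplitude (V).
#' @return The fitted slope (dimensionless gain).
#' @export
fit_gain <- function(vin, vad_mean) {
  stopifnot(length(vin) == length(vad_mean))
  if (length(unique(vin)) < 3L)
    stop("fit_gain: need at least 3 distinct amplitudes")
  vx <- mean(vin^2) - mean(vin)^2
  if (vx == 0) stop("fit_gain: degenerate design (zero variance in vin)")
  (mean(vin * vad_mean) - mean(vin) * mean(vad_mean)) / vx
}

#' Combined uncertainty of the mean output reading
#'
#' Type A as the standard deviation of the sample mean over the repeated
#' readings, combined in quadrature with the instrument type-B term:
#' `u = sqrt((sd(readings)/sqrt(n))^2 + u_b^2)`.
#'
#' @param readings Repeated RMS readings (V) at one amplitude.
#' @param u_b Instrument type-B standard uncertainty (V).
#' @return Combined standard uncertainty of the mean reading (V).
#' @export
output_uncertainty <- function(readings, u_b) {
  n <- length(readings)
  if (n < 2L) stop("output_uncertainty: need >= 2 readings for type A")
  u_a <- stats::sd(readings) / sqrt(n)
  sqrt(u_a^2 + u_b^2)
}

#' Uncertainty of the least-squares gain
#'
#' First-order propagation of per-point input and output uncertainties
#' through the [fit_gain()] slope.  The sensitivities to the output means
#' are analytic (`dG/dvad_i = (vin_i - mean(vin)) / sum((vin - mean)^2)`);
#' the sensitivities to the inputs are evaluated by central differences.
#'
#' @param vin Input amplitudes (V).
#' @param vad_mean Mean output readings (V).
#' @param u_vin_vec Per-point input uncertainties (V).
#' @param u_vad_vec Per-point output uncertainties (V).
#' @return List with `u_gain` (standard uncertainty of the slope) and
#'   `method` (how each sensitivity was obtained).
#' @export
gain_uncertainty <- function(vin, vad_mean, u_vin_vec, u_vad_vec) {
  n <- length(vin)
  stopifnot(length(vad_mean) == n, length(u_vin_vec) == n,
            length(u_vad_vec) == n)
  sxx <- sum((vin - mean(vin))^2)
  if (sxx == 0) stop("gain_uncertainty: degenerate design")
  d_vad <- (vin - mean(vin)) / sxx
  d_vin <- vapply(seq_len(n), function(i) {
    h <- max(abs(vin[i]), max(abs(vin))) * 1e-6
    vp <- vin; vp[i] <- vp[i] + h
    vm <- vin; vm[i] <- vm[i] - h
    (fit_gain(vp, vad_mean) - fit_gain(vm, vad_mean)) / (2 * h)
  }, numeric(1))
  u <- sqrt(sum((d_vin * u_vin_vec)^2) + sum((d_vad * u_vad_vec)^2))
  list(u_gain = u,
       method = c(vin = "central-difference", vad = "analytic"))
}

#' Linearity error of a characterized channel
#'
#' Deviation of the measured input-referred amplitudes from the
#' least-squares line: `residual_i = vad_mean_i / slope - vin_i`, reported
#' in volts and as a percentage of the input full scale.  For the reference
#' headband the figure is about 0.8% of the 750 uV span, i.e. 6 uV.
#'
#' @param vin Input amplitudes (V).
#' @param vad_mean Mean output readings (V).
#' @param slope Gain from [fit_gain()].
#' @param full_scale Input full scale (V) used for the percentage.
#' @return List with `residual_v`, `residual_pct_fs`, and
#'   `linearity_pct_fs` (max absolute percentage).
#' @export
linearity_error <- function(vin, vad_mean, slope, full_scale = 750e-6) {
  res <- vad_mean / slope - vin
  pct <- 100 * res / full_scale
  list(residual_v = res, residual_pct_fs = pct,
       linearity_pct_fs = max(abs(pct)))
}

#' Characterize gain, uncertainty and linearity from a run
#'
#' Convenience wrapper applying [fit_gain()], [output_uncertainty()],
#' [input_uncertainty()], [gain_uncertainty()] and [linearity_error()] to a
#' [characterization_run()].  Stimulus peak-to-peak amplitudes are converted
#' to RMS (`/ 2 sqrt(2)`) to match the RMS readings of the output.
#'
#' @param run A [characterization_run()].
#' @param full_scale Input full scale (V) for the linearity percentage.
#' @return An object of class `gain_fit`: `gain`, `u_gain`, `residuals`
#'   (input-referred, V), `linearity_pct_fs`, `vin`, `vad_mean`.
#' @export
characterize_gain <- function(run, full_scale = 750e-6) {
  stopifnot(inherits(run, "characterization_run"))
  vin <- run$alpha * run$vg_amplitudes / (2 * sqrt(2))
  vad_mean <- rowMeans(run$rms_matrix)
  g <- fit_gain(vin, vad_mean)
  u_vin <- input_uncertainty(run$vg_amplitudes / (2 * sqrt(2)),
                             run$u_vg / (2 * sqrt(2)),
                             run$alpha, run$u_alpha)
  u_vad <- apply(run$rms_matrix, 1, output_uncertainty, u_b = run$u_b)
  ug <- gain_uncertainty(vin, vad_mean, u_vin, u_vad)
  lin <- linearity_error(vin, vad_mean, g, full_scale)
  structure(list(gain = g, u_gain = ug$u_gain,
                 residuals = lin$residual_v,
                 linearity_pct_fs = lin$linearity_pct_fs,
                 vin = vin, vad_mean = vad_mean),
            class = "gain_fit")
}

#' @export
print.gain_fit <- function(x, ...) {
  cat(sprintf("<gain_fit> G = %.1f +/- %.1f (k = 1), linearity %.2f %%FS\n",
              x$gain, x$u_gain, x$linearity_pct_fs))
  invisible(x)
}

#' Bandwidth estimation from a sampled frequency response
#'
#' Locates the -3 dB crossings of a magnitude response sampled on a
#' frequency grid, by linear interpolation in log-frequency / dB
#' coordinates, and estimates the asymptotic slopes from the two lowest and
#' two highest grid points.  The -3 dB level can be referenced to the peak
#' of the sampled response (default) or to a supplied nominal center-band
#' gain; for a response with a narrow peak the two differ (for the default
#' front end: 0.73 Hz from the peak, 0.75 Hz from the nominal gain).
#'
#' @param frequencies Strictly increasing frequency grid (Hz) covering at
#'   least two decades.
#' @param gains Linear magnitude at each frequency.
#' @param ref `"peak"` or `"nominal"`.
#' @param nominal_gain Reference gain when `ref = "nominal"`.
#' @return An object of class `frequency_response`: the grid, `f_lo_3db`,
#'   `f_hi_3db` (NA when no crossing lies inside the grid), `slope_lo`,
#'   `slope_hi` (dB/decade), and the reference level used.
#' @export
estimate_bandwidth <- function(frequencies, gains,
                               ref = c("peak", "nominal"),
                               nominal_gain = NULL) {
  ref <- match.arg(ref)
  stopifnot(length(frequencies) == length(gains),
            all(diff(frequencies) > 0), all(frequencies > 0),
            all(gains > 0))
  if (log10(frequencies[length(frequencies)] / frequencies[1]) < 2)
    stop("estimate_bandwidth: grid must cover at least two decades")
  g0 <- if (ref == "peak") max(gains) else {
    if (is.null(nominal_gain))
      stop("estimate_bandwidth: nominal_gain required when ref = 'nominal'")
    nominal_gain
  }
  level <- 20 * log10(g0) - 20 * log10(sqrt(2))  # -3 dB (exactly 10log10(2))
  lf <- log10(frequencies)
  db <- 20 * log10(gains)
  ipk <- which.max(gains)
  cross <- function(idx) {
    # first crossing of `level` within the index range, linearly interpolated
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      if ((db[i] - level) * (db[j] - level) <= 0 && db[i] != db[j]) {
        t <- (level - db[i]) / (db[j] - db[i])
        return(10^(lf[i] + t * (lf[j] - lf[i])))
      }
    }
    NA_real_
  }
  f_lo <- cross(rev(seq_len(ipk)))        # walk down from the peak
  f_hi <- cross(seq(ipk, length(gains)))  # walk up from the peak
  n <- length(gains)
  slope_lo <- (db[2] - db[1]) / (lf[2] - lf[1])
  slope_hi <- (db[n] - db[n - 1]) / (lf[n] - lf[n - 1])
  structure(list(frequencies = frequencies, gains = gains,
                 f_lo_3db = f_lo, f_hi_3db = f_hi,
                 slope_lo = slope_lo, slope_hi = slope_hi,
                 ref = ref, ref_gain = g0),
            class = "frequency_response")
}

#' @export
print.frequency_response <- function(x, ...) {
  cat(sprintf(
    "<frequency_response> -3 dB [%s, %s] Hz (ref %s), slopes %+.1f / %+.1f dB/dec\n",
    format(x$f_lo_3db, digits = 3), format(x$f_hi_3db, digits = 3),
    x$ref, x$slope_lo, x$slope_hi))
  invisible(x)
}

#' The standard 81-point characterization grid
#'
#' 81 logarithmically spaced frequencies from 0.1 to 1000 Hz, the grid used
#' to characterize the front-end bandwidth.
#' @return Numeric vector of frequencies (Hz).
#' @export
bandwidth_grid <- function() 10^seq(log10(0.1), log10(1000), length.out = 81)

#' Design the power-line notch filter
#'
#' Second-order (two-pole, two-zero) IIR notch: zeros just inside the unit
#' circle at the notch frequency (their radius sets the notch depth), poles
#' at the same angle with a radius set by the -3 dB bandwidth, and the gain
#' normalized to one at DC.  The design is checked against its own
#' frequency response: attenuation at `f0` of at least
#' `min_attenuation_db`, and passband deviation below 1 dB outside
#' `f0 +/- 5` Hz.
#'
#' @param f0 Notch frequency in Hz, `0 < f0 < fs/2`.
#' @param fs Sampling rate in Sa/s.
#' @param min_attenuation_db Required attenuation at `f0` (dB).
#' @param depth_db Designed notch depth at `f0` (dB).
#' @param bandwidth_hz Approximate -3 dB notch width (Hz).
#' @return An object of class `notch_filter`: coefficient vectors `b`, `a`,
#'   the evaluated response (`frequencies`, `response_db`), and
#'   `attenuation_db` at `f0`.
#' @examples
#' nf <- design_notch(50, 200)
#' nf$attenuation_db >= 30
#' @export
design_notch <- function(f0, fs, min_attenuation_db = 30,
                         depth_db = 40, bandwidth_hz = 3) {
  if (!(f0 > 0 && f0 < fs / 2))
    stop("design_notch: need 0 < f0 < fs/2")
  if (depth_db < min_attenuation_db)
    stop("design_notch: designed depth below the required attenuation")
  w0 <- 2 * pi * f0 / fs
  rp <- 1 - pi * bandwidth_hz / fs
  if (rp <= 0 || rp >= 1)
    stop("design_notch: infeasible bandwidth for this sampling rate")
  coef <- function(rz) {
    b <- c(1, -2 * rz * cos(w0), rz^2)
    a <- c(1, -2 * rp * cos(w0), rp^2)
    list(b = b * sum(a) / sum(b), a = a)  # unit DC gain
  }
  mag_at <- function(rz, w) {
    co <- coef(rz)
    z <- exp(-1i * w * (0:2))
    Mod(sum(co$b * z) / sum(co$a * z))
  }
  target <- 10^(-depth_db / 20)
  rz <- stats::uniroot(function(r) mag_at(r, w0) - target,
                       interval = c(rp, 1 - 1e-12), tol = 1e-14)$root
  co <- coef(rz)
  f <- seq(0, fs / 2, length.out = 2001)
  h <- vapply(2 * pi * f / fs, function(w) {
    z <- exp(-1i * w * (0:2))
    Mod(sum(co$b * z) / sum(co$a * z))
  }, numeric(1))
  resp_db <- 20 * log10(h)
  atten <- -20 * log10(mag_at(rz, w0))
  if (atten < min_attenuation_db)
    stop("design_notch: attenuation target not met")
  pass <- abs(f - f0) > 5
  if (max(abs(resp_db[pass])) >= 1)
    stop("design_notch: passband deviation exceeds 1 dB outside f0 +/- 5 Hz")
  structure(list(b = co$b, a = co$a, f0 = f0, fs = fs,
                 frequencies = f, response_db = resp_db,
                 attenuation_db = atten),
            class = "notch_filter")
}

#' Apply a notch filter to a signal
#' @param nf A `notch_filter` from [design_notch()].
#' @param x Numeric signal sampled at `nf$fs`.
#' @return Filtered signal.
#' @export
apply_notch <- function(nf, x) {
  as.numeric(signal::filter(nf$b, nf$a, x))
}

#' @export
print.notch_filter <- function(x, ...) {
  cat(sprintf("<notch_filter> f0 = %g Hz @ %g Sa/s, attenuation %.1f dB\n",
              x$f0, x$fs, x$attenuation_db))
  invisible(x)
}
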