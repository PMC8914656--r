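#' Simulate a full gain/linearity characterization protocol
#'
#' Emulates the bench protocol end to end against the digital twin: a 5 Hz
#' sinusoidal stimulus stepped through 47 amplitudes (0.1 to 2.4 V
#' peak-to-peak, 50 mV steps), attenuated to the microvolt range, run
#' through [simulate_front_end()], and read back as repeated RMS values over
#' 25 stimulus periods after the high-pass transient has settled.
#'
#' The simulated oscilloscope is ideal: the reading-to-reading scatter has
#' standard deviation `reading_sd`, while the type-B allowance `u_b` carried
#' into the uncertainty budget is, as in bench practice, a conservative
#' bound taken from the instrument manual rather than the realized error.
#' The quantity recovered by [characterize_gain()] on the result is the
#' chain's amplitude gain at the stimulus frequency, `|H(5 Hz)|` (about
#' 4399 for the default constants) -- not the asymptotic product `g1 g2`,
#' because the stimulus sits on the (gently curved) top of the band-pass
#' response.
#'
#' @param cfg A [sensor_config()].
#' @param seed Integer seed for the reading noise.
#' @param vg_amplitudes Stimulus amplitudes (V peak-to-peak).
#' @param n_readings Repeated readings per amplitude.
#' @param f_stim Stimulus frequency (Hz).
#' @param alpha,u_alpha Attenuator value and uncertainty.
#' @param u_vg Stimulus-amplitude uncertainty (V) carried into the budget.
#' @param u_b Instrument type-B uncertainty (V) carried into the budget.
#' @param reading_sd Realized standard deviation of one RMS reading (V).
#' @param noiseless_rms Optional precomputed noiseless RMS vector (one value
#'   per amplitude), to amortize the deterministic simulation across
#'   repeated synthetic runs.
#' @return A [characterization_run()] with attributes `true_gain`
#'   (`|H(f_stim)|` of the continuous model) and `noiseless_rms`.
#' @export
synth_characterization_run <- function(cfg, seed,
                                       vg_amplitudes = seq(0.1, 2.4, by = 0.05),
                                       n_readings = 20L,
                                       f_stim = 5,
                                       alpha = 0.303e-3, u_alpha = 3e-6,
                                       u_vg = 1e-3, u_b = 2e-3,
                                       reading_sd = 1e-3,
                                       noiseless_rms = NULL) {
  if (is.null(noiseless_rms))
    noiseless_rms <- noiseless_protocol_rms(cfg, vg_amplitudes, alpha, f_stim)
  n_amp <- length(vg_amplitudes)
  noise <- with_seed(seed,
                     matrix(stats::rnorm(n_amp * n_readings, 0, reading_sd),
                            n_amp, n_readings))
  run <- characterization_run(vg_amplitudes, u_vg, alpha, u_alpha,
                              rms_matrix = noiseless_rms + noise, u_b = u_b)
  attr(run, "true_gain") <- Mod(analog_transfer(f_stim, cfg))
  attr(run, "noiseless_rms") <- noiseless_rms
  run
}

#' Noiseless steady-state RMS of the twin for each stimulus amplitude
#'
#' Runs the deterministic part of the front-end simulation on a sinusoid at
#' each amplitude and returns the RMS of the settled output (reference
#' offset removed) over 25 stimulus periods.
#'
#' @inheritParams synth_characterization_run
#' @return Numeric vector of RMS values (V), one per amplitude.
#' @export
noiseless_protocol_rms <- function(cfg, vg_amplitudes = seq(0.1, 2.4, by = 0.05),
                                   alpha = 0.303e-3, f_stim = 5) {
  quiet <- sensor_config(g1 = cfg$g1, g2 = cfg$g2, tau_hp = cfg$tau_hp,
                         tau_lp = cfg$tau_lp, v_ref = cfg$v_ref,
                         v_supply = cfg$v_supply, adc_bits = cfg$adc_bits,
                         fs_over = cfg$fs_over,
                         oversample_factor = cfg$oversample_factor,
                         fs_out = cfg$fs_out, noise_density = 0,
                         input_fullscale = cfg$input_fullscale)
  settle <- ceiling(10 * cfg$tau_hp)                  # seconds
  n_per <- 25
  t <- seq(0, settle + n_per / f_stim, by = 1 / cfg$fs_over)
  keep <- t > settle
  vapply(vg_amplitudes, function(vg) {
    vin <- alpha * (vg / 2) * sin(2 * pi * f_stim * t)
    out <- simulate_front_end(vin, quiet) - quiet$v_ref
    sqrt(mean(out[keep]^2))
  }, numeric(1))
}
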