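#' Front-end and converter configuration of the EEG headband
#'
#' Collects every design constant of the analog front-end and the
#' oversampling A/D scheme: stage gains, filter time constants, reference and
#' supply voltages, converter geometry, amplifier noise density and input
#' span.  The defaults reproduce the headband as designed: a two-stage
#' amplifier with overall gain `g1 * g2 = 4488` maps EEG signals in
#' +/- 350 uV onto the 3.3 V converter span around the 1.65 V reference, and
#' a 12-bit converter runs at 3200 Sa/s with blocks of 16 samples summed into
#' one 200 Sa/s output datum.
#'
#' @param g1 First-stage (instrumentation amplifier) gain, dimensionless.
#' @param g2 Filter-stage (Sallen-Key) gain, dimensionless.
#' @param tau_hp High-pass time constant in seconds; the DC-compensation
#'   integrator uses the same constant, so the high-pass pole is double.
#' @param tau_lp Low-pass (anti-alias) time constant in seconds; the
#'   anti-alias filter has three coincident poles at `1/tau_lp`.
#' @param v_ref Reference voltage in volts, applied to the mastoid reference
#'   electrodes; must equal `v_supply / 2`.
#' @param v_supply Full supply span in volts.
#' @param adc_bits Converter resolution in bits.
#' @param fs_over Oversampled rate in Sa/s; must equal
#'   `fs_out * oversample_factor`.
#' @param oversample_factor Number of consecutive samples summed into one
#'   output datum.
#' @param fs_out Output (transmitted) rate in Sa/s.
#' @param noise_density Input-referred amplifier noise density in V/sqrt(Hz).
#' @param input_fullscale One-sided input span in volts (+/- this value).
#'
#' @return An object of class `sensor_config` (a validated named list).
#' @examples
#' cfg <- sensor_config()
#' sensor_gain(cfg)   # 4488
#' @export
sensor_config <- function(g1 = 680, g2 = 6.6,
                          tau_hp = 0.33, tau_lp = 2.7e-3,
                          v_ref = 1.65, v_supply = 3.3,
                          adc_bits = 12L, fs_over = 3200,
                          oversample_factor = 16L, fs_out = 200,
                          noise_density = 35e-9,
                          input_fullscale = 350e-6) {
  cfg <- list(g1 = g1, g2 = g2, tau_hp = tau_hp, tau_lp = tau_lp,
              v_ref = v_ref, v_supply = v_supply,
              adc_bits = as.integer(adc_bits), fs_over = fs_over,
              oversample_factor = as.integer(oversample_factor),
              fs_out = fs_out, noise_density = noise_density,
              input_fullscale = input_fullscale)
  pos <- c("g1", "g2", "tau_hp", "tau_lp", "v_supply", "fs_over",
           "oversample_factor", "fs_out", "input_fullscale")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0)
      stop("sensor_config: '", nm, "' must be a single positive number")
  }
  if (cfg$noise_density < 0)
    stop("sensor_config: 'noise_density' must be non-negative")
  if (!isTRUE(all.equal(cfg$fs_over, cfg$fs_out * cfg$oversample_factor)))
    stop("sensor_config: fs_over must equal fs_out * oversample_factor")
  if (!isTRUE(all.equal(cfg$v_ref, cfg$v_supply / 2)))
    stop("sensor_config: v_ref must equal v_supply / 2")
  class(cfg) <- "sensor_config"
  cfg
}

#' Overall signal-chain gain
#'
#' @param cfg A [sensor_config()].
#' @return `g1 * g2`, the nominal center-band gain.
#' @export
sensor_gain <- function(cfg) cfg$g1 * cfg$g2

#' Read a sensor configuration from a plain-text key-value file
#'
#' One `key value` (or `key: value`) pair per line; `#` starts a comment.
#' Unknown keys are an error; missing keys keep their defaults.
#'
#' @param path File path.
#' @return A [sensor_config()].
#' @export
read_sensor_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    parts <- strsplit(sub(":", " ", ln, fixed = TRUE), "[[:space:]]+")[[1]]
    if (length(parts) != 2L)
      stop("read_sensor_config: cannot parse line '", ln, "'")
    args[[parts[1L]]] <- as.numeric(parts[2L])
  }
  known <- names(formals(sensor_config))
  bad <- setdiff(names(args), known)
  if (length(bad))
    stop("read_sensor_config: unknown keys: ", paste(bad, collapse = ", "))
  do.call(sensor_config, args)
}

#' @export
print.sensor_config <- function(x, ...) {
  cat("<sensor_config>\n")
  cat(sprintf("  gain            : %g x %g = %g\n", x$g1, x$g2, x$g1 * x$g2))
  cat(sprintf("  time constants  : tau_hp %g s, tau_lp %g s\n",
              x$tau_hp, x$tau_lp))
  cat(sprintf("  converter       : %d bit over [0, %g] V, ref %g V\n",
              x$adc_bits, x$v_supply, x$v_ref))
  cat(sprintf("  sampling        : %g Sa/s, blocks of %d -> %g Sa/s\n",
              x$fs_over, x$oversample_factor, x$fs_out))
  cat(sprintf("  amplifier noise : %g nV/sqrt(Hz), input span +/- %g uV\n",
              x$noise_density * 1e9, x$input_fullscale * 1e6))
  invisible(x)
}
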