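#' Band-limited Gaussian EEG-like signal
#'
#' Generates a stationary Gaussian process whose power is confined exactly
#' to `[f_lo, f_hi)`: white Gaussian noise is shaped in the frequency
#' domain (bins outside the band zeroed) and rescaled so the realized
#' variance equals the requested band power.  Out-of-band power is zero by
#' construction; a Welch estimate recovers the band power up to windowing
#' leakage (well within 5% for 60 s or more).
#'
#' @param band A band name from [band_specs()] or `c(f_lo, f_hi)` in Hz.
#' @param power Target band power in uV^2 (variance of the signal).
#' @param duration Duration in seconds.
#' @param fs Sampling rate (Sa/s); must exceed `2 * f_hi`.
#' @param seed Integer seed.
#' @return Numeric vector of length `round(duration * fs)` in uV.
#' @examples
#' x <- generate_band_signal("beta", power = 5, duration = 120,
#'                           fs = 200, seed = 1)
#' var(x)   # 5 exactly
#' @export
generate_band_signal <- function(band, power, duration, fs = 200, seed) {
  band <- resolve_band(band)
  if (fs <= 2 * band[2])
    stop("generate_band_signal: fs must exceed twice the upper band edge")
  stopifnot(power >= 0, duration > 0)
  n <- round(duration * fs)
  if (power == 0) return(numeric(n))
  # generate at an FFT-friendly length and truncate: the process is
  # stationary, so the cut does not alter its band limits
  n2 <- stats::nextn(n, c(2, 3, 5))
  x <- with_seed(seed, stats::rnorm(n2))
  x <- band_limit(x, fs, band)[seq_len(n)]
  x * sqrt(power) / stats::sd(x)
}

# Brick-wall band limiting in the frequency domain, keeping f_lo <= f < f_hi.
band_limit <- function(x, fs, band) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)                 # two-sided bin frequencies
  keep <- f >= band[1] & f < band[2]
  X <- stats::fft(x)
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Default per-band resting powers of the generator
#'
#' Band powers (uV^2) of the non-beta background used for synthetic
#' sessions; beta is set per subject and condition by the cohort model.
#' @return Named numeric vector.
#' @export
default_band_powers <- function() {
  c(delta = 10, theta = 6, alpha = 8, beta = 4, gamma = 1.5)
}

#' Synthesize one multichannel EEG recording with known band powers
#'
#' Each channel is the sum of five independent band-limited Gaussian
#' processes, one per standard band, with the requested powers; channels
#' are mutually independent.
#'
#' @param band_powers Either a named vector of per-band powers applied to
#'   every channel, or a channels x bands matrix (rownames = channel
#'   labels).
#' @param duration Duration in seconds.
#' @param fs Sampling rate (Sa/s).
#' @param seed Integer seed.
#' @param channels Channel labels.
#' @return An [eeg_recording()] with attribute `true_band_powers`
#'   (channels x bands matrix, uV^2).
#' @export
generate_recording <- function(band_powers = default_band_powers(),
                               duration = 300, fs = 200, seed = 1L,
                               channels = headband_channels()) {
  bs <- band_specs()
  if (is.matrix(band_powers)) {
    stopifnot(nrow(band_powers) == length(channels),
              ncol(band_powers) == nrow(bs))
    P <- band_powers
  } else {
    stopifnot(all(bs$name %in% names(band_powers)))
    P <- matrix(band_powers[bs$name], length(channels), nrow(bs),
                byrow = TRUE)
  }
  dimnames(P) <- list(channels, bs$name)
  n <- round(duration * fs)
  X <- matrix(0, n, length(channels))
  for (ch in seq_along(channels)) {
    for (b in seq_len(nrow(bs))) {
      X[, ch] <- X[, ch] +
        generate_band_signal(c(bs$f_lo[b], bs$f_hi[b]), P[ch, b],
                             duration, fs,
                             seed = derive_seed(seed, ch * 100L + b))
    }
  }
  rec <- eeg_recording(X, fs, channels,
                       provenance = sprintf("generate_recording seed=%d", seed))
  attr(rec, "true_band_powers") <- P
  rec
}

#' Inject blink, motion and power-line artifacts
#'
#' Adds the three artifact families seen on a driving simulator:
#' * blinks: 400 ms biphasic (one-cycle sine, Hann-shaped) pulses of about
#'   `blink_amp` uV, dominant on Fp1/Fp2 with a fixed cross-channel loading
#'   (frontal 1.0/0.95, central 0.25, occipital 0.08);
#' * motion bursts: 1-2 s broadband (1-45 Hz) bursts scaled to
#'   `motion_mult` times each channel's background RMS on all channels;
#' * power line: a common 50 Hz sinusoid of `line_amp` uV amplitude.
#'
#' @param rec An [eeg_recording()].
#' @param blink_rate Blinks per minute.
#' @param motion_rate Motion bursts per minute.
#' @param line_amp 50 Hz amplitude in uV (power `line_amp^2 / 2`).
#' @param blink_amp Blink peak amplitude on Fp1 in uV.
#' @param motion_mult Burst amplitude in units of the channel background RMS
#'   (>= 5 so every burst is detectable above background).
#' @param seed Integer seed.
#' @return List with `recording` (artifacts added) and `events` (data frame:
#'   type, onset_s, duration_s, amplitude).
#' @export
inject_artifacts <- function(rec, blink_rate = 12, motion_rate = 2,
                             line_amp = 5, blink_amp = 100, motion_mult = 8,
                             seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"),
            blink_rate >= 0, motion_rate >= 0, line_amp >= 0)
  if (blink_rate == 0 && motion_rate == 0 && line_amp == 0)
    return(list(recording = rec,
                events = data.frame(type = character(), onset_s = numeric(),
                                    duration_s = numeric(),
                                    amplitude = numeric())))
  fs <- rec$fs
  n <- nrow(rec$data)
  dur <- n / fs
  X <- rec$data
  ev <- list()
  with_seed(seed, {
    bg_rms <- apply(X, 2, stats::sd)
    # blinks
    n_blink <- stats::rpois(1, blink_rate * dur / 60)
    if (n_blink > 0) {
      loading <- blink_loading(rec$channels)
      lb <- round(0.4 * fs)
      shape <- sin(2 * pi * (0:(lb - 1)) / lb) *
        0.5 * (1 - cos(2 * pi * (0:(lb - 1)) / lb))
      shape <- shape / max(abs(shape))
      onsets <- sort(stats::runif(n_blink, 0, dur - 0.4))
      for (o in onsets) {
        i0 <- round(o * fs) + 1L
        idx <- i0:(i0 + lb - 1L)
        amp <- blink_amp * stats::runif(1, 0.8, 1.2)
        X[idx, ] <- X[idx, ] + outer(shape * amp, loading)
        ev[[length(ev) + 1L]] <- data.frame(type = "blink", onset_s = o,
                                            duration_s = 0.4, amplitude = amp)
      }
    }
    # motion bursts
    n_mot <- stats::rpois(1, motion_rate * dur / 60)
    if (n_mot > 0) {
      onsets <- sort(stats::runif(n_mot, 0, dur - 2.2))
      for (o in onsets) {
        blen <- stats::runif(1, 1, 2)
        lb <- round(blen * fs)
        i0 <- round(o * fs) + 1L
        idx <- i0:(i0 + lb - 1L)
        env <- 0.5 * (1 - cos(2 * pi * (0:(lb - 1)) / lb))
        for (ch in seq_along(rec$channels)) {
          burst <- band_limit(stats::rnorm(lb), fs, c(1, 45))
          burst <- burst / stats::sd(burst) * motion_mult * bg_rms[ch]
          X[idx, ch] <- X[idx, ch] + burst * env
        }
        ev[[length(ev) + 1L]] <- data.frame(type = "motion", onset_s = o,
                                            duration_s = blen,
                                            amplitude = motion_mult)
      }
    }
    # power line
    if (line_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      line <- line_amp * sin(2 * pi * 50 * (0:(n - 1)) / fs + phase)
      X <- X + line
      ev[[length(ev) + 1L]] <- data.frame(type = "line", onset_s = 0,
                                          duration_s = dur,
                                          amplitude = line_amp)
    }
  })
  rec$data <- X
  colnames(rec$data) <- rec$channels
  rec <- log_step(rec, sprintf("inject_artifacts seed=%d", seed))
  events <- do.call(rbind, ev)
  list(recording = rec, events = events)
}

# Fixed cross-channel loading of the ocular source.
blink_loading <- function(channels) {
  full <- c(Fp1 = 1, Fp2 = 0.95, C3 = 0.25, C4 = 0.25, O1 = 0.08, O2 = 0.08)
  out <- full[channels]
  out[is.na(out)] <- 0.1
  unname(out)
}

#' Cohort specification for the driving experiment emulator
#'
#' Describes a synthetic cohort mirroring the driving study: `n_subjects`
#' volunteers, each recorded in three sessions (manual driving and two
#' autonomous-driving styles), 7 to 10 minutes per session.  Per-channel
#' beta powers are drawn from log-normal distributions whose medians
#' default to the per-channel medians of the bundled reference cohort (see
#' [load_fixture()]), with a common log-scale spread.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param conditions Session labels.
#' @param duration_range Session duration range in seconds.
#' @param beta_medians Channels x conditions matrix of median beta powers
#'   (uV^2); `NULL` uses the reference-cohort medians.
#' @param sigma_log Between-subject log-scale standard deviation.
#' @param background Named per-band powers (uV^2) of the non-beta
#'   background, shared by all sessions.
#' @param blink_rate,motion_rate,line_amp Artifact intensities, as
#'   [inject_artifacts()].
#' @param seed Master seed for the whole cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10L,
                        conditions = c("Manual", "ADAS1", "ADAS2"),
                        duration_range = c(420, 600),
                        beta_medians = NULL,
                        sigma_log = 0.35,
                        background = c(delta = 10, theta = 6, alpha = 8,
                                       gamma = 1.5),
                        blink_rate = 12, motion_rate = 2, line_amp = 5,
                        seed = 1L) {
  stopifnot(n_subjects >= 2L, length(duration_range) == 2L,
            duration_range[1] <= duration_range[2])
  if (is.null(beta_medians)) {
    ref <- load_fixture("cohort_beta")
    beta_medians <- apply(ref, c(3, 2), stats::median)   # channels x cond
    beta_medians <- beta_medians[, conditions, drop = FALSE]
  }
  stopifnot(ncol(beta_medians) == length(conditions))
  structure(list(n_subjects = as.integer(n_subjects),
                 conditions = conditions,
                 duration_range = duration_range,
                 beta_medians = beta_medians, sigma_log = sigma_log,
                 background = background,
                 blink_rate = blink_rate, motion_rate = motion_rate,
                 line_amp = line_amp, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws the per-subject, per-condition, per-channel true beta powers and
#' session durations, and (optionally) materializes every session as an
#' artifact-injected [eeg_recording()].  Sessions are reproducible
#' individually: [generate_session()] rebuilds any single recording from
#' the spec alone, so large cohorts can be processed one session at a time.
#'
#' @param spec A [cohort_spec()].
#' @param keep_recordings If `FALSE`, only the ground truth and per-session
#'   seeds are returned and sessions are regenerated on demand.
#' @return List with `ground_truth` (data frame: subject, condition,
#'   channel, beta_power, duration_s, seed) and, when requested,
#'   `recordings` (nested list `[[subject]][[condition]]`, each the
#'   [inject_artifacts()] result) and `events`.
#' @export
generate_cohort <- function(spec, keep_recordings = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  channels <- rownames(spec$beta_medians)
  if (is.null(channels)) channels <- headband_channels()
  grid <- expand.grid(subject = seq_len(spec$n_subjects),
                      condition = spec$conditions,
                      stringsAsFactors = FALSE)
  gt <- list()
  with_seed(spec$seed, {
    for (r in seq_len(nrow(grid))) {
      s <- grid$subject[r]; cond <- grid$condition[r]
      med <- spec$beta_medians[, cond]
      beta <- stats::rlnorm(length(channels), log(med), spec$sigma_log)
      dur <- stats::runif(1, spec$duration_range[1], spec$duration_range[2])
      gt[[r]] <- data.frame(subject = s, condition = cond,
                            channel = channels, beta_power = beta,
                            duration_s = dur,
                            seed = derive_seed(spec$seed,
                                               s * 10L + match(cond, spec$conditions)))
    }
  })
  ground_truth <- do.call(rbind, gt)
  out <- list(ground_truth = ground_truth, spec = spec)
  if (keep_recordings) {
    recs <- lapply(seq_len(spec$n_subjects), function(s) {
      setNames(lapply(spec$conditions, function(cond)
        generate_session(spec, s, cond, ground_truth)), spec$conditions)
    })
    out$recordings <- recs
  }
  out
}

#' Regenerate one cohort session
#'
#' Rebuilds the recording of one subject x condition cell from the cohort
#' spec and ground truth, byte-identical to the one produced by
#' [generate_cohort()].
#'
#' @param spec A [cohort_spec()].
#' @param subject Subject index.
#' @param condition Condition label.
#' @param ground_truth The ground-truth table from [generate_cohort()]
#'   (recomputed if omitted).
#' @return The [inject_artifacts()] result for that session (fields
#'   `recording`, `events`), with attribute `true_band_powers`.
#' @export
generate_session <- function(spec, subject, condition, ground_truth = NULL) {
  if (is.null(ground_truth))
    ground_truth <- generate_cohort(spec, keep_recordings = FALSE)$ground_truth
  rows <- ground_truth$subject == subject & ground_truth$condition == condition
  if (!any(rows)) stop("generate_session: no such subject/condition cell")
  cell <- ground_truth[rows, ]
  channels <- cell$channel
  bs <- band_specs()
  P <- matrix(0, length(channels), nrow(bs),
              dimnames = list(channels, bs$name))
  for (b in setdiff(bs$name, "beta")) P[, b] <- spec$background[[b]]
  P[, "beta"] <- cell$beta_power
  sseed <- cell$seed[1]
  rec <- generate_recording(P, duration = cell$duration_s[1],
                            fs = 200, seed = sseed, channels = channels)
  res <- inject_artifacts(rec, blink_rate = spec$blink_rate,
                          motion_rate = spec$motion_rate,
                          line_amp = spec$line_amp,
                          seed = derive_seed(sseed, 999L))
  attr(res, "true_band_powers") <- attr(rec, "true_band_powers")
  res
}
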