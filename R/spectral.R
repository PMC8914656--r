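#' EEG frequency-band definitions
#'
#' The conventional clinical bands used throughout the analysis, half-open
#' on the right: delta \[0.5, 4), theta \[4, 8), alpha \[8, 12), beta
#' \[12, 30), gamma \[30, 45).  Gamma is capped at 45 Hz, the upper passband
#' edge of the cleaning filter.
#'
#' @return A data frame with columns `name`, `f_lo`, `f_hi` (Hz).
#' @export
band_specs <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             f_lo = c(0.5, 4, 8, 12, 30),
             f_hi = c(4, 8, 12, 30, 45),
             stringsAsFactors = FALSE)
}

# resolve a band argument: a name from band_specs() or c(f_lo, f_hi)
resolve_band <- function(band) {
  if (is.character(band)) {
    bs <- band_specs()
    i <- match(band, bs$name)
    if (is.na(i)) stop("unknown band name '", band, "'")
    c(bs$f_lo[i], bs$f_hi[i])
  } else {
    stopifnot(is.numeric(band), length(band) == 2L, band[1] < band[2])
    band
  }
}

#' Welch power spectral density estimate
#'
#' Averaged one-sided periodogram over von Hann-windowed segments with 50%
#' overlap (4 s segments by default, the spectral settings used for the
#' driving sessions).  Each segment is mean-detrended.  The density is
#' scaled so that its integral over frequency equals the signal variance
#' (units: input units squared per Hz).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Sa/s).
#' @param window_s Segment duration in seconds.
#' @param overlap Fractional overlap between consecutive segments.
#' @return An object of class `psd_estimate`: `frequencies` (Hz, one-sided),
#'   `density`, `n_segments`, `window`, `fs`.
#' @examples
#' x <- sin(2 * pi * 20 * seq(0, 60, by = 1 / 200))
#' psd <- welch_psd(x, fs = 200)
#' band_power(psd, "beta")   # ~ 0.5 (= A^2/2)
#' @export
welch_psd <- function(x, fs, window_s = 4, overlap = 0.5) {
  L <- round(window_s * fs)
  hop <- round(L * (1 - overlap))
  n <- length(x)
  if (n < L + hop)
    stop("welch_psd: signal shorter than two segments")
  n_seg <- (n - L) %/% hop + 1L
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))   # periodic von Hann
  scale <- 1 / (fs * sum(w^2))
  nf <- L %/% 2 + 1L
  acc <- numeric(nf)
  for (k in seq_len(n_seg)) {
    seg <- x[((k - 1L) * hop + 1L):((k - 1L) * hop + L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg)[seq_len(nf)])^2 * scale
    acc <- acc + p
  }
  dens <- acc / n_seg
  # one-sided: double everything except DC and (for even L) Nyquist
  dbl <- rep(2, nf); dbl[1] <- 1; if (L %% 2 == 0) dbl[nf] <- 1
  dens <- dens * dbl
  structure(list(frequencies = seq(0, by = fs / L, length.out = nf),
                 density = dens, n_segments = n_seg,
                 window = "hann", window_s = window_s, overlap = overlap,
                 fs = fs),
            class = "psd_estimate")
}

#' Integrated band power from a PSD estimate
#'
#' Trapezoidal integral of the spectral density over `[f_lo, f_hi)`, with
#' linear interpolation of the density at the band edges.
#'
#' @param psd A `psd_estimate` from [welch_psd()] (or any list with
#'   `frequencies` and `density`).
#' @param band A band name (see [band_specs()]) or `c(f_lo, f_hi)` in Hz.
#' @return Band power in input units squared (uV^2 for recordings).
#' @export
band_power <- function(psd, band) {
  band <- resolve_band(band)
  f <- psd$frequencies
  d <- psd$density
  if (band[1] < f[1] - 1e-9 || band[2] > f[length(f)] + 1e-9)
    stop("band_power: band extends outside the PSD frequency range")
  inside <- f > band[1] & f < band[2]
  fi <- c(band[1], f[inside], band[2])
  di <- c(stats::approx(f, d, xout = band[1])$y, d[inside],
          stats::approx(f, d, xout = band[2])$y)
  trapz(fi, di)
}

#' Per-channel band-power table for a session
#'
#' One Welch PSD per channel over the whole recording, integrated over all
#' five standard bands.
#'
#' @param rec An [eeg_recording()] (normally after preprocessing).
#' @param bands Band definition data frame, as [band_specs()].
#' @param window_s,overlap Welch settings, as [welch_psd()].
#' @return A `band_power_table`: numeric matrix channels x bands (uV^2)
#'   with attributes `fs` and `duration_s`.
#' @export
session_band_table <- function(rec, bands = band_specs(),
                               window_s = 4, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- matrix(0, length(rec$channels), nrow(bands),
                dimnames = list(rec$channels, bands$name))
  for (ch in seq_along(rec$channels)) {
    x <- rec$data[, ch]
    if (stats::var(x) == 0) next   # zero signal -> all-zero row
    psd <- welch_psd(x, rec$fs, window_s, overlap)
    for (b in seq_len(nrow(bands)))
      out[ch, b] <- band_power(psd, c(bands$f_lo[b], bands$f_hi[b]))
  }
  structure(out, class = c("band_power_table", "matrix"),
            fs = rec$fs, duration_s = recording_duration(rec))
}

#' Short-time spectrogram
#'
#' Per-window one-sided power densities with the same windowing and scaling
#' as [welch_psd()]; the row-wise mean over windows equals the Welch
#' estimate exactly.
#'
#' @inheritParams welch_psd
#' @return List with `time` (window centers, s), `frequencies` (Hz), and
#'   `power` (frequency x time matrix, units^2/Hz).
#' @export
eeg_spectrogram <- function(x, fs, window_s = 4, overlap = 0.5) {
  L <- round(window_s * fs)
  hop <- round(L * (1 - overlap))
  n <- length(x)
  if (n < L + hop)
    stop("eeg_spectrogram: signal shorter than two segments")
  n_seg <- (n - L) %/% hop + 1L
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))
  scale <- 1 / (fs * sum(w^2))
  nf <- L %/% 2 + 1L
  dbl <- rep(2, nf); dbl[1] <- 1; if (L %% 2 == 0) dbl[nf] <- 1
  P <- matrix(0, nf, n_seg)
  for (k in seq_len(n_seg)) {
    seg <- x[((k - 1L) * hop + 1L):((k - 1L) * hop + L)]
    seg <- (seg - mean(seg)) * w
    P[, k] <- Mod(stats::fft(seg)[seq_len(nf)])^2 * scale * dbl
  }
  list(time = (seq_len(n_seg) - 1L) * hop / fs + window_s / 2,
       frequencies = seq(0, by = fs / L, length.out = nf),
       power = P)
}
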