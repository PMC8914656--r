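# FFT-based convolution (linear, full length).
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                     stats::fft(c(h, numeric(nfft - length(h)))),
                     inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# Zero-phase FIR filtering: forward-backward application of a symmetric
# windowed-sinc filter, implemented as one convolution with conv(h, h)
# (identical because h is symmetric), with odd reflection padding at the
# edges.  Overall magnitude response is |H|^2.
filtfilt_fir <- function(h, x) {
  m <- length(h)
  n <- length(x)
  if (n < 3L * m) stop("too short to filter")
  g <- fft_conv(h, h)                       # length 2m - 1, center at m
  p <- m
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- fft_conv(xp, g)
  y[(p + m - 1L) + seq_len(n)]
}

# Design the band-pass taps: windowed-sinc (Hamming) with the -6 dB points
# placed so the passband proper starts at band[1] and ends at band[2], the
# lower stopband begins one octave below band[1], and the upper stopband
# is reached before the power-line frequency.
fir_bandpass_taps <- function(band, fs) {
  trans_lo <- band[1] * 0.35
  cut_lo <- band[1] * 0.675
  trans_hi <- 4
  cut_hi <- band[2] + 2
  if (cut_hi >= fs / 2) stop("fir_bandpass: band too close to Nyquist")
  n <- ceiling(3.3 * fs / min(trans_lo, trans_hi))
  if (n %% 2 == 1L) n <- n + 1L                    # even order -> odd length
  signal::fir1(n, c(cut_lo, cut_hi) / (fs / 2), type = "pass")
}

#' Zero-phase FIR band-pass filter
#'
#' First cleaning step: a linear-phase windowed-sinc band-pass with passband
#' edges `[1, 45]` Hz applied forward-backward, so the net response has zero
#' phase and squared magnitude.  The lower stopband starts one octave below
#' the lower edge (>= 40 dB there even single-pass), and the upper stopband
#' is reached below 50 Hz, so power-line residue is strongly attenuated.
#'
#' @param rec An [eeg_recording()].
#' @param band Passband edges `c(lo, hi)` in Hz; requires `fs > 2 * hi`.
#' @return The filtered recording (provenance updated).
#' @export
fir_bandpass <- function(rec, band = c(1, 45)) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 2 * band[2])
    stop("fir_bandpass: sampling rate must exceed twice the upper edge")
  h <- fir_bandpass_taps(band, rec$fs)
  if (nrow(rec$data) < 3L * length(h))
    stop("fir_bandpass: recording too short to filter")
  out <- apply(rec$data, 2, function(x) filtfilt_fir(h, x))
  rec$data <- out
  colnames(rec$data) <- rec$channels
  log_step(rec, sprintf("fir_bandpass[%g,%g]Hz ntaps=%d",
                        band[1], band[2], length(h)))
}

#' Simplified artifact-subspace reconstruction
#'
#' Second cleaning step, a simplified reimplementation of
#' artifact-subspace reconstruction: short sliding windows are examined in a
#' space whitened against clean calibration data; principal directions
#' whose variance exceeds the calibration spread -- the mean window
#' variance plus `cutoff_k` standard deviations of the calibration
#' window-variance distribution -- are projected out and the window is
#' rebuilt from the retained subspace.  Windows use 50% overlap with von
#' Hann weights and are overlap-added.
#'
#' Calibration defaults to the lowest-RMS one-second stretches of the
#' recording itself, accumulated to at least `calib_s` seconds; the
#' calibration statistics are robust (MAD-based channel scales combined with
#' the calibration correlation matrix), so occasional artifacts in the
#' selected stretches do not inflate the threshold.
#'
#' @param rec An [eeg_recording()].
#' @param calibration Optional [eeg_recording()] of low-artifact data.
#' @param cutoff_k Rejection threshold in standard deviations of the
#'   calibration window-variance distribution (default 20); `Inf` makes the
#'   step an identity transform.
#' @param window_s Sliding-window length in seconds.
#' @param calib_s Seconds of calibration data selected when none is given.
#' @return List with `recording` (cleaned) and `reconstructed_fraction`
#'   (share of windows in which at least one direction was rejected).
#' @export
asr_clean <- function(rec, calibration = NULL, cutoff_k = 20,
                      window_s = 0.5, calib_s = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  X <- rec$data
  n <- nrow(X); nc <- ncol(X)
  L <- round(window_s * rec$fs)
  hop <- L %/% 2L
  if (is.null(calibration)) {
    calib <- select_calibration(X, rec$fs, calib_s)
  } else {
    stopifnot(inherits(calibration, "eeg_recording"))
    calib <- calibration$data
  }
  if (nrow(calib) < 10L * L)
    stop("asr_clean: calibration shorter than 10 windows")
  # robust calibration covariance: MAD scales + correlation shape
  scales <- apply(calib, 2, stats::mad)
  if (any(scales == 0)) scales[scales == 0] <- 1e-12
  C <- diag(scales) %*% stats::cor(calib) %*% diag(scales)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, max(eg$values) * 1e-12)
  M <- diag(1 / sqrt(ev)) %*% t(eg$vectors)        # whitener
  Minv_t <- t(eg$vectors %*% diag(sqrt(ev)))       # (M^T)^{-1} = t(M^{-1})
  # calibration spread: distribution of window variances in whitened space
  Zcal <- calib %*% t(M)
  ncw <- nrow(Zcal) %/% L
  wv <- vapply(seq_len(ncw), function(k) {
    blk <- Zcal[((k - 1L) * L + 1L):(k * L), , drop = FALSE]
    apply(blk, 2, stats::var)
  }, numeric(nc))
  threshold <- if (is.finite(cutoff_k))
    mean(wv) + cutoff_k * stats::sd(wv) else Inf
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))   # overlap-add weights
  out <- matrix(0, n, nc)
  wsum <- numeric(n)
  starts <- seq(1L, n - L + 1L, by = hop)
  n_rej <- 0L
  for (s in starts) {
    idx <- s:(s + L - 1L)
    Y <- X[idx, , drop = FALSE] %*% t(M)
    S <- crossprod(Y) / L
    es <- eigen(S, symmetric = TRUE)
    keep <- es$values <= threshold
    if (all(keep)) {
      Xc <- X[idx, , drop = FALSE]
    } else {
      n_rej <- n_rej + 1L
      P <- es$vectors %*% (t(es$vectors) * keep)
      Xc <- (Y %*% P) %*% Minv_t
    }
    out[idx, ] <- out[idx, ] + Xc * w
    wsum[idx] <- wsum[idx] + w
  }
  covered <- wsum > 1e-9
  out[covered, ] <- out[covered, ] / wsum[covered]
  out[!covered, ] <- X[!covered, ]                 # edges / tail remainder
  rec$data <- out
  colnames(rec$data) <- rec$channels
  rec <- log_step(rec, sprintf("asr_clean cutoff_k=%g", cutoff_k))
  list(recording = rec,
       reconstructed_fraction = n_rej / length(starts))
}

# Pick the lowest-RMS one-second windows totalling >= calib_s seconds.
select_calibration <- function(X, fs, calib_s) {
  L <- round(fs)
  nwin <- nrow(X) %/% L
  if (nwin < 1L) stop("asr_clean: recording too short for calibration")
  rms <- vapply(seq_len(nwin), function(k) {
    sqrt(mean(X[((k - 1L) * L + 1L):(k * L), ]^2))
  }, numeric(1))
  need <- min(nwin, ceiling(calib_s))
  sel <- sort(order(rms)[seq_len(need)])
  do.call(rbind, lapply(sel, function(k)
    X[((k - 1L) * L + 1L):(k * L), , drop = FALSE]))
}

#' ICA decomposition of a multichannel recording
#'
#' Square blind source separation by a symmetric fixed-point ICA with the
#' tanh contrast (a reimplementation in the spirit of the extended-infomax
#' decompositions commonly applied to EEG): the data are centered and
#' whitened, and the orthonormal rotation is iterated from a seeded random
#' start until convergence.  Components are ordered by explained variance.
#' The result is deterministic for a fixed seed.
#'
#' @param rec An [eeg_recording()] (>= 30 s) or a samples x channels matrix.
#' @param seed Integer seed for the random initial rotation.
#' @param fs Sampling rate; taken from `rec` when it is a recording.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return An object of class `ica_decomposition`: `components` (components
#'   x time, unit variance), `mixing` (channels x components), `unmixing`,
#'   `means`, `channels`, `fs`, `converged`, `iterations`.
#' @export
ica_unmix <- function(rec, seed, fs = NULL, max_iter = 200L, tol = 1e-6) {
  if (inherits(rec, "eeg_recording")) {
    X <- t(rec$data); fs <- rec$fs; channels <- rec$channels
    if (recording_duration(rec) < 30)
      stop("ica_unmix: need at least 30 s of data")
  } else {
    X <- t(as.matrix(rec)); channels <- colnames(rec)
    if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(X)))
    if (is.null(fs)) stop("ica_unmix: fs required for matrix input")
  }
  nc <- nrow(X); n <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < max(eg$values) * 1e-10)
    stop("ica_unmix: rank-deficient data; remove or regenerate degenerate ",
         "channels before decomposing")
  K <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  Z <- K %*% Xc
  sym_decorr <- function(W) {
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors) %*% W
  }
  W <- sym_decorr(with_seed(seed, matrix(stats::rnorm(nc * nc), nc, nc)))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    G <- tanh(W %*% Z)
    W1 <- sym_decorr(G %*% t(Z) / n - diag(rowMeans(1 - G^2)) %*% W)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  U <- W %*% K
  A <- solve(U)
  S <- U %*% Xc
  ord <- order(colSums(A^2), decreasing = TRUE)
  structure(list(components = S[ord, , drop = FALSE],
                 mixing = A[, ord, drop = FALSE],
                 unmixing = U[ord, , drop = FALSE],
                 means = mu, channels = channels, fs = fs,
                 converged = converged, iterations = it),
            class = "ica_decomposition")
}

#' Rule-based labelling of ICA components
#'
#' Heuristic labels for non-brain components:
#' * `ocular` -- frontal (Fp1/Fp2) share of the absolute mixing weights
#'   above `frontal_share` and more than `lowfreq_share` of the component
#'   power below 4 Hz (blinks are frontal, slow, high-amplitude);
#' * `line` -- spectral density around 50 Hz more than `line_ratio` times
#'   the spectral median;
#' * `brain` otherwise.
#'
#' @param ica An `ica_decomposition` from [ica_unmix()].
#' @param frontal_share,lowfreq_share,line_ratio Rule thresholds.
#' @param frontal_channels Labels counted as frontal.
#' @return Character vector of labels, one per component, with the rule
#'   scores attached as attribute `scores`.
#' @export
classify_components <- function(ica, frontal_share = 0.6,
                                lowfreq_share = 0.6, line_ratio = 10,
                                frontal_channels = c("Fp1", "Fp2")) {
  stopifnot(inherits(ica, "ica_decomposition"))
  ncomp <- nrow(ica$components)
  fidx <- which(ica$channels %in% frontal_channels)
  labels <- character(ncomp)
  scores <- matrix(NA_real_, ncomp, 3,
                   dimnames = list(NULL, c("frontal", "lowfreq", "line")))
  for (i in seq_len(ncomp)) {
    a <- abs(ica$mixing[, i])
    frontal <- if (length(fidx)) sum(a[fidx]) / sum(a) else 0
    psd <- welch_psd(ica$components[i, ], ica$fs,
                     window_s = min(4, floor(ncol(ica$components) / ica$fs / 4)))
    total <- trapz(psd$frequencies, psd$density)
    low <- band_power(psd, c(0, 4)) / total
    nyq <- ica$fs / 2
    line <- if (nyq > 50) {
      sel <- psd$frequencies >= 49 & psd$frequencies <= 51
      max(psd$density[sel]) / stats::median(psd$density)
    } else 0
    scores[i, ] <- c(frontal, low, line)
    labels[i] <- if (frontal > frontal_share && low > lowfreq_share)
      "ocular" else if (line > line_ratio) "line" else "brain"
  }
  attr(labels, "scores") <- scores
  labels
}

#' Remove labelled components and re-project the data
#'
#' Zeroes the non-brain components and maps the decomposition back to the
#' channel space, returning a brain-only recording.
#'
#' @param rec The [eeg_recording()] the decomposition was computed from.
#' @param ica An `ica_decomposition`.
#' @param labels Labels from [classify_components()] (same length as the
#'   number of components).
#' @param drop Labels to remove.
#' @return The cleaned recording.
#' @export
remove_components <- function(rec, ica, labels, drop = c("ocular", "line")) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(ica, "ica_decomposition"),
            length(labels) == nrow(ica$components))
  keep <- !(labels %in% drop)
  Xc <- if (any(keep)) {
    ica$mixing[, keep, drop = FALSE] %*%
      ica$components[keep, , drop = FALSE]
  } else {
    matrix(0, length(ica$channels), ncol(ica$components))
  }
  rec$data <- t(Xc + ica$means)
  colnames(rec$data) <- rec$channels
  log_step(rec, sprintf("remove_components dropped=%d", sum(!keep)))
}

#' Full three-step cleaning pipeline
#'
#' Band-pass filtering ([fir_bandpass()]), artifact-subspace reconstruction
#' ([asr_clean()]), and ICA-based non-brain component removal
#' ([ica_unmix()], [classify_components()], [remove_components()]), in that
#' order.
#'
#' @param rec An [eeg_recording()].
#' @param band Passband edges (Hz).
#' @param cutoff_k ASR variance threshold.
#' @param seed Integer seed for the ICA initialization.
#' @return List with `recording` (cleaned) and `report` (filter spec, ASR
#'   reconstructed fraction, component labels and rule scores, unmixing
#'   matrix).
#' @export
preprocess_recording <- function(rec, band = c(1, 45), cutoff_k = 20, seed = 1L) {
  filtered <- fir_bandpass(rec, band)
  asr <- asr_clean(filtered, cutoff_k = cutoff_k)
  ica <- ica_unmix(asr$recording, seed = seed)
  labels <- classify_components(ica)
  clean <- remove_components(asr$recording, ica, labels)
  list(recording = clean,
       report = list(filter = sprintf("zero-phase FIR band-pass [%g, %g] Hz",
                                      band[1], band[2]),
                     asr_reconstructed_fraction = asr$reconstructed_fraction,
                     component_labels = labels,
                     component_scores = attr(labels, "scores"),
                     unmixing = ica$unmixing,
                     ica_converged = ica$converged,
                     seed = seed))
}
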