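#' Read a recording from the tab-separated dialect
#'
#' The on-disk dialect mirrors the headband's text logger: `#`-prefixed
#' header lines (`fs`, `units`, `channels`, optionally `gain` and
#' `provenance`), then one row per sample: sample index followed by one
#' tab-separated value per channel.  `units` is `uV` (values pass through)
#' or `counts` (raw block-sum data, converted to input-referred microvolts
#' with [counts_to_input_microvolts()] using the header `gain`).
#'
#' @param path File path.
#' @param cfg A [sensor_config()] used for counts-mode conversion.
#' @return An [eeg_recording()] in microvolts.
#' @export
read_recording <- function(path, cfg = sensor_config()) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && !identical(hdr_idx, seq_along(hdr_idx)))
    stop("read_recording: header lines must precede all data rows")
  header <- list()
  for (ln in lines[hdr_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) header[[trimws(m[2])]] <- trimws(m[3])
  }
  for (key in c("fs", "units", "channels"))
    if (is.null(header[[key]]))
      stop("read_recording: missing mandatory header key '", key, "'")
  fs <- as.numeric(header$fs)
  units <- header$units
  channels <- strsplit(header$channels, "[[:space:]]+")[[1]]
  data_lines <- lines[-hdr_idx]
  data_lines <- data_lines[nzchar(data_lines)]
  ncol_expected <- length(channels) + 1L
  vals <- matrix(NA_real_, length(data_lines), length(channels))
  for (i in seq_along(data_lines)) {
    parts <- strsplit(data_lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != ncol_expected)
      stop("read_recording: parse error at line ",
           length(hdr_idx) + i, ": expected ", ncol_expected,
           " columns, found ", length(parts))
    v <- suppressWarnings(as.numeric(parts[-1]))
    if (any(is.na(v)))
      stop("read_recording: parse error at line ",
           length(hdr_idx) + i, ": non-numeric cell")
    vals[i, ] <- v
  }
  prov <- if (!is.null(header$provenance))
    strsplit(header$provenance, " -> ", fixed = TRUE)[[1]] else character()
  if (identical(units, "uV")) {
    eeg_recording(vals, fs, channels, provenance = prov)
  } else if (identical(units, "counts")) {
    if (is.null(header$gain))
      stop("read_recording: counts mode requires a 'gain' header key")
    gain <- as.numeric(header$gain)
    uv <- ((vals / cfg$oversample_factor) *
             (cfg$v_supply / 2^cfg$adc_bits) - cfg$v_ref) / gain * 1e6
    eeg_recording(uv, fs, channels,
                  provenance = c(prov,
                                 sprintf("counts_to_uV gain=%g", gain)))
  } else stop("read_recording: unknown units '", units, "'")
}

#' Write a recording in the tab-separated dialect
#'
#' Microvolt values are written with full double precision (17 significant
#' digits, locale-independent), so `read_recording(write_recording(x))`
#' round-trips bit-exactly.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# fs: %.17g", rec$fs),
               "# units: uV",
               paste("# channels:", paste(rec$channels, collapse = " ")),
               if (length(rec$provenance))
                 paste("# provenance:",
                       paste(rec$provenance, collapse = " -> "))),
             con)
  rows <- apply(rec$data, 1, function(v)
    paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(seq_len(nrow(rec$data)) - 1L, rows, sep = "\t"), con)
  invisible(path)
}

#' Load a bundled fixture
#'
#' Named reference tables shipped with the package:
#' * `"cohort_beta"`: the reference driving cohort -- per-subject
#'   session-mean beta powers (uV^2) for ten drivers in the three driving
#'   conditions, as a 10 x 3 x 6 array (subjects x conditions x channels);
#' * `"band_definitions"`: the standard band table ([band_specs()]);
#' * `"sensor_defaults"`: the default [sensor_config()].
#'
#' @param name Fixture name.
#' @return The fixture object.
#' @examples
#' tb <- load_fixture("cohort_beta")
#' tb["1", "ADAS1", "Fp1"]   # 2.33
#' @export
load_fixture <- function(name) {
  available <- c("cohort_beta", "band_definitions", "sensor_defaults")
  if (!name %in% available)
    stop("load_fixture: unknown fixture '", name, "'; available: ",
         paste(available, collapse = ", "))
  switch(name,
         cohort_beta = {
           path <- system.file("extdata", "cohort_beta_power.tsv",
                               package = "betadrive", mustWork = TRUE)
           df <- utils::read.delim(path, check.names = FALSE)
           channels <- setdiff(names(df), c("subject", "condition"))
           subjects <- sort(unique(df$subject))
           conds <- unique(df$condition)
           arr <- array(NA_real_,
                        dim = c(length(subjects), length(conds),
                                length(channels)),
                        dimnames = list(as.character(subjects), conds,
                                        channels))
           for (r in seq_len(nrow(df)))
             arr[as.character(df$subject[r]), df$condition[r], ] <-
               as.numeric(df[r, channels])
           arr
         },
         band_definitions = band_specs(),
         sensor_defaults = sensor_config())
}
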