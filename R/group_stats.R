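#' Two-sample Wilcoxon rank-sum test
#'
#' Mann-Whitney/Wilcoxon rank-sum comparison of two independent samples
#' using mid-ranks for ties.  Two methods:
#' * `"normal"`: large-sample approximation
#'   `z = (W - n(n+m+1)/2) / sqrt(var)` with the tie-corrected variance
#'   `nm/12 * (n+m+1 - sum(t^3-t)/((n+m)(n+m-1)))`, two-sided, without
#'   continuity correction;
#' * `"exact"`: tie-aware enumeration of the permutation null distribution
#'   of the rank sum (available for `n + m <= 24`), two-sided probability
#'   `min(1, 2 min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @param method `"normal"` or `"exact"`.
#' @return A `rank_test_result`: `statistic` (rank sum of `x`), `method`,
#'   `p.value` (two-sided, in (0, 1]), `ties` (note on tie handling).
#' @examples
#' ranksum_test(c(1, 2, 3), c(4, 5, 6), method = "exact")$p.value   # 0.1
#' @export
ranksum_test <- function(x, y, method = c("normal", "exact")) {
  method <- match.arg(method)
  if (length(x) < 2L || length(y) < 2L)
    stop("ranksum_test: each group needs at least 2 values")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))                      # mid-ranks
  w <- sum(r[seq_len(n)])
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (method == "normal") {
    mu <- n * (N + 1) / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n * m / 12 * ((N + 1) - tie_term)
    if (v <= 0) stop("ranksum_test: zero variance (all values tied)")
    z <- (w - mu) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    if (N > 24)
      stop("ranksum_test: exact enumeration limited to n + m <= 24")
    p <- ranksum_exact_p(r, n, w)
  }
  structure(list(statistic = w, method = method,
                 p.value = min(max(p, .Machine$double.xmin), 1),
                 ties = if (has_ties)
                   "mid-ranks; tie-corrected variance / tie-aware enumeration"
                 else "no ties"),
            class = "rank_test_result")
}

# Exact two-sided p for the rank sum via dynamic programming over doubled
# (integer) mid-ranks: counts subsets of size n by rank sum.
ranksum_exact_p <- function(r, n, w) {
  r2 <- as.integer(round(2 * r))
  S <- sum(r2)
  # counts[k + 1, s + 1] = number of size-k subsets with doubled-rank sum s
  counts <- matrix(0, n + 1L, S + 1L)
  counts[1L, 1L] <- 1
  for (v in r2) {
    kmax <- n
    for (k in kmax:1) {
      shifted <- c(numeric(v), counts[k, seq_len(S + 1L - v)])
      counts[k + 1L, ] <- counts[k + 1L, ] + shifted
    }
  }
  dist <- counts[n + 1L, ]
  total <- sum(dist)
  w2 <- as.integer(round(2 * w))
  pl <- sum(dist[seq_len(w2 + 1L)]) / total
  pu <- sum(dist[(w2 + 1L):(S + 1L)]) / total
  min(1, 2 * min(pl, pu))
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank comparison of paired samples: zero differences are dropped
#' (their count is reported), absolute differences are mid-ranked, and the
#' statistic is the sum of ranks of the positive differences.  The exact
#' method enumerates the `2^n` sign-flip null (default for `n <= 20`); the
#' normal method uses the tie-corrected large-sample approximation without
#' continuity correction.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @param method `"auto"` (exact when `n <= 20`), `"exact"` or `"normal"`.
#' @return A `rank_test_result` with `statistic` (V), `p.value`,
#'   `n_zero_dropped`.  When every difference is zero the test is
#'   degenerate: `p.value` is `NA` and `degenerate = TRUE`.
#' @export
signed_rank_test <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(structure(list(statistic = NA_real_, method = "degenerate",
                          p.value = NA_real_, n_zero_dropped = n_zero,
                          degenerate = TRUE),
                     class = "rank_test_result"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (method == "auto") method <- if (n <= 20L) "exact" else "normal"
  if (method == "exact") {
    r2 <- as.integer(round(2 * r))
    S <- sum(r2)
    dist <- numeric(S + 1L); dist[1L] <- 1
    for (val in r2)
      dist <- dist + c(numeric(val), dist[seq_len(S + 1L - val)])
    total <- sum(dist)
    v2 <- as.integer(round(2 * v))
    pl <- sum(dist[seq_len(v2 + 1L)]) / total
    pu <- sum(dist[(v2 + 1L):(S + 1L)]) / total
    p <- min(1, 2 * min(pl, pu))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    vv <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(vv)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = v, method = method,
                 p.value = min(max(p, .Machine$double.xmin), 1),
                 n_zero_dropped = n_zero, degenerate = FALSE),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("<rank_test_result> statistic = %s, method = %s, p = %s\n",
              format(x$statistic), x$method, format.pval(x$p.value)))
  invisible(x)
}

#' Five-number percentile summary
#'
#' The 5th, 25th, 50th, 75th and 95th percentiles by linear interpolation
#' (the whisker/box/median levels of the cohort box plots).
#'
#' @param values Numeric vector with at least one value.
#' @return Named numeric vector `p5, p25, p50, p75, p95` (non-decreasing).
#' @export
percentile_summary <- function(values) {
  stopifnot(length(values) >= 1L)
  q <- stats::quantile(values, probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                       names = FALSE, type = 7)
  stats::setNames(q, c("p5", "p25", "p50", "p75", "p95"))
}

#' Channel-by-channel condition comparison matrix
#'
#' Applies the rank-sum test (normal approximation) to every channel and
#' every condition pair of a cohort beta-power table, mirroring the layout
#' of the published probability table: rows Fp1..O2, columns ADAS1 vs
#' ADAS2, ADAS1 vs Manual, ADAS2 vs Manual.
#'
#' Display rounding follows the published convention: two decimals, three
#' when the value is below 0.005.
#'
#' @param cohort A subjects x conditions x channels array of session-mean
#'   beta powers (uV^2), complete (no missing cells); dimension names must
#'   identify the conditions and channels.
#' @param method Test method passed to [ranksum_test()].
#' @return A `comparison_table`: numeric channels x pairs matrix of
#'   unrounded two-sided probabilities, with attribute `display` (the
#'   rounded character matrix).
#' @export
build_comparison_table <- function(cohort, method = "normal") {
  stopifnot(length(dim(cohort)) == 3L)
  if (any(is.na(cohort)))
    stop("build_comparison_table: cohort table must be complete")
  conds <- dimnames(cohort)[[2]]
  channels <- dimnames(cohort)[[3]]
  stopifnot(all(c("Manual", "ADAS1", "ADAS2") %in% conds))
  pairs <- list(c("ADAS1", "ADAS2"), c("ADAS1", "Manual"),
                c("ADAS2", "Manual"))
  out <- matrix(NA_real_, length(channels), length(pairs),
                dimnames = list(channels,
                                vapply(pairs, paste, "", collapse = " vs ")))
  for (ch in seq_along(channels)) {
    for (p in seq_along(pairs)) {
      out[ch, p] <- ranksum_test(cohort[, pairs[[p]][1], ch],
                                 cohort[, pairs[[p]][2], ch],
                                 method = method)$p.value
    }
  }
  disp <- matrix(format_probability(out), nrow(out), ncol(out),
                 dimnames = dimnames(out))
  structure(out, class = c("comparison_table", "matrix"), display = disp)
}

#' Published-style probability rounding
#'
#' Two decimals, three below 0.005.
#' @param p Numeric probabilities.
#' @return Character vector.
#' @export
format_probability <- function(p) {
  ifelse(p < 0.005, sprintf("%.3f", p), sprintf("%.2f", p))
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("<comparison_table> two-sided rank-sum probabilities\n")
  print(attr(x, "display"), quote = FALSE)
  invisible(x)
}
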