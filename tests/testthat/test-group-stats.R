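test_that("rank-sum normal method matches the tie-corrected reference", {
  set.seed(3)
  for (rep in 1:10) {
    x <- round(rlnorm(10, 1, 0.4), 2)
    y <- round(rlnorm(10, 1.3, 0.4), 2)
    ours <- ranksum_test(x, y, method = "normal")$p.value
    ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
  expect_equal(ranksum_test(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_error(ranksum_test(1, c(1, 2)), "at least 2")
})

test_that("rank-sum exact method equals brute-force enumeration", {
  set.seed(5)
  for (rep in 1:5) {
    x <- round(rnorm(6), 1)      # rounding induces occasional ties
    y <- round(rnorm(6, 0.8), 1)
    ours <- ranksum_test(x, y, method = "exact")$p.value
    expect_equal(ours, ranksum_brute_p(x, y), tolerance = 1e-12)
  }
  # exact and normal agree at n = m = 10 on the reference cohort; the gap
  # of the uncorrected normal approximation peaks near p ~ 0.7 and stays
  # below 0.04 on these columns
  tb <- ref_cohort()
  for (ch in dimnames(tb)[[3]]) {
    pe <- ranksum_test(tb[, "ADAS1", ch], tb[, "Manual", ch],
                       method = "exact")$p.value
    pn <- ranksum_test(tb[, "ADAS1", ch], tb[, "Manual", ch],
                       method = "normal")$p.value
    expect_lt(abs(pe - pn), 0.04)
  }
})

test_that("signed-rank test matches closed forms and brute force", {
  # ten all-positive differences: extreme tail 2/2^10
  r <- signed_rank_test(2:11, 1:10, method = "exact")
  expect_equal(r$p.value, 2 / 1024)
  # identical pairs: degenerate
  dg <- signed_rank_test(1:5, 1:5)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$p.value))
  expect_equal(dg$n_zero_dropped, 5L)
  set.seed(8)
  for (rep in 1:5) {
    x <- round(rnorm(8), 1)
    y <- round(rnorm(8, 0.5), 1)
    if (any(x == y)) next
    expect_equal(signed_rank_test(x, y, method = "exact")$p.value,
                 signedrank_brute_p(x, y), tolerance = 1e-12)
  }
})

test_that("percentile summary uses linear interpolation and is monotone", {
  expect_equal(percentile_summary(1:10)[["p50"]], 5.5)
  expect_equal(unname(percentile_summary(rep(3.7, 8))), rep(3.7, 5))
  set.seed(10)
  for (rep in 1:10) {
    v <- rnorm(sample(5:50, 1))
    ps <- percentile_summary(v)
    expect_true(all(diff(ps) >= 0))
    expect_equal(unname(ps),
                 unname(quantile(sort(v), c(.05, .25, .5, .75, .95))))
  }
})

test_that("monotonicity: shifting one group moves the one-sided evidence", {
  set.seed(11)
  x <- rlnorm(10, 1, 0.3)
  y <- rlnorm(10, 1, 0.3)
  stat_shift <- vapply(c(0, 0.5, 1, 2), function(s)
    ranksum_test(x, y + s)$statistic, numeric(1))
  # rank sum of x can only fall as y grows
  expect_true(all(diff(stat_shift) <= 0))
})

test_that("comparison table reproduces the reference cohort probabilities", {
  tb <- ref_cohort()
  cm <- build_comparison_table(tb)
  disp <- attr(cm, "display")
  # the five significant cells of the published table, at printed rounding
  expect_equal(disp["Fp1", "ADAS1 vs ADAS2"], "0.05")
  expect_equal(disp["C3", "ADAS1 vs Manual"], "0.02")
  expect_equal(disp["O1", "ADAS1 vs Manual"], "0.02")
  expect_equal(disp["O2", "ADAS1 vs ADAS2"], "0.02")
  expect_equal(disp["O2", "ADAS1 vs Manual"], "0.003")
  # unrounded values retained and in range
  expect_true(all(cm > 0 & cm <= 1))
  # permuting subjects leaves every cell unchanged
  cm2 <- build_comparison_table(tb[sample(10), , ])
  expect_equal(unclass(cm2), unclass(cm))
  expect_error(build_comparison_table(tb[, 1:2, ]), "Manual|ADAS")
})

test_that("null cohorts rarely produce significant cells", {
  set.seed(12)
  n_sig <- 0L
  n_try <- 60L
  for (rep in seq_len(n_try)) {
    arr <- array(rlnorm(10 * 3 * 6, 1, 0.3), c(10, 3, 6),
                 dimnames = list(1:10, c("Manual", "ADAS1", "ADAS2"),
                                 headband_channels()))
    cm <- build_comparison_table(arr)
    if (any(cm < 0.05)) n_sig <- n_sig + 1L
  }
  # 18 tests per cohort at ~5% each: most null cohorts show something only
  # rarely below the family-wise chance level; require no excess
  expect_lt(n_sig / n_try, 0.85)
  # per-cell rate near nominal
  expect_lt(mean(replicate(200, {
    ranksum_test(rnorm(10), rnorm(10))$p.value
  }) <= 0.05), 0.12)
})
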