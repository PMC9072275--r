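test_that("percent error follows (ref - test)/ref and zero refs are excluded", {
  expect_equal(percent_error(4, 3), 25)
  expect_equal(percent_error(7, 7), 0)
  expect_true(is.na(percent_error(0, 1)))

  acc <- overall_accuracy(c(4, 10), c(3, 10))
  expect_equal(acc$error_pct, 12.5)       # mean(25, 0)
  expect_equal(acc$accuracy_pct, 87.5)
  expect_equal(overall_accuracy(c(2), c(1))$accuracy_pct, 50)
  perfect <- overall_accuracy(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$accuracy_pct, 100)
  # complement identity with zero-ref exclusion counted
  mixed <- overall_accuracy(c(0, 4, 5), c(1, 3, 5))
  expect_equal(mixed$accuracy_pct + mixed$error_pct, 100)
  expect_equal(mixed$n_excluded_zero_ref, 1)
  expect_error(overall_accuracy(c(0, 0), c(1, 2)), "nonzero")
})

test_that("Pearson correlation matches the sum-of-products formula", {
  expect_equal(pearson_agreement(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_agreement(c(1, 2, 3), c(3, 2, 1))$r, -1)
  set.seed(10)
  x <- rnorm(10); y <- 0.6 * x + rnorm(10, 0, 0.5)
  got <- pearson_agreement(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_direct, tolerance = 1e-12)
  expect_equal(got$r2, r_direct^2, tolerance = 1e-12)
  expect_error(pearson_agreement(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("ICC(2,1) matches the aov mean-squares oracle and penalizes offsets", {
  expect_equal(icc_agreement(1:5, 1:5)$icc, 1)
  off <- icc_agreement(1:5, 2:6)
  expect_lt(off$icc, 1)
  expect_equal(off$icc, icc_oracle(1:5, 2:6), tolerance = 1e-10)

  for (s in 1:100) {
    set.seed(s)
    n <- sample(5:25, 1)
    base <- rnorm(n, 5, 2)
    x <- base + rnorm(n, 0, 0.7)
    y <- base + rnorm(n, 0.3, 0.7)
    expect_equal(icc_agreement(x, y)$icc, icc_oracle(x, y), tolerance = 1e-10)
  }
  expect_error(icc_agreement(rep(1, 6), rep(1, 6)), "between-row")
})

test_that("ICC confidence interval brackets the point estimate", {
  set.seed(2)
  base <- rnorm(20, 5, 2)
  r <- icc_agreement(base + rnorm(20, 0, 1), base + rnorm(20, 0, 1))
  expect_lt(r$ci_lo, r$icc)
  expect_gt(r$ci_hi, r$icc)
  expect_true(r$icc >= -1 && r$icc <= 1)
})

test_that("Bland-Altman limits follow mean(d) +/- 1.96 sd(d)", {
  ba0 <- bland_altman(c(1, 2), c(1, 2))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa_halfwidth, 0)

  # diffs {1,1,1,5}: mean 2, sample SD 2, half-width 3.92
  ba <- bland_altman(c(2, 3, 4, 10), c(1, 2, 3, 5))
  expect_equal(ba$mean_diff, 2)
  expect_equal(ba$loa_halfwidth, 3.92)
  expect_equal(ba$loa_hi - ba$loa_lo, 2 * ba$loa_halfwidth)

  # antisymmetry
  set.seed(6)
  a <- rnorm(12); b <- rnorm(12)
  f <- bland_altman(a, b); g <- bland_altman(b, a)
  expect_equal(f$mean_diff, -g$mean_diff)
  expect_equal(f$loa_halfwidth, g$loa_halfwidth)
  expect_error(bland_altman(1, 1), "n >= 2")
})

test_that("exact Wilcoxon matches full sign-enumeration for small n", {
  # 5 strictly positive differences: 2/2^5
  w5 <- wilcoxon_paired(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(w5$p, 0.0625)
  expect_true(w5$exact)

  expect_equal(wilcoxon_paired(1:6, 1:6)$p, 1.0)
  expect_true(wilcoxon_paired(1:6, 1:6)$all_zero)

  for (s in 1:100) {
    set.seed(s)
    n <- sample(4:12, 1)
    d <- rnorm(n, 0.3)       # continuous: no ties, no zeros a.s.
    got <- wilcoxon_paired(d + 1, rep(1, n))
    expect_true(got$exact)
    expect_equal(got$p, wilcox_enum_oracle(d), tolerance = 1e-12)
  }
})

test_that("Wilcoxon falls back to a tie-corrected normal approximation", {
  x <- c(3, 3, 3, 5, 5, 5, 7, 7, 2, 2)
  y <- c(1, 1, 1, 2, 2, 2, 3, 3, 4, 4)
  got <- wilcoxon_paired(x, y)
  expect_false(got$exact)
  expect_true(got$p > 0 && got$p <= 1)
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))$p.value
  expect_equal(got$p, ref, tolerance = 1e-10)
})

test_that("per-condition summaries use sample variance and flag singletons", {
  study <- data.frame(subject_id = rep(c("a", "b", "c"), 2),
                      foil_pd = rep(c(2, 4), each = 3),
                      apct_pd = c(1, 3, 5, 2, 2, 2),
                      vog_pd = c(1, 3, 5, 2, 2, 2))
  cs <- condition_summary(study)
  expect_equal(cs$apct_mean_pd, c(3, 2))
  expect_equal(cs$apct_var_pd2, c(4, 0))   # n-1 denominator
  expect_equal(cs$apct_mean_deg, pd_to_deg(c(3, 2)))

  one <- data.frame(subject_id = "a", foil_pd = 6, apct_pd = 5, vog_pd = 4)
  cs1 <- condition_summary(one)
  expect_true(cs1$single_record)
  expect_equal(cs1$apct_sd_pd, 0)
})

test_that("the full report is order-invariant and handles perfect agreement", {
  set.seed(12)
  study <- expand.grid(subject_id = sprintf("S%02d", 1:10),
                       foil_pd = c(1, 2, 4, 6, 8, 10),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  study$apct_pd <- pmin(10, pmax(0, round(study$foil_pd + rnorm(60, 0, 1.5))))
  study$vog_pd <- pmax(0, study$foil_pd + rnorm(60, 0, 0.5))
  rep1 <- build_report(study)
  shuffled <- study[sample(nrow(study)), ]
  rep2 <- build_report(shuffled)
  expect_equal(rep1$icc, rep2$icc)
  expect_equal(rep1$pearson_r, rep2$pearson_r)
  expect_equal(rep1$overall_error_pct, rep2$overall_error_pct)
  expect_equal(rep1$overall_accuracy_pct + rep1$overall_error_pct, 100)

  perfect <- study
  perfect$vog_pd <- perfect$apct_pd
  perfect$apct_pd <- pmax(perfect$apct_pd, 1)  # avoid zero refs
  perfect$vog_pd <- perfect$apct_pd
  repp <- build_report(perfect)
  expect_equal(repp$pearson_r2, 1)
  expect_equal(repp$icc, 1)
  expect_equal(repp$ba_mean_diff_pd, 0)
  expect_equal(repp$overall_error_pct, 0)
})
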