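# Method-agreement statistics comparing the automated estimate against the
# prism cover test over a study table: percent error / accuracy, Pearson
# correlation, ICC(2,1) with F-based CI, Bland-Altman limits of agreement,
# paired two-sided Wilcoxon per condition, and per-condition summaries.

#' Percent error of a test reading against a reference
#'
#' `(ref - test) / ref * 100`. Undefined (NA) where the reference is zero;
#' aggregate statistics exclude and count such pairs.
#'
#' @param ref Reference (cover test) readings, PD.
#' @param test Test (automated) estimates, PD.
#' @return Percent error, `NA` where `ref == 0`.
#' @export
percent_error <- function(ref, test) {
  stopifnot(length(ref) == length(test))
  out <- (ref - test) / ref * 100
  out[ref == 0] <- NA_real_
  out
}

#' Overall accuracy and error rate
#'
#' Error rate is the mean absolute percent error over pairs with a nonzero
#' reference; accuracy is its complement to 100, so the two always sum to
#' 100 exactly.
#'
#' @param ref,test Paired readings (PD).
#' @return List with `accuracy_pct`, `error_pct`, `n_used`,
#'   `n_excluded_zero_ref`.
#' @export
overall_accuracy <- function(ref, test) {
  pe <- percent_error(ref, test)
  ok <- !is.na(pe)
  if (!any(ok)) stop("no pairs with nonzero reference reading", call. = FALSE)
  err <- mean(abs(pe[ok]))
  list(accuracy_pct = 100 - err, error_pct = err,
       n_used = sum(ok), n_excluded_zero_ref = sum(!ok))
}

#' Pearson correlation between two methods
#'
#' Product-moment correlation with a two-sided p-value from the t
#' transform (via [stats::cor.test()]).
#'
#' @param x,y Paired readings, n >= 3, both with nonzero variance.
#' @return List with `r`, `r2`, `p`.
#' @export
pearson_agreement <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("Pearson correlation needs n >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r2 = r^2, p = ct$p.value)
}

#' Intraclass correlation ICC(2,1): two-way random, absolute agreement,
#' single measures
#'
#' Computed from the two-way ANOVA mean squares over an n x 2
#' (subject-condition x method) table; 95% CI by the standard F-based
#' interval (McGraw & Wong) and p-value from the between-row F test.
#'
#' @param x,y Paired measurements (the two methods/raters), n >= 5 rows.
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return List with `icc`, `ci_lo`, `ci_hi`, `p`, `F`, `df1`, `df2` and
#'   the mean squares `msr`, `msc`, `mse`.
#' @export
icc_agreement <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  k <- 2
  if (n < 5L) stop("ICC needs at least 5 paired rows", call. = FALSE)
  dat <- cbind(x, y)
  if (any(!is.finite(dat))) stop("non-finite measurements", call. = FALSE)
  g <- mean(dat)
  rm_ <- rowMeans(dat)
  cm <- colMeans(dat)
  if (stats::var(rm_) == 0) {
    stop("zero between-row variance: ICC undefined", call. = FALSE)
  }
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm - g)^2)
  sst <- sum((dat - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  Fstat <- msr / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  alpha <- 1 - conf_level
  Fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * icc * Fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * Fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  FU <- stats::qf(1 - alpha / 2, df1, v)
  FL <- stats::qf(1 - alpha / 2, v, df1)
  lo <- n * (msr - FU * mse) /
    (FU * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (FL * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * FL * msr)
  list(icc = icc, ci_lo = lo, ci_hi = hi, p = p,
       F = Fstat, df1 = df1, df2 = df2, msr = msr, msc = msc, mse = mse)
}

#' Bland-Altman limits of agreement
#'
#' Differences `d = ref - test`; the bias is `mean(d)` and the 95% limits
#' of agreement are `mean(d) +/- 1.96 * sd(d)` with the sample (n-1) SD.
#'
#' @param ref,test Paired readings, n >= 2.
#' @return List with `mean_diff`, `loa_halfwidth`, `loa_lo`, `loa_hi`,
#'   `sd_diff`, `n`, and the per-pair `mean` and `diff` vectors (for
#'   plotting difference against pairwise mean).
#' @export
bland_altman <- function(ref, test) {
  stopifnot(length(ref) == length(test))
  if (length(ref) < 2L) stop("Bland-Altman needs n >= 2", call. = FALSE)
  d <- ref - test
  m <- mean(d)
  s <- stats::sd(d)
  hw <- 1.96 * s
  list(mean_diff = m, loa_halfwidth = hw, loa_lo = m - hw, loa_hi = m + hw,
       sd_diff = s, n = length(d),
       mean = (ref + test) / 2, diff = d)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped (classic Wilcoxon convention; set
#' `zero_method = "pratt"` to keep them in the ranking). The p-value is
#' exact (signed-rank distribution) for up to 25 nonzero untied
#' differences, otherwise a normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param x,y Paired measurements.
#' @param zero_method `"wilcox"` (drop zeros, default) or `"pratt"`.
#' @param exact_max Largest n for which the exact distribution is used
#'   (default 25).
#' @return List with `p`, `statistic` (W+, the positive-rank sum),
#'   `n_used`, `n_zero`, `exact`, `all_zero` flag.
#' @export
wilcoxon_paired <- function(x, y, zero_method = c("wilcox", "pratt"),
                            exact_max = 25L) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[is.finite(d)]
  nz <- sum(d == 0)
  if (all(d == 0) || length(d) == 0L) {
    return(list(p = 1.0, statistic = 0, n_used = 0L, n_zero = nz,
                exact = TRUE, all_zero = TRUE))
  }
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    ties <- any(duplicated(r))
    if (!ties && n <= exact_max) {
      p <- 2 * min(stats::psignrank(W, n),
                   stats::psignrank(W - 1, n, lower.tail = FALSE))
      return(list(p = min(p, 1), statistic = W, n_used = n, n_zero = nz,
                  exact = TRUE, all_zero = FALSE))
    }
    mu <- n * (n + 1) / 4
    tt <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
  } else {
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    mu <- (n * (n + 1) - nz * (nz + 1)) / 4
    tt <- table(r[d != 0])
    sig2 <- (n * (n + 1) * (2 * n + 1) - nz * (nz + 1) * (2 * nz + 1)) / 24 -
      sum(tt^3 - tt) / 48
    n <- n - nz
  }
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
  p <- 2 * stats::pnorm(-abs(z))
  list(p = min(p, 1), statistic = W, n_used = n, n_zero = nz,
       exact = FALSE, all_zero = FALSE)
}

#' Per-condition summary statistics
#'
#' For each foil strength: mean, sample SD and sample variance of both
#' methods' readings (PD), their degree equivalents via the linear
#' 0.57 deg/PD mapping applied to the PD summaries, and the paired
#' two-sided Wilcoxon p-value comparing the methods.
#'
#' @param study Study table (`subject_id`, `foil_pd`, `apct_pd`, `vog_pd`).
#' @return A data.frame, one row per foil, ordered by foil strength.
#' @export
condition_summary <- function(study) {
  study <- validate_study_table(study)
  foils <- sort(unique(study$foil_pd))
  rows <- lapply(foils, function(f) {
    sub <- study[study$foil_pd == f, ]
    n <- nrow(sub)
    sdv <- function(v) if (n > 1L) stats::sd(v) else 0
    wp <- if (n >= 1L) wilcoxon_paired(sub$apct_pd, sub$vog_pd)$p else NA_real_
    data.frame(foil_pd = f, n = n, single_record = n == 1L,
               apct_mean_pd = mean(sub$apct_pd), apct_sd_pd = sdv(sub$apct_pd),
               apct_var_pd2 = sdv(sub$apct_pd)^2,
               vog_mean_pd = mean(sub$vog_pd), vog_sd_pd = sdv(sub$vog_pd),
               vog_var_pd2 = sdv(sub$vog_pd)^2,
               apct_mean_deg = pd_to_deg(mean(sub$apct_pd)),
               apct_sd_deg = pd_to_deg(sdv(sub$apct_pd)),
               vog_mean_deg = pd_to_deg(mean(sub$vog_pd)),
               vog_sd_deg = pd_to_deg(sdv(sub$vog_pd)),
               wilcoxon_p = wp)
  })
  do.call(rbind, rows)
}

#' Full agreement report for a study table
#'
#' Composes all agreement statistics between the cover-test readings
#' (reference) and the automated estimates (test): Pearson r/r2/p,
#' ICC(2,1) with 95% CI, Bland-Altman bias and limits of agreement,
#' overall accuracy/error, and per-condition summaries with paired
#' Wilcoxon tests. Deterministic and invariant to record order.
#'
#' @param study Study table (`subject_id`, `foil_pd`, `apct_pd`, `vog_pd`),
#'   `vog_pd` filled.
#' @return A list of class `agreement_report`.
#' @export
build_report <- function(study) {
  study <- validate_study_table(study)
  if (any(!is.finite(study$vog_pd))) {
    stop("study table has missing vog_pd values; run the engine first",
         call. = FALSE)
  }
  ref <- study$apct_pd
  test <- study$vog_pd
  pe <- pearson_agreement(ref, test)
  icc <- tryCatch(icc_agreement(ref, test),
                  error = function(e) list(icc = NA_real_, ci_lo = NA_real_,
                                           ci_hi = NA_real_, p = NA_real_))
  ba <- bland_altman(ref, test)
  acc <- overall_accuracy(ref, test)
  structure(list(
    n_records = nrow(study),
    pearson_r = pe$r, pearson_r2 = pe$r2, pearson_p = pe$p,
    icc = icc$icc, icc_ci95_lo = icc$ci_lo, icc_ci95_hi = icc$ci_hi,
    icc_p = icc$p,
    ba_mean_diff_pd = ba$mean_diff, ba_loa_halfwidth_pd = ba$loa_halfwidth,
    ba_loa_lo_pd = ba$loa_lo, ba_loa_hi_pd = ba$loa_hi,
    overall_accuracy_pct = acc$accuracy_pct,
    overall_error_pct = acc$error_pct,
    n_excluded_zero_ref = acc$n_excluded_zero_ref,
    per_condition = condition_summary(study)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat(sprintf("  n = %d records\n", x$n_records))
  cat(sprintf("  Pearson r = %.3f (R2 = %.3f, p = %.3g)\n",
              x$pearson_r, x$pearson_r2, x$pearson_p))
  cat(sprintf("  ICC(2,1) = %.3f [%.3f, %.3f], p = %.3g\n",
              x$icc, x$icc_ci95_lo, x$icc_ci95_hi, x$icc_p))
  cat(sprintf("  Bland-Altman: bias %.2f PD, LoA half-width %.2f PD\n",
              x$ba_mean_diff_pd, x$ba_loa_halfwidth_pd))
  cat(sprintf("  accuracy %.2f%% (error %.2f%%)\n",
              x$overall_accuracy_pct, x$overall_error_pct))
  invisible(x)
}

#' Serialize an agreement report to JSON
#'
#' @param report An [build_report()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  obj <- unclass(report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
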