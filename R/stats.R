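## Nonparametric group comparisons and regressions: paired Wilcoxon per
## frequency across surgical conditions, Mann-Whitney for shallow vs deep
## insertions, and the depth / frequency-position regressions. Per-frequency
## alpha = 0.05, no multiple-testing correction (a Holm option exists but is
## off by default, matching the study design).

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped by default (`"pratt"` keeps them in the
#' ranking). With 15 or fewer non-zero, tie-free differences the exact
#' sign-flip null distribution is used; otherwise the normal approximation
#' with continuity correction. If all differences are zero the test is
#' degenerate: `p = 1` with a warning.
#'
#' @param diffs Numeric paired differences.
#' @param zero_method `"drop"` (default) or `"pratt"`.
#' @param exact_n Largest n for the exact branch.
#' @return List: `statistic` (V, sum of positive ranks), `p_value`
#'   (two-sided), `n` (differences used), `method`.
#' @export
wilcoxon_signed_rank <- function(diffs, zero_method = c("drop", "pratt"),
                                 exact_n = 15) {
  zero_method <- match.arg(zero_method)
  if (length(diffs) < 1) stop("empty differences")
  d <- diffs[!is.na(diffs)]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n = 0L, method = "degenerate"))
  }
  if (zero_method == "pratt") {
    r <- rank(abs(d))
    r <- r[d != 0]
    v <- sum(r[nz > 0])
    n <- length(d)
    mu <- sum(r) / 2
    sig2 <- sum(r^2) / 4
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    return(list(statistic = v, p_value = min(1, 2 * stats::pnorm(-abs(z))),
                n = length(nz), method = "pratt-normal"))
  }
  ties <- any(duplicated(abs(nz)))
  exact <- length(nz) <= exact_n && !ties
  wt <- suppressWarnings(stats::wilcox.test(nz, mu = 0, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # fully tied data carry no evidence
  list(statistic = unname(wt$statistic), p_value = p,
       n = length(nz), method = if (exact) "exact" else "normal-cc")
}

#' Mann-Whitney U test for two independent groups
#'
#' Exact distribution by enumeration when the pooled sample is small
#' (`n + m <= exact_total`) and tie-free; normal approximation with
#' continuity correction otherwise.
#'
#' @param group_a,group_b Numeric vectors, both non-empty.
#' @param exact_total Largest pooled size for the exact branch.
#' @return List: `statistic` (U for `group_a`), `p_value` (two-sided), `n`
#'   (pooled size), `method`.
#' @export
mann_whitney_u <- function(group_a, group_b, exact_total = 12) {
  if (length(group_a) < 1 || length(group_b) < 1)
    stop("both groups must be non-empty")
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- (length(group_a) + length(group_b)) <= exact_total && !ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # degenerate (e.g. fully tied) comparison
  list(statistic = unname(wt$statistic), p_value = p,
       n = length(group_a) + length(group_b),
       method = if (exact) "exact" else "normal-cc")
}

#' Ordinary least-squares regression with a slope test
#'
#' @param x,y Numeric vectors, `n >= 3`, `x` non-constant.
#' @return List: `slope`, `intercept`, `r_squared`, `p_value` (t-test of
#'   the slope), `n`.
#' @export
linear_regression_test <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("x is constant")
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = y[1], r_squared = 0, p_value = 1,
                n = length(x)))
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0           # constant y: no variance explained
  p <- sm$coefficients[2, 4]
  if (!is.finite(p)) p <- if (r2 >= 1 - 1e-12) 0 else 1  # exact fit / flat y
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       p_value = p,
       n = length(x))
}

#' Per-frequency contrasts and regressions of the study design
#'
#' Given the analyzed cohort, computes (a) per-frequency paired Wilcoxon
#' tests of the threshold shifts initial->cochleostomy and
#' initial->inserted (pooled over ears), (b) per-frequency Mann-Whitney
#' tests of the insertion shift between 5Ch and 6Ch groups, (c) an OLS
#' regression of per-ear maximal insertion shift on insertion depth, and
#' (d) an OLS regression of the insertion shift at the 5.6 kHz lattice
#' frequency (5657 Hz) on the characteristic frequency of contact 1.
#' Censored cells are excluded by default. No multiple-testing correction
#' is applied unless `adjust = "holm"`.
#'
#' @param shifts `data.frame` with columns `ear`, `group`, `contrast`
#'   (`"cochleostomy"` or `"inserted"`), `frequency_hz`, `ts_db`,
#'   `censored` (as produced by [analyze_cohort()]).
#' @param metrics Optional `data.frame` with `ear`, `depth_ch1_um` (µm) for
#'   the regressions.
#' @param map A [place_frequency_map()] for the contact-1 frequency
#'   position.
#' @param alpha Per-test significance level.
#' @param exclude_censored Drop censored cells before testing.
#' @param adjust `"none"` (default, matching the per-frequency design) or
#'   `"holm"`.
#' @param regression_frequency Lattice frequency (Hz) for the
#'   frequency-position regression.
#' @return `data.frame` of class `comparison_table`: `contrast`,
#'   `frequency_hz`, `test`, `statistic`, `p`, `n`, `significant`.
#' @export
run_study_contrasts <- function(shifts, metrics = NULL,
                                map = place_frequency_map(), alpha = 0.05,
                                exclude_censored = TRUE,
                                adjust = c("none", "holm"),
                                regression_frequency = 5657) {
  adjust <- match.arg(adjust)
  if (is.null(shifts$group)) stop("shifts must carry group labels")
  sh <- shifts
  if (exclude_censored) sh <- sh[!sh$censored, , drop = FALSE]
  freqs <- sort(unique(shifts$frequency_hz))
  rows <- list()
  add <- function(contrast, f, test, res) {
    rows[[length(rows) + 1]] <<- data.frame(
      contrast = contrast, frequency_hz = f, test = test,
      statistic = res$statistic %||% NA_real_,
      p = res$p_value, n = res$n, stringsAsFactors = FALSE)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  for (con in intersect(c("cochleostomy", "inserted"), unique(sh$contrast))) {
    for (f in freqs) {
      d <- sh$ts_db[sh$contrast == con & sh$frequency_hz == f]
      if (length(d) == 0) next
      res <- suppressWarnings(wilcoxon_signed_rank(d))
      add(paste0("initial_vs_", con), f, "wilcoxon_signed_rank", res)
    }
  }
  ins <- sh[sh$contrast == "inserted", , drop = FALSE]
  for (f in freqs) {
    a <- ins$ts_db[ins$frequency_hz == f & ins$group == "6Ch"]
    b <- ins$ts_db[ins$frequency_hz == f & ins$group == "5Ch"]
    if (length(a) >= 1 && length(b) >= 1)
      add("5Ch_vs_6Ch", f, "mann_whitney_u", mann_whitney_u(a, b))
  }
  if (!is.null(metrics)) {
    max_ts <- stats::aggregate(ts_db ~ ear, data = ins, FUN = max)
    m <- merge(max_ts, metrics, by = "ear")
    if (nrow(m) >= 3) {
      res <- linear_regression_test(m$depth_ch1_um, m$ts_db)
      add("depth_vs_max_ts", NA_real_, "ols_slope",
          list(statistic = res$slope, p_value = res$p_value, n = res$n))
    }
    at_f <- ins[abs(ins$frequency_hz - regression_frequency) < 0.5, ]
    m2 <- merge(at_f, metrics, by = "ear")
    if (nrow(m2) >= 3) {
      cf_khz <- place_to_frequency(m2$depth_ch1_um, map) / 1000
      res <- linear_regression_test(cf_khz, m2$ts_db)
      add("cf_ch1_vs_ts", regression_frequency, "ols_slope",
          list(statistic = res$slope, p_value = res$p_value, n = res$n))
    }
  }
  out <- do.call(rbind, rows)
  p_adj <- if (adjust == "holm") stats::p.adjust(out$p, "holm") else out$p
  out$significant <- p_adj < alpha
  class(out) <- c("comparison_table", class(out))
  out
}
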