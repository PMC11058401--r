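new_test_result <- function(family, statistic, df, p_two_sided,
                            p_one_sided = NA_real_, effect_size = NA_real_,
                            n = NA_integer_, extra = list()) {
  stopifnot(is.na(p_two_sided) || (p_two_sided >= 0 && p_two_sided <= 1))
  structure(c(list(family = family, statistic = statistic, df = df,
                   p_two_sided = p_two_sided, p_one_sided = p_one_sided,
                   effect_size = effect_size, n = n), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4f, df = %s, p = %.4g",
              x$family, x$statistic, paste(round(x$df, 2), collapse = ", "),
              x$p_two_sided))
  if (!is.na(x$effect_size)) cat(sprintf(", effect size = %.4f", x$effect_size))
  cat("\n")
  invisible(x)
}

#' Pooled-variance two-sample t-test
#'
#' Student's two-sample t with pooled variance and `df = n1 + n2 - 2`, as
#' used for the baseline group comparisons. The numerator is
#' `mean2 - mean1`, so a positive statistic means group 2 exceeds group 1.
#' Accepts either summary statistics or raw vectors (`x1`, `x2`), and offers
#' the Welch unpooled variant.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 summary statistics per group.
#' @param x1,x2 alternatively, raw vectors (summaries are then computed).
#' @param welch use the Welch-Satterthwaite unpooled test; default `FALSE`.
#' @return a `test_result` (family `two_sample_t`); `effect_size` is Cohen's
#'   d on the pooled SD.
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2,
                         x1 = NULL, x2 = NULL, welch = FALSE) {
  if (!is.null(x1) || !is.null(x2)) {
    if (is.null(x1) || is.null(x2))
      stop("supply both 'x1' and 'x2'", call. = FALSE)
    mean1 <- mean(x1); sd1 <- stats::sd(x1); n1 <- length(x1)
    mean2 <- mean(x2); sd2 <- stats::sd(x2); n2 <- length(x2)
  }
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be nonnegative", call. = FALSE)
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2)
    stop("undefined t: both groups constant and equal", call. = FALSE)
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    tstat <- (mean2 - mean1) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
    sp <- sqrt((sd1^2 + sd2^2) / 2)
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    sp <- sqrt(sp2)
    tstat <- (mean2 - mean1) / (sp * sqrt(1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  new_test_result("two_sample_t", tstat, df, p,
                  p_one_sided = stats::pt(-abs(tstat), df),
                  effect_size = if (sp > 0) (mean2 - mean1) / sp else NA_real_,
                  n = c(n1 = n1, n2 = n2))
}

#' Paired-samples t-test
#'
#' Tests pre/post change within a group on the differences
#' `d_i = pre_i - post_i` (so an improvement, post above pre, yields a
#' negative statistic; the magnitude convention of the accompanying text is
#' recovered by `abs()`). Cohen's d for the paired design is
#' `mean(d)/sd(d) = t/sqrt(n)` exactly.
#'
#' @param pre,post equal-length numeric vectors.
#' @return a `test_result` (family `paired_t`) with `effect_size` = Cohen's d.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post))
    stop("'pre' and 'post' must have equal length", call. = FALSE)
  ok <- stats::complete.cases(pre, post)
  pre <- pre[ok]; post <- post[ok]
  n <- length(pre)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- pre - post
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0)
      return(new_test_result("paired_t", 0, n - 1, 1, 0.5, 0, n))
    stop("zero variance of differences with nonzero mean: t is infinite",
         call. = FALSE)
  }
  tstat <- mean(d) / (sdd / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), n - 1)
  new_test_result("paired_t", tstat, n - 1, p,
                  p_one_sided = stats::pt(-abs(tstat), n - 1),
                  effect_size = tstat / sqrt(n), n = n)
}

#' Time-by-Group interaction of the 2x2 mixed ANOVA
#'
#' The interaction term of a two-group (between) by two-timepoint (within)
#' repeated-measures ANOVA, computed from the within-subject error
#' decomposition: with per-subject change `d_i`, the interaction sum of
#' squares is `sum_g n_g (dbar_g - dbar)^2 / 2` and the error term is the
#' within-group change variance, giving `F` on `(1, N - 2)` degrees of
#' freedom. This equals the square of the pooled two-sample t on change
#' scores. Participants missing either timepoint are dropped with a warning.
#'
#' @param frame tidy cohort data.frame with columns `participant`, `group`,
#'   `time` (`"pre"`/`"post"`), `measure`, `value`.
#' @param measure which measure to analyze.
#' @return a `test_result` (family `anova_interaction`); `effect_size` is
#'   partial eta squared.
#' @export
mixed_anova_2x2 <- function(frame, measure) {
  fr <- frame[frame$measure == measure, , drop = FALSE]
  if (nrow(fr) == 0) stop("measure not found: ", measure, call. = FALSE)
  w <- stats::reshape(fr[, c("participant", "group", "time", "value")],
                      idvar = c("participant", "group"),
                      timevar = "time", direction = "wide")
  names(w) <- sub("^value\\.", "", names(w))
  if (!all(c("pre", "post") %in% names(w)))
    stop("both timepoints required", call. = FALSE)
  incomplete <- !stats::complete.cases(w$pre, w$post)
  if (any(incomplete)) {
    warning(sum(incomplete), " participant(s) missing a timepoint dropped ",
            "for measure ", measure)
    w <- w[!incomplete, , drop = FALSE]
  }
  groups <- sort(unique(w$group))
  if (length(groups) != 2L) stop("need exactly two groups", call. = FALSE)
  ns <- table(factor(w$group, groups))
  if (any(ns < 2)) stop("each group needs n >= 2", call. = FALSE)
  d <- w$post - w$pre
  n_total <- length(d)
  dbar <- mean(d)
  dbar_g <- tapply(d, factor(w$group, groups), mean)
  ss_int <- sum(as.numeric(ns) * (dbar_g - dbar)^2) / 2
  ss_err <- sum((d - dbar_g[as.character(w$group)])^2) / 2
  df_err <- n_total - 2
  fstat <- (ss_int / 1) / (ss_err / df_err)
  p <- stats::pf(fstat, 1, df_err, lower.tail = FALSE)
  new_test_result("anova_interaction", fstat, c(df1 = 1, df2 = df_err), p,
                  effect_size = partial_eta_squared(fstat, 1, df_err),
                  n = as.integer(n_total),
                  extra = list(group_change_means = as.list(dbar_g)))
}

#' Partial eta squared from an F statistic
#'
#' `F * df1 / (F * df1 + df2)`, the proportion of the effect-plus-error
#' variance attributable to the effect.
#'
#' @param F_value F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return a number in `[0, 1)`.
#' @export
partial_eta_squared <- function(F_value, df1, df2) {
  if (any(F_value < 0) || df1 <= 0 || df2 <= 0)
    stop("need F >= 0 and positive degrees of freedom", call. = FALSE)
  F_value * df1 / (F_value * df1 + df2)
}

#' Pearson correlation between change scores
#'
#' Pearson r with the t-test of zero correlation:
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param dx,dy equal-length change-score vectors, n >= 4.
#' @return a `test_result` (family `pearson_r`) with `effect_size` = r.
#' @export
pearson_change_correlation <- function(dx, dy) {
  if (length(dx) != length(dy))
    stop("'dx' and 'dy' must have equal length", call. = FALSE)
  ok <- stats::complete.cases(dx, dy)
  dx <- dx[ok]; dy <- dy[ok]
  n <- length(dx)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (stats::sd(dx) == 0 || stats::sd(dy) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  r <- sum((dx - mean(dx)) * (dy - mean(dy))) /
    sqrt(sum((dx - mean(dx))^2) * sum((dy - mean(dy))^2))
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  new_test_result("pearson_r", tstat, n - 2, p,
                  p_one_sided = stats::pt(-abs(tstat), n - 2),
                  effect_size = r, n = n, extra = list(r = r))
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' Tests equality of two Pearson correlations from independent samples via
#' the variance-stabilizing transform:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`.
#' Both one- and two-sided normal p values are reported; the one-sided tail
#' is the probability beyond `|z|`.
#'
#' @param r1,n1 first correlation and its sample size (n >= 4, |r| < 1).
#' @param r2,n2 second correlation and its sample size.
#' @return a list of class `correlation_comparison` with `r1`, `r2`, `n1`,
#'   `n2`, `z`, `p_one_sided`, `p_two_sided`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| must be < 1", call. = FALSE)
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in each sample", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(r1 = r1, r2 = r2, n1 = n1, n2 = n2, z = z,
                 p_one_sided = stats::pnorm(-abs(z)),
                 p_two_sided = 2 * stats::pnorm(-abs(z))),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf(paste0("<fisher_z> r1 = %.3f (n = %d) vs r2 = %.3f (n = %d): ",
                     "z = %.3f, one-sided p = %.4g, two-sided p = %.4g\n"),
              x$r1, x$n1, x$r2, x$n2, x$z, x$p_one_sided, x$p_two_sided))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: sort p values ascending, set
#' `adj_i = min_{j >= i} p_(j) * m / j` capped at 1, and reject at level `q`.
#' Output order follows input order; permuting the input permutes the output
#' identically.
#'
#' @param pvals numeric vector of p values in `[0, 1]`.
#' @param q FDR level for the rejection flags; default 0.05.
#' @return list with `adjusted` (numeric) and `rejected` (logical), both in
#'   input order.
#' @export
benjamini_hochberg <- function(pvals, q = 0.05) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  m <- length(pvals)
  o <- order(pvals)
  adj_sorted <- rev(cummin(rev(pvals[o] * m / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, rejected = adjusted <= q)
}

#' Pearson chi-square on a 2x2 table
#'
#' Without continuity correction:
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 degree of freedom.
#'
#' @param a,b,c,d cell counts (group 1 yes/no, group 2 yes/no).
#' @return a `test_result` (family `chi_square`).
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  n <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("zero margin: chi-square undefined",
                              call. = FALSE)
  stat <- n * (a * d - b * c)^2 / prod(margins)
  new_test_result("chi_square", stat, 1,
                  stats::pchisq(stat, 1, lower.tail = FALSE),
                  n = as.integer(n))
}

# power of the two-sided one-sample/paired t at effect size d and size n
paired_t_power <- function(n, d, alpha) {
  ncp <- d * sqrt(n)
  tc <- stats::qt(1 - alpha / 2, n - 1)
  stats::pt(tc, n - 1, ncp, lower.tail = FALSE) +
    stats::pt(-tc, n - 1, ncp)
}

#' Sample size for a paired-samples t-test
#'
#' Smallest n such that the two-sided paired t-test at level `alpha` with
#' noncentrality `d * sqrt(n)` reaches the target power, using the
#' noncentral t distribution (the standard a-priori power computation).
#'
#' @param d effect size (mean difference over SD of differences), nonzero.
#' @param alpha two-sided significance level; default 0.05.
#' @param power target power in (0, 1); default 0.80.
#' @param n_max search ceiling; default 1e5.
#' @return integer sample size.
#' @export
power_paired_n <- function(d, alpha = 0.05, power = 0.80, n_max = 1e5) {
  if (d == 0) stop("effect size must be nonzero", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  d <- abs(d)
  lo <- 2L
  if (paired_t_power(lo, d, alpha) >= power) return(lo)
  hi <- lo
  while (paired_t_power(hi, d, alpha) < power) {
    hi <- hi * 2L
    if (hi > n_max) stop("target power unattainable below n_max",
                         call. = FALSE)
  }
  while (hi - lo > 1L) {            # power is nondecreasing in n
    mid <- (lo + hi) %/% 2L
    if (paired_t_power(mid, d, alpha) >= power) hi <- mid else lo <- mid
  }
  hi
}

#' Trail-making difference score
#'
#' Part B minus Part A completion time, per participant (vectorized).
#'
#' @param b_sec,a_sec positive completion times in seconds.
#' @return `b_sec - a_sec`.
#' @export
tmt_b_minus_a <- function(b_sec, a_sec) {
  if (any(b_sec <= 0, na.rm = TRUE) || any(a_sec <= 0, na.rm = TRUE))
    stop("completion times must be positive", call. = FALSE)
  b_sec - a_sec
}
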