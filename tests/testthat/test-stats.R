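test_that("pooled two-sample t reproduces printed baselines and base R", {
  # from published group summaries
  expect_equal(round(two_sample_t(95.445, 4.254, 35,
                                  97.476, 3.507, 35)$statistic, 3), 2.179)
  expect_equal(round(abs(two_sample_t(31.641, 17.726, 35,
                                      24.031, 10.244, 35)$statistic), 3),
               2.199)
  expect_identical(two_sample_t(5, 1, 10, 5, 1, 10)$statistic, 0)
  # raw-vector path agrees with the summary path, the from-scratch oracle
  # and stats::t.test
  set.seed(21)
  for (i in 1:5) {
    x1 <- rnorm(5 + i); x2 <- rnorm(7)
    a <- two_sample_t(x1 = x1, x2 = x2)
    b <- two_sample_t(mean(x1), sd(x1), length(x1),
                      mean(x2), sd(x2), length(x2))
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
    expect_equal(a$statistic, oracle_pooled_t(x1, x2), tolerance = 1e-12)
    tt <- t.test(x2, x1, var.equal = TRUE)
    expect_equal(a$statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(a$p_two_sided, tt$p.value, tolerance = 1e-10)
    w <- two_sample_t(x1 = x1, x2 = x2, welch = TRUE)
    tw <- t.test(x2, x1)
    expect_equal(w$statistic, unname(tw$statistic), tolerance = 1e-10)
    expect_equal(unname(w$df), unname(tw$parameter), tolerance = 1e-8)
  }
  expect_error(two_sample_t(1, 0, 5, 1, 0, 5), "undefined")
})

test_that("paired t satisfies d = t / sqrt(n) exactly and matches base R", {
  set.seed(22)
  for (n in c(5, 12, 35)) {
    pre <- rnorm(n, 100, 4); post <- pre + rnorm(n, 0.4, 1.5)
    res <- paired_t(pre, post)
    expect_identical(res$effect_size, res$statistic / sqrt(n))
    tt <- t.test(pre, post, paired = TRUE)
    expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_two_sided, tt$p.value, tolerance = 1e-10)
  }
  z <- paired_t(1:5, 1:5)
  expect_identical(z$statistic, 0)
  expect_identical(z$effect_size, 0)
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "infinite")
})

test_that("published paired effect sizes follow from t and n", {
  expect_equal(round(2.078 / sqrt(35), 3), 0.351)
  expect_equal(round(1.281 / sqrt(35), 3), 0.217)
})

test_that("interaction F equals squared change-score t and matches aov", {
  set.seed(23)
  for (i in 1:6) {
    n1 <- sample(4:20, 1); n2 <- sample(4:20, 1)
    ids <- sprintf("S%02d", seq_len(n1 + n2))
    grp <- rep(c("intervention", "control"), c(n1, n2))
    pre <- rnorm(n1 + n2, 100, 4)
    post <- pre + rnorm(n1 + n2, ifelse(grp == "intervention", 0.8, 0), 1.4)
    fr <- rbind(data.frame(participant = ids, group = grp, time = "pre",
                           measure = "m", value = pre),
                data.frame(participant = ids, group = grp, time = "post",
                           measure = "m", value = post))
    an <- mixed_anova_2x2(fr, "m")
    tt <- two_sample_t(x1 = (post - pre)[grp == "intervention"],
                       x2 = (post - pre)[grp == "control"])
    expect_equal(an$statistic, tt$statistic^2, tolerance = 1e-10)
    # independent fit: aov with Error(subject) stratum
    long <- rbind(data.frame(id = ids, g = grp, t = "pre", y = pre),
                  data.frame(id = ids, g = grp, t = "post", y = post))
    fit <- summary(aov(y ~ g * t + Error(id / t), data = long))
    ftab <- fit[["Error: id:t"]][[1]]
    expect_equal(an$statistic, ftab["g:t", "F value"], tolerance = 1e-8)
    expect_equal(an$p_two_sided, ftab["g:t", "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("interaction is null when both groups change identically", {
  set.seed(24)
  n <- 10
  ids <- sprintf("S%02d", 1:(2 * n))
  grp <- rep(c("intervention", "control"), each = n)
  pre <- rnorm(2 * n, 100, 3)
  shift <- rnorm(n)                      # same change vector in both groups
  post <- pre + c(shift, shift)
  fr <- rbind(data.frame(participant = ids, group = grp, time = "pre",
                         measure = "m", value = pre),
              data.frame(participant = ids, group = grp, time = "post",
                         measure = "m", value = post))
  an <- mixed_anova_2x2(fr, "m")
  expect_lt(an$statistic, 1e-20)
})

test_that("partial eta squared follows its closed form", {
  expect_equal(round(partial_eta_squared(5.292, 1, 68), 3), 0.072)
  expect_equal(round(partial_eta_squared(6.605, 1, 68), 3), 0.089)
  expect_identical(partial_eta_squared(0, 1, 68), 0)
  expect_equal(partial_eta_squared(34, 2, 68), 0.5)
  # strictly increasing in F, bounded in (0, 1)
  f <- seq(0.1, 50, length.out = 40)
  e <- partial_eta_squared(f, 1, 68)
  expect_true(all(diff(e) > 0) && all(e > 0 & e < 1))
})

test_that("change correlation matches the covariance oracle and cor.test", {
  set.seed(25)
  for (i in 1:5) {
    dx <- rnorm(20); dy <- 0.5 * dx + rnorm(20)
    res <- pearson_change_correlation(dx, dy)
    r_oracle <- sum((dx - mean(dx)) * (dy - mean(dy))) /
      sqrt(sum((dx - mean(dx))^2) * sum((dy - mean(dy))^2))
    expect_equal(res$r, r_oracle, tolerance = 1e-12)
    ct <- cor.test(dx, dy)
    expect_equal(res$statistic, unname(ct$statistic), tolerance = 1e-10)
    expect_equal(res$p_two_sided, ct$p.value, tolerance = 1e-10)
  }
  expect_equal(pearson_change_correlation(1:5, 1:5 * 2)$r, 1)
  # the published r = .359 at n = 35 corresponds to p = .034
  r <- 0.359; n <- 35
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(round(2 * pt(-abs(t), n - 2), 3), 0.034)
  expect_error(pearson_change_correlation(rep(1, 5), rnorm(5)), "constant")
})

test_that("Fisher r-to-z comparison is antisymmetric and reproduces print", {
  fz <- fisher_z_compare(0.359, 35, -0.286, 35)
  expect_equal(round(fz$z, 3), 2.680)
  expect_equal(round(fz$p_one_sided, 3), 0.004)
  sw <- fisher_z_compare(-0.286, 35, 0.359, 35)
  expect_equal(sw$z, -fz$z, tolerance = 1e-12)
  expect_identical(fisher_z_compare(0.4, 20, 0.4, 20)$z, 0)
  expect_error(fisher_z_compare(1, 10, 0, 10), "< 1")
})

test_that("BH adjustment matches brute force, p.adjust and is stable", {
  expect_identical(benjamini_hochberg(0.03)$adjusted, 0.03)
  expect_equal(benjamini_hochberg(rep(0.2, 5))$adjusted, rep(0.2, 5))
  set.seed(26)
  for (i in 1:10) {
    p <- runif(8)
    res <- benjamini_hochberg(p)
    expect_equal(res$adjusted, oracle_bh(p), tolerance = 1e-12)
    expect_equal(res$adjusted, p.adjust(p, "BH"), tolerance = 1e-12)
    perm <- sample(8)
    expect_equal(benjamini_hochberg(p[perm])$adjusted, res$adjusted[perm])
    # BH rejects a superset of Bonferroni at the same level
    expect_true(all(res$rejected[p.adjust(p, "bonferroni") <= 0.05]))
    # adjusted p monotone with raw p
    expect_true(all(diff(res$adjusted[order(p)]) >= -1e-12))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("2x2 chi-square matches the observed-vs-expected oracle", {
  expect_equal(round(chi_square_2x2(14, 21, 17, 18)$statistic, 3), 0.521)
  expect_identical(chi_square_2x2(10, 20, 5, 10)$statistic, 0)
  set.seed(27)
  for (i in 1:5) {
    tb <- matrix(rpois(4, 20) + 1, 2)
    res <- chi_square_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    exp_tab <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    expect_equal(res$statistic, sum((tb - exp_tab)^2 / exp_tab),
                 tolerance = 1e-10)
    ct <- chisq.test(tb, correct = FALSE)
    expect_equal(res$statistic, unname(ct$statistic), tolerance = 1e-10)
  }
  expect_error(chi_square_2x2(0, 0, 3, 4), "margin")
})

test_that("noncentral-t sample size solver matches its definition", {
  expect_identical(power_paired_n(0.5, 0.05, 0.80), 34L)
  # boundary: huge effects need only the minimum n
  expect_identical(power_paired_n(50, 0.05, 0.80), 2L)
  # independent check against stats::power.t.test (one-sample = paired)
  for (d in c(0.3, 0.5, 0.8)) {
    n <- power_paired_n(d, 0.05, 0.80)
    n_ref <- ceiling(power.t.test(delta = d, sd = 1, power = 0.80,
                                  type = "one.sample")$n)
    expect_identical(n, as.integer(n_ref))
    # achieved power brackets the target
    expect_gte(power.t.test(n = n, delta = d, sd = 1,
                            type = "one.sample")$power, 0.80)
    expect_lt(power.t.test(n = n - 1, delta = d, sd = 1,
                           type = "one.sample")$power, 0.80)
  }
  # power is nondecreasing in n (exhaustive sweep at d = .3)
  pw <- vapply(2:200, function(n) bhqpipe:::paired_t_power(n, 0.3, 0.05),
               numeric(1))
  expect_true(all(diff(pw) > -1e-12))
  expect_error(power_paired_n(0), "nonzero")
})

test_that("trail-making difference score is linear and validated", {
  expect_identical(tmt_b_minus_a(30, 30), 0)
  b <- c(50, 60, 45); a <- c(20, 25, 22)
  expect_equal(mean(tmt_b_minus_a(b, a)), mean(b) - mean(a))
  # published baseline means are consistent within rounding
  expect_lt(abs((51.867 - 22.640) - 31.641), 5)
  expect_error(tmt_b_minus_a(-1, 5), "positive")
})
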