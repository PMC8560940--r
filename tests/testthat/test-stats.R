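test_that("descriptive summaries match a sort-and-interpolate oracle", {
  x <- c(5, 1, 7, 3, 8, 2, 6, 4)  # {1..8} shuffled
  tab <- data.frame(group = "Low", sex = rep(c("male", "female"), 4),
                    ff_pct = x)
  d <- descriptive_table(tab)
  all_row <- d[d$gender == "All" & d$stratum == "Low", ]
  expect_equal(all_row$median, 4.5)
  s <- sort(x)
  # type-7 quartiles by hand: h = (n-1)p + 1
  q1 <- s[2] + 0.75 * (s[3] - s[2])
  q3 <- s[6] + 0.25 * (s[7] - s[6])
  expect_equal(all_row$q1, q1)
  expect_equal(all_row$q3, q3)
  expect_equal(all_row$iqr, q3 - q1)
  expect_equal(all_row$mean, mean(x))

  # constant vector degenerates cleanly
  tabc <- data.frame(group = "Mid", sex = rep(c("male", "female"), 3),
                     ff_pct = rep(7, 6))
  dc <- descriptive_table(tabc)
  expect_true(all(dc$mean == 7 & dc$median == 7 & dc$sd == 0 & dc$iqr == 0))

  # Tukey hinges rule is selectable and matches fivenum
  dh <- descriptive_table(tab, quantile_rule = "hinges")
  fn <- fivenum(x)
  expect_equal(dh[dh$gender == "All", "q1"], fn[2])
  expect_equal(dh[dh$gender == "All", "q3"], fn[4])

  expect_error(descriptive_table(data.frame(group = "Low", sex = "male",
                                            ff_pct = 1)),
               "empty stratum")
})

test_that("descriptives recover the generating distribution of a synthetic cohort", {
  # patients-like draws: mean 27.7, sd 7.7
  spec <- cohort_spec(model = "draws", seed = 202)
  sim <- generate_cohort_table(spec)
  subj <- subject_level(sim$table)
  d <- descriptive_table(subj)
  pain_all <- d[d$stratum == "Pain" & d$gender == "All", ]
  expect_equal(pain_all$mean, 27.7, tolerance = 3 * 7.7 / sqrt(19))
  expect_equal(pain_all$n, 19)
  # lognormal draws: median below mean (right skew)
  expect_lt(pain_all$median, pain_all$mean + 2)
  # pooled healthy row present with n = 51
  expect_equal(d[d$stratum == "All HS" & d$gender == "All", "n"], 51)
})

test_that("Shapiro-Wilk gate detects skew and enforces n limits", {
  set.seed(3)
  skewed <- exp(rnorm(50, 0, 1))
  rej <- vapply(1:50, function(i) {
    normality_gate(exp(rnorm(50)))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.5)  # power against lognormal far above alpha
  r <- normality_gate(skewed)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  expect_error(normality_gate(c(1, 2)), "3 <= n")
})

test_that("Kruskal-Wallis matches base R on large samples and enumeration when exact", {
  set.seed(21)
  groups <- split(rlnorm(70, 2.8, 0.35), rep(1:4, c(19, 13, 18, 20)))
  mine <- kruskal_wallis(groups, exact = "never")
  ref <- stats::kruskal.test(unlist(groups), factor(rep(1:4, c(19, 13, 18, 20))))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)

  # with ties
  gt <- list(c(1, 2, 2, 3), c(2, 3, 3, 4), c(4, 4, 5, 5))
  mt <- kruskal_wallis(gt, exact = "never")
  rt <- stats::kruskal.test(unlist(gt), factor(rep(1:3, each = 4)))
  expect_equal(mt$statistic, unname(rt$statistic), tolerance = 1e-12)

  # spec-style separation: {1,2,3} {4,5,6} {7,8,9}
  gsep <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  ex <- kruskal_wallis(gsep, exact = "always")
  expect_equal(ex$statistic,
               unname(stats::kruskal.test(unlist(gsep),
                                          factor(rep(1:3, each = 3)))$statistic),
               tolerance = 1e-12)
  expect_equal(ex$p_value, kw_exact_oracle(gsep), tolerance = 1e-12)
  # chi-square p approximates the exact p for this configuration
  approx_p <- kruskal_wallis(gsep, exact = "never")$p_value
  expect_lt(abs(ex$p_value - approx_p), 0.03)

  # extreme separation at larger n
  far <- list(rnorm(15), rnorm(15) + 50, rnorm(15) + 100)
  expect_lt(kruskal_wallis(far, exact = "never")$p_value, 1e-4)

  # identical observations: H = 0, p = 1, flagged
  same <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_match(same$note, "identical")

  expect_error(kruskal_wallis(list(c(1, 2))), "2")
  expect_error(kruskal_wallis(list(1, 2)), "n must be >= 3")
})

test_that("rank-based Tukey HSD returns all pairs and behaves under the null", {
  g4 <- split(rnorm(40), rep(1:4, each = 10))
  ph <- posthoc_pairwise(g4)
  expect_equal(nrow(ph), 6L)
  expect_true(all(ph$p_adj >= 0 & ph$p_adj <= 1))

  # one shifted group: the 3 pairs involving it dominate the signal
  set.seed(33)
  gs <- list(A = rnorm(15), B = rnorm(15), C = rnorm(15), D = rnorm(15) + 4)
  ph2 <- posthoc_pairwise(gs)
  with_d <- grepl("D", ph2$pair)
  expect_true(all(ph2$p_adj[with_d] < 0.01))
  expect_true(all(ph2$p_adj[!with_d] > 0.05))

  raw <- posthoc_pairwise(gs, scale = "raw")
  expect_equal(nrow(raw), 6L)
  expect_error(posthoc_pairwise(list(rnorm(5))), "2 groups")
})

test_that("Wilcoxon signed-rank matches base R and the sign-pattern oracle", {
  # spec example: differences {1,-2,3,-4,5}
  d <- c(1, -2, 3, -4, 5)
  r <- wilcoxon_paired(d, rep(0, 5))
  expect_equal(r$p_value, wilcoxon_exact_oracle(d), tolerance = 1e-12)
  ref <- stats::wilcox.test(d, exact = TRUE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)

  # ties in |d|: our generating-function p stays exact
  dt <- c(2, -2, 3, 3, -1, 4)
  rt <- wilcoxon_paired(dt, rep(0, 6))
  expect_equal(rt$p_value, wilcoxon_exact_oracle(dt), tolerance = 1e-12)

  # degenerate: identical sides
  same <- wilcoxon_paired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_match(same$note, "zero")

  # zeros dropped under the Wilcoxon rule
  dz <- c(0, 1, -2, 3, 0, 5)
  rz <- wilcoxon_paired(dz, rep(0, 6))
  expect_equal(rz$n, 4L)
  expect_equal(rz$p_value, wilcoxon_exact_oracle(dz), tolerance = 1e-12)

  # large-sample normal approximation tracks base R closely
  set.seed(8)
  l <- rnorm(60); rr <- rnorm(60)
  mine <- wilcoxon_paired(l, rr)
  base_r <- stats::wilcox.test(l, rr, paired = TRUE, exact = FALSE,
                               correct = TRUE)
  expect_equal(mine$statistic, unname(base_r$statistic))
  expect_equal(mine$p_value, base_r$p.value, tolerance = 1e-10)

  # injected left-right offset is recovered as the median difference
  set.seed(44)
  right <- rnorm(51, 15, 4)
  left <- right + 3.3 + rnorm(51, 0, 1.5)
  res <- wilcoxon_paired(left, right)
  expect_equal(unname(res$effect["median_difference"]), 3.3, tolerance = 1)
  expect_lt(res$p_value, 0.001)

  expect_error(wilcoxon_paired(1:3, 1:2), "length")
})

test_that("outlier rule flags strictly above Q3 + 1.5 IQR", {
  v <- c(10, 12, 14, 16, 18, 20)
  fl <- outlier_flags(v)
  s <- sort(v)
  q1 <- s[2] + 0.25 * (s[3] - s[2])
  q3 <- s[4] + 0.75 * (s[5] - s[4])
  expect_equal(fl$threshold, q3 + 1.5 * (q3 - q1))
  expect_false(any(fl$flags))

  const <- outlier_flags(rep(5, 6))
  expect_equal(const$threshold, 5)
  expect_false(any(const$flags))

  # value exactly at the threshold is NOT flagged ("higher than"): for a
  # constant vector the threshold equals the data, and nothing is flagged
  expect_true(outlier_flags(c(1, 2, 3, 4, 100))$flags[5])
  expect_error(outlier_flags(c(1, 2, 3)), "n >= 4")
})

test_that("two-group sample size matches the closed form", {
  # delta 3, sd 4, power .8, two-sided alpha .05
  z <- qnorm(0.975) + qnorm(0.8)
  expect_equal(sample_size_two_group(3, 4, 0.8, 0.05, 2),
               as.integer(ceiling(2 * (z * 4 / 3)^2)))
  expect_equal(sample_size_two_group(3, 4, 0.8, 0.05, 2), 28L)
  # t-based refinement needs at least as many subjects
  expect_gte(sample_size_two_group(3, 4, 0.8, method = "t"), 28L)
  # limits
  expect_equal(sample_size_two_group(1000, 1, 0.8), 2L)
  expect_equal(sample_size_two_group(3, 4, power = 0.051, alpha = 0.05), 2L)
  expect_error(sample_size_two_group(-1, 4), "positive")
  expect_error(sample_size_two_group(3, 4, power = 1.2), "power")
})

test_that("R-squared-change power follows the noncentral F and its limits", {
  # null effect: power equals alpha
  expect_equal(power_delta_r2(0, 0.5, 140, 3, 7), 0.05, tolerance = 1e-10)
  expect_equal(power_delta_r2(0, 0.5, 140, 3, 7, alpha = 0.10), 0.10,
               tolerance = 1e-10)
  # monotone in n and in delta_r2
  ns <- c(30, 60, 120, 240)
  pw_n <- vapply(ns, function(n) power_delta_r2(0.08, 0.6, n, 3, 7), numeric(1))
  expect_true(all(diff(pw_n) > 0))
  drs <- c(0.02, 0.05, 0.1, 0.2)
  pw_d <- vapply(drs, function(d) power_delta_r2(d, 0.6, 70, 3, 7), numeric(1))
  expect_true(all(diff(pw_d) > 0))
  expect_error(power_delta_r2(0.1, 0.5, 5, 3, 7), "degrees of freedom")

  # Monte-Carlo cross-check of the partial-F power at one parameter point
  set.seed(71)
  n <- 70; dr2 <- 0.085; r2_full <- 0.614
  pow <- power_delta_r2(dr2, r2_full, n, 3, 7)
  f2 <- dr2 / (1 - r2_full)
  reps <- 2000
  # fixed design with orthonormal predictors (scaled sqrt(n), orthogonal to
  # the intercept) so the noncentrality is exactly f2 * n
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 8), n, 8))))[, 2:8]
  X <- Q * sqrt(n)
  beta <- c(rep(0, 4), rep(sqrt(f2 / 3), 3))
  mu <- X %*% beta
  hits <- vapply(seq_len(reps), function(i) {
    y <- mu + rnorm(n)
    full <- lm(y ~ X)
    red <- lm(y ~ X[, 1:4])
    anova(red, full)$`Pr(>F)`[2] < 0.05
  }, logical(1))
  mc_se <- sqrt(pow * (1 - pow) / reps)
  expect_lt(abs(mean(hits) - pow), 3 * mc_se)
})
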