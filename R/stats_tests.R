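ff_test_result <- function(test, statistic, p_value, n, effect = NULL,
                           note = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 n = n, effect = effect, note = note),
            class = "ff_test")
}

#' @export
print.ff_test <- function(x, ...) {
  cat(x$test, "- statistic", format(x$statistic, digits = 4),
      ", p =", format.pval(x$p_value, digits = 3), "\n")
  if (!is.null(x$effect)) {
    cat("  effect:", paste(names(x$effect), format(x$effect, digits = 3),
                           collapse = ", "), "\n")
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

quantile_q13 <- function(x, rule = c("linear", "hinges")) {
  rule <- match.arg(rule)
  if (rule == "linear") {
    unname(stats::quantile(x, c(0.25, 0.75), type = 7))
  } else {
    fn <- stats::fivenum(x)
    c(fn[2], fn[4])
  }
}

#' Descriptive summaries stratified by group and sex
#'
#' Produces the mean +/- SD and median (IQR) layout of the study's
#' descriptive table: per stratum, rows for Male, Female and All, plus a
#' pooled row over the healthy-subject strata when the stratification is
#' the activity group.
#'
#' @param table side- or subject-level data.frame.
#' @param value column to summarize (default `"ff_pct"`).
#' @param strata stratification column (default `"group"`).
#' @param quantile_rule `"linear"` (interpolated quartiles, default) or
#'   `"hinges"` (Tukey hinges).
#' @return data.frame with columns stratum, gender, n, mean, sd, median,
#'   q1, q3, iqr.
#' @export
descriptive_table <- function(table, value = "ff_pct", strata = "group",
                              quantile_rule = c("linear", "hinges")) {
  quantile_rule <- match.arg(quantile_rule)
  stopifnot(value %in% names(table), strata %in% names(table))
  one <- function(x, stratum, gender) {
    if (!length(x)) stop("empty stratum: ", stratum, " / ", gender)
    q <- quantile_q13(x, quantile_rule)
    data.frame(stratum = stratum, gender = gender, n = length(x),
               mean = mean(x), sd = stats::sd(x), median = stats::median(x),
               q1 = q[1], q3 = q[2], iqr = q[2] - q[1],
               stringsAsFactors = FALSE)
  }
  strata_levels <- unique(as.character(table[[strata]]))
  blocks <- list()
  for (s in strata_levels) {
    sub <- table[table[[strata]] == s, ]
    blocks[[length(blocks) + 1L]] <- do.call(rbind, list(
      one(sub[[value]][sub$sex == "male"], s, "Male"),
      one(sub[[value]][sub$sex == "female"], s, "Female"),
      one(sub[[value]], s, "All")))
  }
  hs <- intersect(c("Low", "Mid", "High"), strata_levels)
  if (strata == "group" && length(hs) > 1L) {
    sub <- table[table$group %in% hs, ]
    blocks[[length(blocks) + 1L]] <- do.call(rbind, list(
      one(sub[[value]][sub$sex == "male"], "All HS", "Male"),
      one(sub[[value]][sub$sex == "female"], "All HS", "Female"),
      one(sub[[value]], "All HS", "All")))
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Shapiro-Wilk normality gate
#'
#' Tests within-group normality; a rejection motivates emphasizing the
#' nonparametric summaries and tests (both are always computed).
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return `ff_test` with the W statistic and p-value.
#' @export
normality_gate <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L || length(values) > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  }
  sw <- stats::shapiro.test(values)
  ff_test_result("Shapiro-Wilk", unname(sw$statistic), sw$p.value,
                 length(values))
}

# tie-corrected Kruskal-Wallis H for a value vector and group index vector
kw_statistic <- function(values, g) {
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n_i <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) return(0)  # all observations identical
  H / C
}

# enumerate all distinct assignments of N items to groups of sizes n_i;
# returns matrix with one assignment (group index per item) per column
enumerate_assignments <- function(n_i) {
  N <- sum(n_i)
  res <- list()
  rec <- function(remaining, gi, acc) {
    if (gi == length(n_i)) {
      acc[remaining] <- gi
      res[[length(res) + 1L]] <<- acc
      return(invisible(NULL))
    }
    picks <- if (length(remaining) == 1L) list(remaining)
             else utils::combn(remaining, n_i[gi], simplify = FALSE)
    for (p in picks) {
      acc2 <- acc
      acc2[p] <- gi
      rec(setdiff(remaining, p), gi + 1L, acc2)
    }
  }
  rec(seq_len(N), 1L, integer(N))
  do.call(cbind, res)
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H statistic with a chi-square reference distribution
#' (df = k - 1). For small samples an exact permutation p-value is
#' available by full enumeration of the distinct group assignments;
#' `exact = "auto"` switches to enumeration when the total sample size
#' is at most 9.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups,
#'   total n >= 3).
#' @param exact `"auto"`, `"never"` or `"always"`.
#' @return `ff_test` with the H statistic; `note` records which
#'   reference distribution produced the p-value.
#' @export
kruskal_wallis <- function(groups, exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  stopifnot(is.list(groups), length(groups) >= 2L)
  n_i <- lengths(groups)
  if (any(n_i < 1L)) stop("each group needs n >= 1")
  values <- unlist(groups, use.names = FALSE)
  N <- length(values)
  if (N < 3L) stop("total n must be >= 3")
  g <- rep(seq_along(groups), n_i)
  H <- kw_statistic(values, g)
  k <- length(groups)
  if (length(unique(values)) == 1L) {
    return(ff_test_result("Kruskal-Wallis", 0, 1, n_i,
                          note = "all observations identical; H = 0"))
  }
  use_exact <- exact == "always" || (exact == "auto" && N <= 9L)
  if (use_exact) {
    assignments <- enumerate_assignments(n_i)
    Hs <- apply(assignments, 2L, function(gg) kw_statistic(values, gg))
    p <- mean(Hs >= H - 1e-12)
    note <- sprintf("exact permutation p over %d assignments", ncol(assignments))
  } else {
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
    note <- "chi-square approximation"
  }
  ff_test_result("Kruskal-Wallis", H, p, n_i, note = note)
}

#' Tukey HSD pairwise comparisons after a Kruskal-Wallis test
#'
#' All k(k-1)/2 pairwise comparisons with familywise adjustment through
#' the studentized-range distribution. By default the HSD procedure is
#' applied to the rank-transformed data, consistent with the
#' nonparametric omnibus test; `scale = "raw"` applies it to the
#' original values.
#'
#' @param groups list of numeric vectors, one per (named) group.
#' @param scale `"rank"` (default) or `"raw"`.
#' @param conf_level familywise confidence level.
#' @return data.frame with one row per pair: difference (on the chosen
#'   scale), interval bounds, adjusted p.
#' @export
posthoc_pairwise <- function(groups, scale = c("rank", "raw"),
                             conf_level = 0.95) {
  scale <- match.arg(scale)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  y <- if (scale == "rank") rank(values) else values
  fit <- stats::aov(y ~ g)
  th <- stats::TukeyHSD(fit, conf.level = conf_level)$g
  data.frame(pair = rownames(th), diff = th[, "diff"], lwr = th[, "lwr"],
             upr = th[, "upr"], p_adj = th[, "p adj"], scale = scale,
             row.names = NULL, stringsAsFactors = FALSE)
}

# exact null distribution of the signed-rank sum via the generating
# function prod_i (1 + x^{2 r_i}) / 2^n (ranks doubled so midranks from
# ties become integers); returns P(V = v/2) on the doubled-support grid
signed_rank_null <- function(ranks2) {
  maxv <- sum(ranks2)
  dp <- numeric(maxv + 1L)
  dp[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dp[seq_len(maxv + 1L - r)])
    dp <- (dp + shifted) / 2
  }
  dp
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Paired left/right comparison. Zero differences are dropped before
#' ranking (Wilcoxon's treatment; `zeros = "pratt"` keeps them for
#' ranking and drops them from the statistic). The p-value is exact for
#' n <= `exact_max` after zero handling - computed from the generating
#' function of the signed-rank sum, which remains exact under ties -
#' and uses the normal approximation with continuity and tie correction
#' otherwise. The reported effect is the median paired difference.
#'
#' @param left,right equal-length numeric vectors.
#' @param zeros `"wilcoxon"` (drop zero differences) or `"pratt"`.
#' @param exact_max largest n for which the exact distribution is used.
#' @return `ff_test` with statistic `V` (sum of positive-difference
#'   ranks).
#' @export
wilcoxon_paired <- function(left, right, zeros = c("wilcoxon", "pratt"),
                            exact_max = 25L) {
  zeros <- match.arg(zeros)
  if (length(left) != length(right)) stop("paired vectors differ in length")
  d <- left - right
  d <- d[!is.na(d)]
  if (!length(d)) stop("no paired differences")
  med_d <- stats::median(d)
  nz <- d != 0
  if (!any(nz)) {
    return(ff_test_result("Wilcoxon signed-rank", 0, 1, length(d),
                          effect = c(median_difference = 0),
                          note = "all differences zero"))
  }
  if (zeros == "wilcoxon") {
    dd <- d[nz]
    r <- rank(abs(dd))
  } else {
    r_all <- rank(abs(d))
    dd <- d[nz]
    r <- r_all[nz]
  }
  n <- length(dd)
  V <- sum(r[dd > 0])
  if (n <= exact_max) {
    dp <- signed_rank_null(as.integer(round(2 * r)))
    v2 <- as.integer(round(2 * V))
    p_le <- sum(dp[seq_len(v2 + 1L)])
    p_ge <- sum(dp[(v2 + 1L):length(dp)])
    p <- min(1, 2 * min(p_le, p_ge))
    note <- "exact (signed-rank generating function)"
  } else {
    mu <- sum(r) / 2
    sig2 <- sum(r^2) / 4  # equals n(n+1)(2n+1)/24 minus the tie correction
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    note <- "normal approximation with continuity correction"
  }
  ff_test_result("Wilcoxon signed-rank", V, p, n,
                 effect = c(median_difference = med_d), note = note)
}

#' Flag high outliers by the Q3 + 1.5 IQR rule
#'
#' @param values numeric vector (n >= 4).
#' @param quantile_rule quartile convention, see [descriptive_table()].
#' @return list with `threshold` and logical `flags`; values strictly
#'   above the threshold are flagged.
#' @export
outlier_flags <- function(values, quantile_rule = c("linear", "hinges")) {
  quantile_rule <- match.arg(quantile_rule)
  values <- values[!is.na(values)]
  if (length(values) < 4L) stop("outlier rule needs n >= 4")
  q <- quantile_q13(values, quantile_rule)
  threshold <- q[2] + 1.5 * (q[2] - q[1])
  list(threshold = threshold, flags = values > threshold)
}

#' Sample size for a two-group comparison of means
#'
#' Smallest n per group reaching the requested power to detect a mean
#' difference `delta` at common sd `sd`:
#' `n = 2 (z_{1-alpha/tails} + z_{power})^2 (sd / delta)^2` (normal
#' approximation), optionally refined iteratively with the noncentral-t
#' power of the two-sample t test.
#'
#' @param delta true mean difference (> 0).
#' @param sd common group standard deviation (> 0).
#' @param power target power in (0, 1).
#' @param alpha significance level.
#' @param tails 1 or 2.
#' @param method `"normal"` (closed form) or `"t"` (iterative).
#' @return integer n per group (>= 2).
#' @export
sample_size_two_group <- function(delta, sd, power = 0.8, alpha = 0.05,
                                  tails = 2, method = c("normal", "t")) {
  method <- match.arg(method)
  if (delta <= 0 || sd <= 0) stop("delta and sd must be positive")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  if (power <= alpha) return(2L)
  z <- stats::qnorm(1 - alpha / tails) + stats::qnorm(power)
  n <- 2 * (z * sd / delta)^2
  n <- max(2L, as.integer(ceiling(n - 1e-9)))
  if (method == "t") {
    pow_t <- function(n) {
      df <- 2 * n - 2
      ncp <- delta / (sd * sqrt(2 / n))
      crit <- stats::qt(1 - alpha / tails, df)
      stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
        (tails == 2) * stats::pt(-crit, df, ncp = ncp)
    }
    while (n > 2L && pow_t(n - 1L) >= power) n <- n - 1L
    while (pow_t(n) < power) {
      n <- n + 1L
      if (n > 1e7) stop("unreachable power")
    }
  }
  n
}

#' Power of a sequential R-squared-change (partial F) test
#'
#' Post-hoc power for a block of `df_tested` predictors entering a
#' linear model: effect size `f2 = delta_r2 / (1 - r2_full)`,
#' noncentrality `lambda = f2 * n`, referred to the noncentral
#' F(df_tested, n - df_model - 1) distribution.
#'
#' @param delta_r2 R-squared increment of the tested block.
#' @param r2_full R-squared of the full model.
#' @param n number of observations.
#' @param df_tested numerator df (predictors in the tested block).
#' @param df_model total predictors in the full model.
#' @param alpha significance level.
#' @return power in (0, 1).
#' @export
power_delta_r2 <- function(delta_r2, r2_full, n, df_tested, df_model,
                           alpha = 0.05) {
  if (delta_r2 < 0 || delta_r2 >= 1 || r2_full >= 1 || delta_r2 > r2_full + 1e-12) {
    stop("need 0 <= delta_r2 <= r2_full < 1")
  }
  df2 <- n - df_model - 1
  if (df_tested < 1 || df2 < 1) stop("invalid degrees of freedom")
  f2 <- delta_r2 / (1 - r2_full)
  lambda <- f2 * n
  crit <- stats::qf(1 - alpha, df_tested, df2)
  stats::pf(crit, df_tested, df2, ncp = lambda, lower.tail = FALSE)
}
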