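# small-grid phantom spec for fast tests
small_spec <- function(ff_field = list(type = "constant", p = 0.25),
                       noise = list(type = "none"), seed = 1L,
                       shape = c(24L, 24L, 16L)) {
  phantom_spec(shape = shape,
               semi_axes_mm = c(2.0, 2.0, 9.0),
               lt_slice = 2L, asis_slice = 13L,
               ff_field = ff_field, noise = noise, seed = seed)
}

# independent masked-mean oracle: explicit triple loop over voxels
loop_masked_mean <- function(ff_arr, labels, code) {
  s <- 0; n <- 0L
  d <- dim(ff_arr)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (labels[i, j, k] == code && !is.na(ff_arr[i, j, k])) {
      s <- s + ff_arr[i, j, k]
      n <- n + 1L
    }
  }
  s / n
}

# independent exact Kruskal-Wallis oracle: enumerate group assignments by
# nested index combinations and score with stats::kruskal.test
kw_exact_oracle <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  n_i <- lengths(groups)
  N <- sum(n_i)
  h_of <- function(g) {
    suppressWarnings(unname(stats::kruskal.test(values, factor(g))$statistic))
  }
  h_obs <- h_of(rep(seq_along(groups), n_i))
  hs <- c()
  recurse <- function(avail, gi, assign_vec) {
    if (gi > length(n_i)) {
      hs <<- c(hs, h_of(assign_vec))
      return(invisible(NULL))
    }
    sets <- if (length(avail) == n_i[gi]) list(avail)
            else utils::combn(avail, n_i[gi], simplify = FALSE)
    for (s in sets) {
      a <- assign_vec
      a[s] <- gi
      recurse(setdiff(avail, s), gi + 1L, a)
    }
  }
  recurse(seq_len(N), 1L, integer(N))
  mean(hs >= h_obs - 1e-12)
}

# independent exact Wilcoxon signed-rank oracle: enumerate all 2^n sign
# patterns of the ranked absolute differences
wilcoxon_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_le <- mean(vs <= v_obs + 1e-12)
  p_ge <- mean(vs >= v_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# side-level table with FF built exactly from a known linear model
exact_linear_table <- function(n_per_group = c(Pain = 6L, Low = 5L, Mid = 5L,
                                               High = 6L),
                               betas = list(b0 = -5.7, male = -3.8, bmi = 0.9,
                                            age = 0.1,
                                            group = c(Pain = 7.2, Low = 5.2,
                                                      Mid = 1.8, High = 0),
                                            side_right = -3.0),
                               seed = 42L) {
  set.seed(seed)
  subj <- do.call(rbind, lapply(names(n_per_group), function(g) {
    n <- n_per_group[[g]]
    data.frame(group = g,
               sex = sample(c("male", "female"), n, replace = TRUE),
               bmi = runif(n, 19, 32), age_years = runif(n, 20, 60),
               ohs_grade = if (g == "Pain") sample(1:4, n, replace = TRUE)
                           else 4L,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(subj)
  subj$subject_id <- sprintf("X%03d", seq_len(n))
  tab <- subj[rep(seq_len(n), each = 2L), ]
  tab$side <- rep(c("left", "right"), n)
  tab$pain_this_side <- FALSE
  right <- as.numeric(tab$side == "right")
  male <- as.numeric(tab$sex == "male")
  tab$ff_pct <- betas$b0 + betas$male * male + betas$bmi * tab$bmi +
    betas$age * tab$age_years + unname(betas$group[tab$group]) +
    betas$side_right * right
  rownames(tab) <- NULL
  tab
}
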