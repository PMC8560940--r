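hlm_blocks <- function() {
  list(
    gender = list(label = "Gender (male)", terms = "male"),
    bmi = list(label = "BMI", terms = "bmi"),
    age = list(label = "Age", terms = "age_years"),
    activity = list(label = "Activity level", terms = "activity"),
    ohs = list(label = "OHS grade", terms = "ohs_grade"),
    side = list(label = "Side (right)", terms = "side_right"),
    pain_side = list(label = "Pain side", terms = "pain_this_side")
  )
}

hlm_design <- function(table) {
  stopifnot(all(c("ff_pct", "sex", "bmi", "age_years", "group", "side") %in%
                  names(table)))
  lv <- intersect(c("High", "Pain", "Low", "Mid"), unique(as.character(table$group)))
  ohs <- if (is.null(table$ohs_grade)) rep(4, nrow(table))
         else as.numeric(table$ohs_grade)
  pain <- if (is.null(table$pain_this_side)) rep(FALSE, nrow(table))
          else table$pain_this_side
  data.frame(
    ff_pct = table$ff_pct,
    male = as.numeric(table$sex == "male"),
    bmi = table$bmi,
    age_years = table$age_years,
    activity = factor(as.character(table$group), levels = lv),
    ohs_grade = ohs,
    side_right = as.numeric(table$side == "right"),
    pain_this_side = as.numeric(isTRUE_vec(pain))
  )
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Hierarchical linear regression of fat fraction
#'
#' Fits the sequence of nested ordinary-least-squares models obtained by
#' entering predictor blocks one at a time in a fixed order - by default
#' gender, BMI, age, activity level (categorical, High-activity
#' reference), OHS grade (numeric 1-4), muscle side, pain side - with FF
#' (percentage points) as the response. Left and right side rows are
#' treated as separate observations. Each step reports the entered
#' block's coefficients, the R-squared increment, the cumulative
#' R-squared and the block F test against the previous model. A block is
#' retained when its F test is significant at `alpha` and it strictly
#' increases R-squared; the final model refits the retained blocks only.
#'
#' @param table side-level cohort data.frame (two rows per subject) with
#'   columns `ff_pct`, `sex`, `bmi`, `age_years`, `group`, `ohs_grade`,
#'   `side`, `pain_this_side`.
#' @param entry_order character vector ordering the blocks; any subset
#'   of `gender, bmi, age, activity, ohs, side, pain_side`.
#' @param alpha retention significance level.
#' @param response response column (FF percentage points).
#' @param on_collinear what to do when a block is collinear with earlier
#'   predictors: `"error"` (default) or `"skip"` (the step is flagged in
#'   the step table and its terms never enter later models).
#' @return An object of class `ff_hlm` with the step table, the
#'   per-step coefficient estimates (at entry and in the final model),
#'   the fitted `lm` objects and the retained-block final fit. Methods:
#'   `print`, `summary`, `coef`, `predict`, `residuals`.
#' @export
ff_hlm <- function(table,
                   entry_order = c("gender", "bmi", "age", "activity",
                                   "ohs", "side", "pain_side"),
                   alpha = 0.05, response = "ff_pct",
                   on_collinear = c("error", "skip")) {
  on_collinear <- match.arg(on_collinear)
  blocks <- hlm_blocks()
  entry_order <- match.arg(entry_order, names(blocks), several.ok = TRUE)
  dat <- hlm_design(table)
  dat$ff_pct <- table[[response]]
  if (anyNA(dat)) stop("missing values in regression design")

  steps <- data.frame(step = seq_along(entry_order), block = entry_order,
                      label = NA_character_, delta_r2 = NA_real_,
                      cum_r2 = NA_real_, F_stat = NA_real_, df1 = NA_integer_,
                      df2 = NA_integer_, p_value = NA_real_, retained = NA,
                      note = NA_character_)
  fits <- vector("list", length(entry_order))
  coef_entry <- vector("list", length(entry_order))
  prev_terms <- character(0)
  prev_fit <- stats::lm(stats::reformulate("1", response = "ff_pct"), data = dat)
  prev_r2 <- 0
  for (i in seq_along(entry_order)) {
    bl <- blocks[[entry_order[i]]]
    terms <- c(prev_terms, bl$terms)
    fit <- stats::lm(stats::reformulate(terms, response = "ff_pct"), data = dat)
    if (any(is.na(stats::coef(fit)))) {
      msg <- paste0("rank-deficient design: block '", entry_order[i],
                    "' is collinear with earlier predictors")
      if (on_collinear == "error") stop(msg)
      # flagged, never silently dropped: the step stays in the table with
      # an explicit note and the block's terms do not enter later models
      steps$label[i] <- bl$label
      steps$delta_r2[i] <- 0
      steps$cum_r2[i] <- prev_r2
      steps$retained[i] <- FALSE
      steps$note[i] <- "collinear with earlier predictors; not entered"
      coef_entry[[i]] <- matrix(numeric(0), 0, 4)
      fits[[i]] <- prev_fit
      next
    }
    r2 <- summary(fit)$r.squared
    an <- stats::anova(prev_fit, fit)
    Fv <- an$F[2]
    pv <- an$`Pr(>F)`[2]
    steps$label[i] <- bl$label
    steps$delta_r2[i] <- r2 - prev_r2
    steps$cum_r2[i] <- r2
    steps$F_stat[i] <- Fv
    steps$df1[i] <- an$Df[2]
    steps$df2[i] <- an$Res.Df[2]
    steps$p_value[i] <- pv
    steps$retained[i] <- !is.na(pv) && pv < alpha && (r2 - prev_r2) > 0
    sm <- summary(fit)$coefficients
    new_rows <- setdiff(rownames(sm), c("(Intercept)",
                                        if (length(prev_terms))
                                          rownames(summary(prev_fit)$coefficients)))
    coef_entry[[i]] <- sm[new_rows, , drop = FALSE]
    fits[[i]] <- fit
    prev_terms <- terms
    prev_fit <- fit
    prev_r2 <- r2
  }
  retained <- entry_order[steps$retained]
  final_terms <- unlist(lapply(blocks[retained], `[[`, "terms"))
  final_fit <- if (length(final_terms)) {
    stats::lm(stats::reformulate(final_terms, response = "ff_pct"), data = dat)
  } else prev_fit
  structure(list(steps = steps, coef_entry = coef_entry, fits = fits,
                 retained = retained, final_fit = final_fit,
                 full_fit = prev_fit, alpha = alpha,
                 entry_order = entry_order, n = nrow(dat),
                 call = match.call()),
            class = "ff_hlm")
}

#' @export
print.ff_hlm <- function(x, ...) {
  cat("Hierarchical linear regression of FF (%),", x$n, "side-level observations\n\n")
  st <- x$steps
  for (i in seq_len(nrow(st))) {
    cat(sprintf("Step %d: %-16s dR2 = %.3f (R2 = %.3f), F(%d, %d) = %.2f, p = %s%s\n",
                st$step[i], st$label[i], st$delta_r2[i], st$cum_r2[i],
                st$df1[i], st$df2[i], st$F_stat[i],
                format.pval(st$p_value[i], digits = 2),
                if (isTRUE(st$retained[i])) "  [retained]" else ""))
    ce <- x$coef_entry[[i]]
    for (r in rownames(ce)) {
      cat(sprintf("    %-18s %6.2f (p = %s)\n", r, ce[r, "Estimate"],
                  format.pval(ce[r, "Pr(>|t|)"], digits = 2)))
    }
  }
  cat("\nRetained blocks:", if (length(x$retained))
    paste(x$retained, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' @export
summary.ff_hlm <- function(object, ...) {
  structure(list(steps = object$steps,
                 final = summary(object$final_fit),
                 full = summary(object$full_fit),
                 retained = object$retained, alpha = object$alpha),
            class = "summary.ff_hlm")
}

#' @export
print.summary.ff_hlm <- function(x, ...) {
  cat("Step table:\n")
  print(x$steps[, c("step", "label", "delta_r2", "cum_r2", "p_value", "retained")],
        row.names = FALSE, digits = 3)
  cat("\nFinal model (retained blocks:",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "none",
      "):\n")
  stats::printCoefmat(x$final$coefficients, digits = 3)
  cat(sprintf("R2 = %.3f\n", x$final$r.squared))
  invisible(x)
}

#' @export
coef.ff_hlm <- function(object, model = c("final", "full"), ...) {
  model <- match.arg(model)
  stats::coef(if (model == "final") object$final_fit else object$full_fit)
}

#' @export
predict.ff_hlm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$final_fit, ...))
  stats::predict(object$final_fit, newdata = hlm_design(newdata), ...)
}

#' @export
residuals.ff_hlm <- function(object, ...) {
  stats::residuals(object$final_fit)
}

#' Collapse a side-level cohort table to one row per subject
#'
#' Averages the left and right metrics per subject (unweighted mean of
#' the two sides) and carries the subject-level covariates through;
#' this is the form the omnibus group tests and logistic models use.
#'
#' @param table side-level cohort data.frame.
#' @return data.frame with one row per subject.
#' @export
subject_level <- function(table) {
  stopifnot(all(c("subject_id", "side", "ff_pct") %in% names(table)))
  sp <- split(table, table$subject_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    num <- intersect(c("ff_pct", "volume_ml", "lean_volume_ml",
                       "norm_volume", "norm_lean_volume"), names(d))
    row <- d[1L, setdiff(names(d), c("side", "pain_this_side", num)),
             drop = FALSE]
    for (cn in num) row[[cn]] <- mean(d[[cn]])
    row
  }))
  rownames(out) <- NULL
  out[order(out$subject_id), ]
}

#' Logistic regression of activity or patient status
#'
#' Multivariable logistic model on subject-level (side-averaged) data.
#' Outcomes: `active_vs_not` codes Not Active (hip-pain and Low-activity
#' groups) as 1 against Active (Mid and High); `pain_vs_healthy` codes
#' the patient group as 1 against all healthy subjects. Default
#' predictors are gender, BMI, age, GMAX FF and normalized GMAX volume.
#' Odds ratios carry Wald 95% confidence intervals on the log-odds
#' scale.
#'
#' @param table side-level or subject-level cohort data.frame; side-level
#'   input is collapsed via [subject_level()].
#' @param outcome `"active_vs_not"` or `"pain_vs_healthy"`.
#' @param predictors subset of `gender, bmi, age, ff, norm_volume`.
#' @param conf_level confidence level of the Wald intervals.
#' @return An object of class `ff_logit` with the OR table and the
#'   underlying `glm` fit. Methods: `print`, `coef`.
#' @export
ff_logistic <- function(table,
                        outcome = c("active_vs_not", "pain_vs_healthy"),
                        predictors = c("gender", "bmi", "age", "ff",
                                       "norm_volume"),
                        conf_level = 0.95) {
  outcome <- match.arg(outcome)
  if ("side" %in% names(table) && anyDuplicated(table$subject_id)) {
    table <- subject_level(table)
  }
  pred_map <- c(gender = "male", bmi = "bmi", age = "age_years",
                ff = "ff_pct", norm_volume = "norm_volume")
  predictors <- match.arg(predictors, names(pred_map), several.ok = TRUE)
  dat <- data.frame(male = as.numeric(table$sex == "male"),
                    bmi = table$bmi, age_years = table$age_years)
  if ("ff" %in% predictors) dat$ff_pct <- table$ff_pct
  if ("norm_volume" %in% predictors) dat$norm_volume <- table$norm_volume
  dat$y <- if (outcome == "active_vs_not") {
    as.numeric(table$group %in% c("Pain", "Low"))
  } else {
    as.numeric(table$group == "Pain")
  }
  terms <- unname(pred_map[predictors])
  fit <- stats::glm(stats::reformulate(terms, response = "y"),
                    family = stats::binomial(), data = dat)
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- setdiff(rownames(sm), "(Intercept)")
  or_table <- data.frame(
    predictor = rows,
    odds_ratio = exp(sm[rows, "Estimate"]),
    ci_low = exp(sm[rows, "Estimate"] - z * sm[rows, "Std. Error"]),
    ci_high = exp(sm[rows, "Estimate"] + z * sm[rows, "Std. Error"]),
    p_value = sm[rows, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  separation <- !fit$converged || any(abs(sm[rows, "Estimate"]) > 15) ||
    all(abs(fit$fitted.values - 0.5) > 0.5 - 1e-8)
  structure(list(outcome = outcome, or_table = or_table, fit = fit,
                 n = nrow(dat), converged = fit$converged,
                 separation_suspected = separation,
                 conf_level = conf_level),
            class = "ff_logit")
}

#' @export
print.ff_logit <- function(x, ...) {
  lab <- if (x$outcome == "active_vs_not") {
    "Not active (Pain + Low) vs active (Mid + High)"
  } else "Hip pain vs healthy"
  cat("Logistic regression:", lab, "- n =", x$n, "\n")
  tb <- x$or_table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-12s OR %.2f (%.2f-%.2f), p = %s\n", tb$predictor[i],
                tb$odds_ratio[i], tb$ci_low[i], tb$ci_high[i],
                format.pval(tb$p_value[i], digits = 2)))
  }
  if (x$separation_suspected) {
    cat("  warning: possible complete separation / non-convergence\n")
  }
  invisible(x)
}

#' @export
coef.ff_logit <- function(object, ...) {
  stats::setNames(object$or_table$odds_ratio, object$or_table$predictor)
}
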