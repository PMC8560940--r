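#' Quantify one subject from imaging files
#'
#' Reads the Dixon channels, label map and landmarks, computes the FF
#' map, extracts the left and right muscle bulks and returns the
#' assembled subject record. This is the per-subject unit of the
#' pipeline; errors are re-thrown with the subject id attached.
#'
#' @param water_path,fat_path,label_path,landmarks_path input files.
#' @param metadata one-row data.frame (or list) with `subject_id`,
#'   `sex`, `age_years`, `weight_kg`, `height_cm`, `group`,
#'   `activity_hours_per_week`, `ohs_score`, `pain_side`.
#' @param in_phase_path optional in-phase NIfTI.
#' @param signal_floor FF undefined-signal threshold, see
#'   [compute_ff_map()].
#' @param code_book label code book, see [read_label_map()].
#' @return a `subject_record`.
#' @export
run_subject <- function(water_path, fat_path, label_path, landmarks_path,
                        metadata, in_phase_path = NULL, signal_floor = 0,
                        code_book = c("1" = "GMAX_left", "2" = "GMAX_right")) {
  sid <- as.character(metadata$subject_id)
  tryCatch({
    study <- read_dixon_study(water_path, fat_path, in_phase_path,
                              subject_id = sid)
    label <- read_label_map(label_path, study$geometry, code_book)
    landmarks <- read_landmarks(landmarks_path, study$geometry)
    quantify_subject(study, label, landmarks, metadata,
                     signal_floor = signal_floor)
  }, error = function(e) {
    stop("subject ", sid, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Quantify one subject from in-memory objects
#'
#' @param study a `dixon_study`.
#' @param label a `label_map` on the same grid.
#' @param landmarks a `landmark_set`.
#' @param metadata as in [run_subject()].
#' @param signal_floor see [compute_ff_map()].
#' @return a `subject_record`.
#' @export
quantify_subject <- function(study, label, landmarks, metadata,
                             signal_floor = 0) {
  ffm <- compute_ff_map(study, signal_floor = signal_floor)
  codes <- stats::setNames(as.integer(names(label$code_book)),
                           label$code_book)
  side_metrics <- lapply(c(left = "left", right = "right"), function(side) {
    bulk <- extract_bulk(label, landmarks, side)
    code <- codes[grepl(side, names(codes))][1]
    muscle_metrics(ffm, bulk, code)
  })
  patient <- identical(as.character(metadata$group), "Pain") ||
    (!is.null(metadata$ohs_score) && !is.na(metadata$ohs_score))
  summarize_subject(side_metrics$left, side_metrics$right,
                    sex = as.character(metadata$sex),
                    age_years = metadata$age_years,
                    weight_kg = metadata$weight_kg,
                    height_cm = metadata$height_cm,
                    subject_id = as.character(metadata$subject_id),
                    activity_hours_per_week =
                      if (is.null(metadata$activity_hours_per_week)) NA_real_
                      else metadata$activity_hours_per_week,
                    patient = patient,
                    ohs_score = if (is.null(metadata$ohs_score)) NA_integer_
                                else metadata$ohs_score,
                    pain_side = if (is.null(metadata$pain_side)) NA_character_
                                else as.character(metadata$pain_side))
}

#' Quantify a list of phantom bundles into a cohort table
#'
#' Runs the FF quantification over every bundle and binds the side-level
#' records. Bundle truth rows do not enter the computation; metadata
#' defaults are synthesized when no metadata table is given (the
#' statistics then exercise only the FF columns).
#'
#' @param bundles list of `phantom_bundle`s.
#' @param metadata optional data.frame keyed by `subject_id` with the
#'   [run_subject()] metadata columns.
#' @param signal_floor see [compute_ff_map()].
#' @return side-level cohort data.frame (two rows per subject).
#' @export
quantify_cohort <- function(bundles, metadata = NULL, signal_floor = 0) {
  rows <- lapply(bundles, function(b) {
    sid <- b$study$subject_id
    md <- if (!is.null(metadata)) {
      metadata[metadata$subject_id == sid, , drop = FALSE]
    } else {
      data.frame(subject_id = sid, sex = "female", age_years = 30,
                 weight_kg = 65, height_cm = 165, group = "Low",
                 activity_hours_per_week = 2, ohs_score = NA_integer_,
                 pain_side = NA_character_, stringsAsFactors = FALSE)
    }
    if (!nrow(md)) stop("no metadata for subject ", sid)
    as.data.frame(quantify_subject(b$study, b$label, b$landmarks, md,
                                   signal_floor = signal_floor))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full cohort statistical report
#'
#' Runs the study's statistical analysis over a side-level cohort table:
#' within-group normality checks, the descriptive FF table stratified by
#' group and sex, Kruskal-Wallis omnibus tests with rank-based Tukey HSD
#' post hocs on the side-averaged FF and volume metrics, paired
#' left/right Wilcoxon tests per group and pooled over healthy subjects,
#' the healthy-subject high-FF outlier threshold, the hierarchical
#' linear regression on side-level rows, and the two logistic models on
#' subject-level rows.
#'
#' @param table side-level cohort data.frame.
#' @param alpha significance level used throughout.
#' @param quantile_rule quartile convention for descriptives and the
#'   outlier rule.
#' @param seed seed recorded in the report (the analyses themselves are
#'   deterministic).
#' @return object of class `ff_report`.
#' @export
cohort_report <- function(table, alpha = 0.05,
                          quantile_rule = c("linear", "hinges"),
                          seed = NULL) {
  quantile_rule <- match.arg(quantile_rule)
  subj <- subject_level(table)
  groups_present <- unique(as.character(subj$group))
  by_group <- function(col) {
    lapply(stats::setNames(nm = groups_present),
           function(g) subj[[col]][subj$group == g])
  }

  normality <- lapply(by_group("ff_pct"), function(x) {
    if (length(x) >= 3) normality_gate(x) else NULL
  })

  omnibus <- list()
  posthoc <- list()
  if (length(groups_present) >= 2L) {
    for (metric in intersect(c("ff_pct", "norm_volume", "norm_lean_volume"),
                             names(subj))) {
      gr <- by_group(metric)
      omnibus[[metric]] <- kruskal_wallis(gr, exact = "never")
      posthoc[[metric]] <- posthoc_pairwise(gr)
    }
  } else {
    warning("only one group present; omnibus tests skipped")
  }

  side_tests <- list()
  lr <- function(rows) {
    l <- rows$ff_pct[rows$side == "left"][order(rows$subject_id[rows$side == "left"])]
    r <- rows$ff_pct[rows$side == "right"][order(rows$subject_id[rows$side == "right"])]
    wilcoxon_paired(l, r)
  }
  for (g in groups_present) {
    rows <- table[table$group == g, ]
    if (length(unique(rows$subject_id)) >= 5) side_tests[[g]] <- lr(rows)
  }
  hs_rows <- table[table$group %in% c("Low", "Mid", "High"), ]
  if (length(unique(hs_rows$subject_id)) >= 5) {
    side_tests[["All HS"]] <- lr(hs_rows)
  }
  pain_side_test <- NULL
  pr <- table[table$group == "Pain" & !is.na(table$pain_side) &
                table$pain_side %in% c("left", "right"), ]
  if (length(unique(pr$subject_id)) >= 5) {
    sp <- split(pr, pr$subject_id)
    sympt <- vapply(sp, function(d) d$ff_pct[d$side == d$pain_side[1]], numeric(1))
    asympt <- vapply(sp, function(d) d$ff_pct[d$side != d$pain_side[1]], numeric(1))
    pain_side_test <- wilcoxon_paired(sympt, asympt)
  }

  hs_subj <- subj[subj$group %in% c("Low", "Mid", "High"), ]
  outliers <- if (nrow(hs_subj) >= 4) {
    outlier_flags(hs_subj$ff_pct, quantile_rule)
  } else NULL

  hreg <- tryCatch(ff_hlm(table, alpha = alpha, on_collinear = "skip"),
                   error = function(e) e)
  logit_active <- if (all(c("Pain", "Low") %in% groups_present) ||
                      all(c("Mid", "High") %in% groups_present)) {
    tryCatch(ff_logistic(table, "active_vs_not"), error = function(e) e)
  } else NULL
  logit_pain <- if ("Pain" %in% groups_present &&
                    length(groups_present) > 1L) {
    tryCatch(ff_logistic(table, "pain_vs_healthy"), error = function(e) e)
  } else NULL

  structure(list(
    descriptives = descriptive_table(subj, "ff_pct", "group", quantile_rule),
    normality = normality, omnibus = omnibus, posthoc = posthoc,
    side_tests = side_tests, pain_side_test = pain_side_test,
    outliers = outliers, hreg = hreg,
    logistic = list(active_vs_not = logit_active,
                    pain_vs_healthy = logit_pain),
    alpha = alpha, quantile_rule = quantile_rule, seed = seed,
    n_subjects = nrow(subj), n_rows = nrow(table)),
    class = "ff_report")
}

#' @export
print.ff_report <- function(x, ...) {
  cat("==== GMAX FF cohort report -", x$n_subjects, "subjects ====\n")
  cat("alpha =", x$alpha, "; quantile rule:", x$quantile_rule,
      if (!is.null(x$seed)) paste("; seed", x$seed) else "", "\n\n")
  cat("-- Descriptives: GMAX FF (%) --\n")
  print(x$descriptives, row.names = FALSE, digits = 3)
  cat("\n-- Omnibus group comparisons (Kruskal-Wallis) --\n")
  for (m in names(x$omnibus)) {
    cat(m, ": "); print(x$omnibus[[m]])
  }
  if (length(x$posthoc)) {
    cat("\n-- Post-hoc Tukey HSD (rank scale), FF --\n")
    if (!is.null(x$posthoc$ff_pct)) {
      print(x$posthoc$ff_pct, row.names = FALSE, digits = 3)
    }
  }
  cat("\n-- Left vs right FF (Wilcoxon signed-rank) --\n")
  for (g in names(x$side_tests)) {
    cat(g, ": "); print(x$side_tests[[g]])
  }
  if (!is.null(x$pain_side_test)) {
    cat("Symptomatic vs asymptomatic side: "); print(x$pain_side_test)
  }
  if (!is.null(x$outliers)) {
    cat(sprintf("\nHS high-FF outlier threshold (Q3 + 1.5 IQR): %.1f%%; %d flagged\n",
                x$outliers$threshold, sum(x$outliers$flags)))
  }
  if (inherits(x$hreg, "ff_hlm")) {
    cat("\n-- Hierarchical linear regression --\n")
    print(x$hreg)
  }
  for (nm in names(x$logistic)) {
    if (inherits(x$logistic[[nm]], "ff_logit")) {
      cat("\n"); print(x$logistic[[nm]])
    }
  }
  invisible(x)
}

#' Write the cohort report tables to CSV
#'
#' @param report an `ff_report`.
#' @param dir output directory.
#' @return vector of paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ff_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "descriptives_ff.csv")
  utils::write.csv(report$descriptives, p, row.names = FALSE)
  paths <- c(paths, p)
  if (inherits(report$hreg, "ff_hlm")) {
    p <- file.path(dir, "hierarchical_regression.csv")
    utils::write.csv(report$hreg$steps, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in names(report$logistic)) {
    fit <- report$logistic[[nm]]
    if (inherits(fit, "ff_logit")) {
      p <- file.path(dir, paste0("logistic_", nm, ".csv"))
      utils::write.csv(fit$or_table, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if (length(report$posthoc)) {
    p <- file.path(dir, "posthoc_ff.csv")
    utils::write.csv(report$posthoc$ff_pct, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  log_p <- file.path(dir, "run_log.txt")
  writeLines(c(paste("alpha:", report$alpha),
               paste("quantile_rule:", report$quantile_rule),
               paste("seed:", if (is.null(report$seed)) "NA" else report$seed),
               paste("subjects:", report$n_subjects),
               paste("generated:", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             log_p)
  c(paths, log_p)
}

#' Simulate a full imaging cohort and optionally write it to disk
#'
#' Generates the tabular cohort, binds each subject's FF truth into a
#' Dixon phantom, and (when `out_dir` is given) writes all per-subject
#' NIfTI/JSON/CSV artifacts plus the cohort truth table and metadata.
#'
#' @param spec a [cohort_spec()].
#' @param template a [phantom_spec()] used for every subject's phantom.
#' @param out_dir optional output directory.
#' @return list with `cohort` (the `cohort_sim`), `bundles` and, when
#'   written, `paths`.
#' @export
simulate_bundles <- function(spec = cohort_spec(), template = phantom_spec(),
                             out_dir = NULL) {
  cohort <- generate_cohort_table(spec)
  bundles <- generate_imaging_cohort(cohort, template)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (b in bundles) {
      write_phantom_bundle(b, file.path(out_dir, b$study$subject_id))
    }
    truth_p <- file.path(out_dir, "cohort_truth.csv")
    utils::write.csv(cohort$table, truth_p, row.names = FALSE)
    md <- cohort$subjects
    md_p <- file.path(out_dir, "metadata.csv")
    utils::write.csv(md, md_p, row.names = FALSE)
    seeds_p <- file.path(out_dir, "seeds.txt")
    writeLines(c(paste("cohort seed:", spec$seed),
                 paste("phantom template seed:", template$seed)), seeds_p)
    paths <- c(truth = truth_p, metadata = md_p, seeds = seeds_p)
  }
  list(cohort = cohort, bundles = bundles, paths = paths)
}
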