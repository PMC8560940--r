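#' Compute the voxelwise fat-fraction map
#'
#' The fat fraction is the ratio image between the fat image and the sum
#' of the water and fat images, `FF = F / (W + F)`, computed per voxel.
#' Voxels with total signal `W + F <= signal_floor` carry no usable Dixon
#' signal (background, air); their FF is undefined and they are excluded
#' from any average, although they still count towards muscle volume.
#'
#' @param study a `dixon_study`.
#' @param signal_floor non-negative total-signal threshold below which FF
#'   is undefined; default 0 (only exactly zero-signal voxels undefined).
#' @return An object of class `ff_map` with elements `ff` (3D array in
#'   `[0, 1]`, `NA` where undefined), `undefined` (logical array) and
#'   `geometry`.
#' @export
compute_ff_map <- function(study, signal_floor = 0) {
  stopifnot(inherits(study, "dixon_study"))
  if (signal_floor < 0) stop("signal_floor must be >= 0")
  total <- study$water + study$fat
  undefined <- total <= signal_floor
  ff <- study$fat / total
  ff[undefined] <- NA_real_
  ff <- pmin(pmax(ff, 0), 1)
  dim(ff) <- dim(study$fat)
  structure(list(ff = ff, undefined = undefined, geometry = study$geometry),
            class = "ff_map")
}

#' @export
print.ff_map <- function(x, ...) {
  cat("Fat-fraction map", paste(x$geometry$shape, collapse = "x"),
      sprintf("- %d undefined voxels (%.1f%%)\n", sum(x$undefined),
              100 * mean(x$undefined)))
  invisible(x)
}

# 0-based inclusive slice range of the muscle bulk for one side
bulk_slice_range <- function(landmarks, side) {
  stopifnot(inherits(landmarks, "landmark_set"))
  side <- match.arg(side, c("left", "right"))
  ax <- si_axis(landmarks$geometry)
  pts <- landmarks[[side]]
  sort(c(pts$LT_tip[ax], pts$ASIS[ax]))
}

#' Restrict a label map to the muscle bulk
#'
#' The muscle bulk runs from the axial slice containing the tip of the
#' lesser trochanter to the slice at the level of the anterior superior
#' iliac spine, both boundary slices included. All labelled voxels on
#' slices outside that range are zeroed; nothing else changes.
#'
#' @param label a `label_map`.
#' @param landmarks a `landmark_set` on the same grid.
#' @param side `"left"` or `"right"`.
#' @return A `label_map` restricted to the bulk, with attribute
#'   `bulk_slice_range` (0-based inclusive pair). If no labelled voxel of
#'   the requested side's muscle survives, a warning flags the empty bulk.
#' @export
extract_bulk <- function(label, landmarks, side = c("left", "right")) {
  stopifnot(inherits(label, "label_map"))
  side <- match.arg(side)
  assert_same_geometry(label$geometry, landmarks$geometry,
                       "label map and landmarks")
  rng <- bulk_slice_range(landmarks, side)
  ax <- si_axis(label$geometry)
  nslice <- label$geometry$shape[ax]
  out <- label$labels
  keep <- seq(rng[1], rng[2]) + 1L  # 0-based range -> 1-based indices
  drop_idx <- setdiff(seq_len(nslice), keep)
  if (length(drop_idx)) {
    idx <- list(TRUE, TRUE, TRUE)
    idx[[ax]] <- drop_idx
    out <- do.call(`[<-`, c(list(out), idx, list(value = 0L)))
  }
  res <- label_map(out, label$geometry, label$code_book)
  attr(res, "bulk_slice_range") <- rng
  side_codes <- as.integer(names(label$code_book)[grepl(side, label$code_book)])
  if (length(side_codes) && !any(out %in% side_codes)) {
    warning("empty bulk: no ", side, " muscle voxels within slices [",
            rng[1], ", ", rng[2], "]")
  }
  res
}

# one 6-connected erosion pass per iteration; keeps voxels whose six
# face neighbours are all inside the mask
erode_mask <- function(mask, iterations = 1L) {
  d <- dim(mask)
  for (it in seq_len(iterations)) {
    padded <- array(FALSE, d + 2L)
    padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
    core <- padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
    mask <- core &
      padded[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
      padded[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
      padded[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
      padded[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
      padded[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
      padded[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  }
  mask
}

#' Per-muscle fat-fraction and volume metrics
#'
#' Averages the defined fat-fraction voxels over one muscle's labelled
#' bulk and derives volumes: `volume = voxel_count * voxel_volume / 1000`
#' (ml), `lean_volume = volume * (1 - mean_ff)`. The voxel count includes
#' undefined-FF voxels (volume is anatomical); the undefined count is
#' reported so the exclusion can be audited.
#'
#' @param ff_map an `ff_map`.
#' @param bulk_label a `label_map`, typically from [extract_bulk()].
#' @param muscle_code integer label code of the muscle.
#' @param erosion_voxels optional number of 6-connected erosion passes
#'   applied to the muscle mask before measuring, to suppress boundary
#'   cross-talk with intermuscular fat; default 0 (no erosion).
#' @return An object of class `muscle_metrics`: `muscle`, `mean_ff`
#'   (fraction), `voxel_count`, `undefined_count`, `volume_ml`,
#'   `lean_volume_ml`, `bulk_slice_range`.
#' @export
muscle_metrics <- function(ff_map, bulk_label, muscle_code,
                           erosion_voxels = 0L) {
  stopifnot(inherits(ff_map, "ff_map"), inherits(bulk_label, "label_map"))
  assert_same_geometry(ff_map$geometry, bulk_label$geometry,
                       "FF map and label map")
  muscle_code <- as.integer(muscle_code)
  if (!as.character(muscle_code) %in% names(bulk_label$code_book)) {
    stop("muscle code ", muscle_code, " not in code book")
  }
  mask <- bulk_label$labels == muscle_code
  if (erosion_voxels > 0L) mask <- erode_mask(mask, as.integer(erosion_voxels))
  n <- sum(mask)
  if (n == 0L) stop("zero labelled voxels for code ", muscle_code)
  vals <- ff_map$ff[mask]
  n_undef <- sum(is.na(vals))
  if (n_undef == n) stop("all labelled voxels have undefined FF (code ",
                         muscle_code, ")")
  mean_ff <- mean(vals, na.rm = TRUE)
  volume_ml <- n * voxel_volume_mm3(ff_map$geometry) / 1000
  structure(list(
    muscle = unname(bulk_label$code_book[[as.character(muscle_code)]]),
    mean_ff = mean_ff,
    voxel_count = n,
    undefined_count = n_undef,
    volume_ml = volume_ml,
    lean_volume_ml = volume_ml * (1 - mean_ff),
    bulk_slice_range = attr(bulk_label, "bulk_slice_range")
  ), class = "muscle_metrics")
}

#' @export
print.muscle_metrics <- function(x, ...) {
  cat(sprintf("%s: FF %.2f%%, %d voxels (%d undefined), volume %.1f ml, lean %.1f ml\n",
              x$muscle, 100 * x$mean_ff, x$voxel_count, x$undefined_count,
              x$volume_ml, x$lean_volume_ml))
  if (!is.null(x$bulk_slice_range)) {
    cat("  bulk slices:", paste(x$bulk_slice_range, collapse = "-"),
        "(0-based, inclusive)\n")
  }
  invisible(x)
}

#' Lean body mass by the Boer formula
#'
#' `male: 0.407 w + 0.267 h - 19.2`; `female: 0.252 w + 0.473 h - 48.3`
#' with weight `w` in kg and height `h` in cm, result in kg.
#'
#' @param sex `"male"` or `"female"`.
#' @param weight_kg body weight, kg (> 0).
#' @param height_cm height, cm (> 0).
#' @param coefficients optional override: list with `male` and `female`
#'   numeric triples `(weight, height, intercept)`.
#' @return lean body mass in kg.
#' @export
boer_lbm <- function(sex, weight_kg, height_cm, coefficients = NULL) {
  if (any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("weight and height must be positive")
  }
  if (!all(sex %in% c("male", "female"))) stop("unknown sex code")
  if (is.null(coefficients)) {
    coefficients <- list(male = c(0.407, 0.267, -19.2),
                         female = c(0.252, 0.473, -48.3))
  }
  co <- do.call(rbind, coefficients[sex])
  unname(co[, 1] * weight_kg + co[, 2] * height_cm + co[, 3])
}

#' Activity group from weekly exercise hours
#'
#' Healthy subjects are grouped by self-reported physical activity:
#' less than 4 h/week is Low, 4 to 8 h/week (inclusive) Mid, more than
#' 8 h/week High.
#'
#' @param hours_per_week non-negative numeric vector.
#' @return factor with levels `Low`, `Mid`, `High`.
#' @export
assign_activity_group <- function(hours_per_week) {
  if (any(hours_per_week < 0, na.rm = TRUE)) stop("negative activity hours")
  cut(hours_per_week, breaks = c(-Inf, 4, 8, Inf), labels = c("Low", "Mid", "High"),
      right = FALSE) -> g
  # boundary 8 belongs to Mid: [4, 8] is Mid, (8, Inf) High
  g[!is.na(hours_per_week) & hours_per_week == 8] <- "Mid"
  g
}

#' Oxford Hip Score grade
#'
#' Grades the 0-48 OHS total: 0-19 Severe (1), 20-29 Moderate (2),
#' 30-39 Mild (3), 40-48 Satisfactory (4).
#'
#' @param score integer vector in 0-48.
#' @return integer grade 1-4 with a `labels` attribute.
#' @export
ohs_grade <- function(score) {
  if (any(score < 0 | score > 48, na.rm = TRUE)) {
    stop("OHS score out of range 0-48")
  }
  g <- findInterval(score, c(0, 20, 30, 40))
  attr(g, "labels") <- c("Severe", "Moderate", "Mild", "Satisfactory")
  g
}

#' Assemble a per-subject record from bilateral muscle metrics
#'
#' Joins left and right metrics with anthropometrics and study metadata:
#' side-mean FF is the unweighted mean of the two sides' mean FF, and
#' volumes are normalized by Boer lean body mass (ml/kg). Healthy
#' subjects are assigned an activity group from their weekly hours;
#' patients are assigned to the `Pain` group.
#'
#' @param metrics_left,metrics_right `muscle_metrics` for each side.
#' @param sex,age_years,weight_kg,height_cm anthropometrics.
#' @param subject_id identifier.
#' @param activity_hours_per_week weekly activity (healthy subjects).
#' @param patient logical; `TRUE` places the subject in the `Pain` group.
#' @param ohs_score optional OHS total (patients).
#' @param pain_side optional `"left"`, `"right"` or `"both"`.
#' @return An object of class `subject_record`; see
#'   [as.data.frame.subject_record()] for the tabular (one row per side)
#'   form consumed by the statistics module.
#' @export
summarize_subject <- function(metrics_left, metrics_right,
                              sex, age_years, weight_kg, height_cm,
                              subject_id,
                              activity_hours_per_week = NA_real_,
                              patient = FALSE, ohs_score = NA_integer_,
                              pain_side = NA_character_) {
  stopifnot(inherits(metrics_left, "muscle_metrics"),
            inherits(metrics_right, "muscle_metrics"))
  lbm <- boer_lbm(sex, weight_kg, height_cm)
  if (lbm <= 0) stop("non-positive lean body mass")
  group <- if (patient) "Pain"
           else as.character(assign_activity_group(activity_hours_per_week))
  grade <- if (!is.na(ohs_score)) as.integer(ohs_grade(ohs_score))
           else if (!patient) 4L else NA_integer_
  structure(list(
    subject_id = as.character(subject_id),
    left = metrics_left, right = metrics_right,
    sex = sex, age_years = age_years,
    weight_kg = weight_kg, height_cm = height_cm,
    bmi = weight_kg / (height_cm / 100)^2,
    lbm_kg = lbm,
    group = group,
    activity_hours_per_week = activity_hours_per_week,
    ohs_grade = grade,
    pain_side = pain_side,
    side_mean_ff = (metrics_left$mean_ff + metrics_right$mean_ff) / 2
  ), class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("Subject %s (%s, %g y, BMI %.1f, LBM %.1f kg, group %s)\n",
              x$subject_id, x$sex, x$age_years, x$bmi, x$lbm_kg, x$group))
  cat(sprintf("  side-mean FF %.2f%%\n", 100 * x$side_mean_ff))
  print(x$left); print(x$right)
  invisible(x)
}

#' Tabulate a subject record as side-level rows
#'
#' @param x a `subject_record`.
#' @param ... unused.
#' @return data.frame with one row per side and the CohortTable schema:
#'   FF in percent, volumes in ml, normalized volumes in ml/kg.
#' @export
as.data.frame.subject_record <- function(x, ...) {
  side_row <- function(side) {
    m <- x[[side]]
    data.frame(
      subject_id = x$subject_id, side = side, group = x$group,
      sex = x$sex, age_years = x$age_years, bmi = x$bmi,
      lbm_kg = x$lbm_kg,
      activity_hours_per_week = x$activity_hours_per_week,
      ohs_grade = x$ohs_grade,
      pain_side = if (is.null(x$pain_side)) NA_character_ else x$pain_side,
      pain_this_side = !is.na(x$pain_side) && x$pain_side %in% c(side, "both"),
      ff_pct = 100 * m$mean_ff,
      voxel_count = m$voxel_count,
      undefined_count = m$undefined_count,
      volume_ml = m$volume_ml,
      lean_volume_ml = m$lean_volume_ml,
      norm_volume = m$volume_ml / x$lbm_kg,
      norm_lean_volume = m$lean_volume_ml / x$lbm_kg,
      stringsAsFactors = FALSE
    )
  }
  rbind(side_row("left"), side_row("right"))
}
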