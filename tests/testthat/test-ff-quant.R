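make_study <- function(water, fat, vox = c(1, 1, 1)) {
  g <- image_geometry(dim(water), voxel_size_mm = vox)
  dixon_study("t", water, fat, geometry = g)
}

test_that("fat fraction is F/(W+F) with undefined voxels excluded from means", {
  w <- array(0, c(2, 2, 2)); f <- array(0, c(2, 2, 2))
  w[1, 1, 1] <- 80; f[1, 1, 1] <- 20   # ff 0.20
  w[2, 1, 1] <- 50; f[2, 1, 1] <- 0    # ff 0
  w[1, 2, 1] <- 30; f[1, 2, 1] <- 30   # ff 0.5
  # remaining voxels W = F = 0 -> undefined
  ffm <- compute_ff_map(make_study(w, f))
  expect_equal(ffm$ff[1, 1, 1], 0.20)
  expect_equal(ffm$ff[2, 1, 1], 0)
  expect_equal(ffm$ff[1, 2, 1], 0.5)
  expect_true(is.na(ffm$ff[2, 2, 2]))
  expect_equal(sum(ffm$undefined), 5)
  expect_true(all(ffm$ff[!ffm$undefined] >= 0 & ffm$ff[!ffm$undefined] <= 1))

  # signal floor widens the undefined set
  ffm2 <- compute_ff_map(make_study(w, f), signal_floor = 55)
  expect_true(is.na(ffm2$ff[2, 1, 1]))
  expect_false(is.na(ffm2$ff[1, 1, 1]))
  expect_error(compute_ff_map(make_study(w, f), signal_floor = -1), ">= 0")
})

test_that("bulk extraction keeps the inclusive landmark slice range only", {
  g <- image_geometry(c(8L, 8L, 40L), voxel_size_mm = c(1, 1, 1))
  labels <- array(0L, dim = g$shape)
  labels[3:4, 3:4, ] <- 1L   # muscle spanning all 40 slices
  labels[6:7, 3:4, ] <- 2L
  lab <- label_map(labels, g)
  lms <- landmark_set(list(LT_tip = c(3, 3, 5), ASIS = c(3, 3, 35)),
                      list(LT_tip = c(6, 3, 5), ASIS = c(6, 3, 35)), g)
  bulk <- extract_bulk(lab, lms, "left")
  in_slices <- apply(bulk$labels == 1L, 3, any)
  expect_equal(which(in_slices), 6:36)  # 0-based 5..35 inclusive
  expect_equal(attr(bulk, "bulk_slice_range"), c(5, 35))
  expect_equal(sum(bulk$labels == 1L), 4 * 31)

  # single-slice bulk is valid
  lms1 <- landmark_set(list(LT_tip = c(3, 3, 10), ASIS = c(3, 4, 11)),
                       list(LT_tip = c(6, 3, 10), ASIS = c(6, 4, 11)), g)
  # LT and ASIS one apart -> two slices; same-slice construction is blocked
  expect_error(landmark_set(list(LT_tip = c(3, 3, 10), ASIS = c(3, 4, 10)),
                            list(LT_tip = c(6, 3, 10), ASIS = c(6, 4, 11)), g),
               "inferior")
  bulk1 <- extract_bulk(lab, lms1, "left")
  expect_equal(sum(bulk1$labels == 1L), 4 * 2)

  # muscle entirely outside the range is flagged
  labels2 <- array(0L, dim = g$shape)
  labels2[3:4, 3:4, 1:3] <- 1L
  labels2[6:7, 3:4, 20] <- 2L
  expect_warning(extract_bulk(label_map(labels2, g), lms, "left"),
                 "empty bulk")
})

test_that("muscle metrics match hand arithmetic and the per-voxel loop oracle", {
  # constant-FF block: 1000 voxels at the protocol voxel volume
  g <- image_geometry(c(10L, 10L, 10L))
  w <- array(75, dim = g$shape); f <- array(25, dim = g$shape)
  lab <- label_map(array(1L, dim = g$shape), g,
                   code_book = c("1" = "GMAX_left"))
  ffm <- compute_ff_map(dixon_study("c", w, f, geometry = g))
  m <- muscle_metrics(ffm, lab, 1)
  expect_equal(m$mean_ff, 0.25)
  expect_equal(m$voxel_count, 1000L)
  expect_equal(m$volume_ml, 1000 * 0.47 * 0.47 * 1.95 / 1000)
  expect_equal(m$volume_ml, 0.430755, tolerance = 1e-9)
  expect_equal(m$lean_volume_ml, m$volume_ml * 0.75)

  # random field, irregular label: equals the naive triple loop
  set.seed(5)
  for (rep in 1:5) {
    d <- c(7L, 6L, 5L)
    ff_true <- array(runif(prod(d)), dim = d)
    pd <- 100
    labels <- array(sample(c(0L, 1L), prod(d), replace = TRUE, prob = c(.4, .6)),
                    dim = d)
    g2 <- image_geometry(d, voxel_size_mm = c(1, 1, 1))
    st <- dixon_study("r", pd * (1 - ff_true), pd * ff_true, geometry = g2)
    ffm2 <- compute_ff_map(st)
    lab2 <- label_map(labels, g2, code_book = c("1" = "GMAX_left"))
    m2 <- muscle_metrics(ffm2, lab2, 1)
    expect_equal(m2$mean_ff, loop_masked_mean(ffm2$ff, labels, 1L),
                 tolerance = 1e-14)
  }

  # undefined voxels counted in volume, excluded from the mean
  w3 <- array(50, c(4, 1, 1)); f3 <- array(50, c(4, 1, 1))
  w3[4, 1, 1] <- 0; f3[4, 1, 1] <- 0
  g3 <- image_geometry(c(4L, 1L, 1L), voxel_size_mm = c(1, 1, 1))
  m3 <- muscle_metrics(compute_ff_map(dixon_study("u", w3, f3, geometry = g3)),
                       label_map(array(1L, c(4, 1, 1)), g3,
                                 code_book = c("1" = "GMAX_left")), 1)
  expect_equal(m3$mean_ff, 0.5)
  expect_equal(m3$voxel_count, 4L)
  expect_equal(m3$undefined_count, 1L)
  expect_equal(m3$volume_ml, 4 / 1000)
})

test_that("optional label erosion trims the mask boundary only", {
  g <- image_geometry(c(12L, 12L, 12L), voxel_size_mm = c(1, 1, 1))
  labels <- array(0L, dim = g$shape)
  labels[2:11, 2:11, 2:11] <- 1L  # 10^3 cube
  lab <- label_map(labels, g, code_book = c("1" = "GMAX_left"))
  w <- array(80, dim = g$shape); f <- array(20, dim = g$shape)
  ffm <- compute_ff_map(dixon_study("e", w, f, geometry = g))
  m0 <- muscle_metrics(ffm, lab, 1)
  m1 <- muscle_metrics(ffm, lab, 1, erosion_voxels = 1)
  expect_equal(m0$voxel_count, 1000L)
  expect_equal(m1$voxel_count, 8L^3)  # 6-connected erosion strips each face
  expect_equal(m1$mean_ff, 0.2)       # constant field: mean unchanged
})

test_that("volume conservation and bulk-restriction equivalence hold", {
  b <- generate_phantom(small_spec(ff_field = list(type = "gradient",
                                                   p_inferior = 0.1,
                                                   p_superior = 0.3)))
  ffm <- compute_ff_map(b$study)
  bulk <- extract_bulk(b$label, b$landmarks, "left")
  m <- muscle_metrics(ffm, bulk, 1)
  fat_vol <- m$volume_ml * m$mean_ff
  expect_equal(m$lean_volume_ml + fat_vol, m$volume_ml, tolerance = 1e-12)
  expect_equal(m$lean_volume_ml, m$volume_ml * (1 - m$mean_ff),
               tolerance = 1e-12)

  # manually zeroing out-of-range slices must give the identical answer
  rng <- gmaxff:::bulk_slice_range(b$landmarks, "left")
  lab2 <- b$label$labels
  keep <- seq(rng[1], rng[2]) + 1L
  lab2[, , setdiff(seq_len(dim(lab2)[3]), keep)] <- 0L
  m2 <- muscle_metrics(ffm, label_map(lab2, b$label$geometry,
                                      b$label$code_book), 1)
  expect_identical(m$mean_ff, m2$mean_ff)
  expect_identical(m$voxel_count, m2$voxel_count)
})

test_that("pointwise increase of the true FF field never decreases mean FF", {
  set.seed(9)
  base <- small_spec(ff_field = list(type = "textured", p = 0.2,
                                     sd_texture = 0.05), seed = 3)
  b1 <- generate_phantom(base)
  m1 <- muscle_metrics(compute_ff_map(b1$study),
                       extract_bulk(b1$label, b1$landmarks, "left"), 1)
  for (bump in c(0.05, 0.1, 0.2)) {
    st <- b1$study
    tot <- st$water + st$fat
    ff <- ifelse(tot > 0, st$fat / tot, 0)
    ff2 <- pmin(ff + bump, 1)
    st2 <- dixon_study("m", tot * (1 - ff2), tot * ff2, geometry = st$geometry)
    m2 <- muscle_metrics(compute_ff_map(st2),
                         extract_bulk(b1$label, b1$landmarks, "left"), 1)
    expect_gte(m2$mean_ff, m1$mean_ff)
  }
})

test_that("Boer lean body mass matches the published formula", {
  expect_equal(boer_lbm("male", 80, 180), 61.42, tolerance = 1e-10)
  expect_equal(boer_lbm("female", 60, 165), 44.865, tolerance = 1e-10)
  expect_true(boer_lbm("male", 80, 180) < 80)
  expect_error(boer_lbm("male", 0, 180), "positive")
  expect_error(boer_lbm("other", 80, 180), "unknown sex")
  # vectorized over subjects
  expect_equal(boer_lbm(c("male", "female"), c(80, 60), c(180, 165)),
               c(61.42, 44.865), tolerance = 1e-10)
})

test_that("activity grouping and OHS grading follow the study cut-points", {
  expect_equal(as.character(assign_activity_group(c(3, 6, 9))),
               c("Low", "Mid", "High"))
  expect_equal(as.character(assign_activity_group(c(4, 8))), c("Mid", "Mid"))
  expect_equal(as.character(assign_activity_group(0)), "Low")
  expect_error(assign_activity_group(-1), "negative")

  expect_equal(as.integer(ohs_grade(c(15, 25))), c(1L, 2L))
  expect_equal(as.integer(ohs_grade(c(19, 20))), c(1L, 2L))
  expect_equal(as.integer(ohs_grade(c(30, 39, 40, 48))), c(3L, 3L, 4L, 4L))
  expect_error(ohs_grade(49), "out of range")
  expect_error(ohs_grade(-1), "out of range")
})

test_that("subject records combine sides, normalize by LBM and assign groups", {
  b <- generate_phantom(small_spec(ff_field = list(type = "constant", p = 0.3)))
  ffm <- compute_ff_map(b$study)
  ml <- muscle_metrics(ffm, extract_bulk(b$label, b$landmarks, "left"), 1)
  mr <- muscle_metrics(ffm, extract_bulk(b$label, b$landmarks, "right"), 2)
  rec <- summarize_subject(ml, mr, sex = "male", age_years = 40,
                           weight_kg = 80, height_cm = 180,
                           subject_id = "S1", activity_hours_per_week = 9)
  expect_equal(rec$side_mean_ff, 0.30, tolerance = 1e-12)
  expect_equal(rec$group, "High")
  expect_equal(rec$lbm_kg, 61.42, tolerance = 1e-10)
  df <- as.data.frame(rec)
  expect_equal(nrow(df), 2L)
  expect_equal(df$norm_volume, df$volume_ml / 61.42, tolerance = 1e-10)
  expect_equal(df$ff_pct, c(30, 30), tolerance = 1e-10)

  rec2 <- summarize_subject(ml, mr, sex = "female", age_years = 55,
                            weight_kg = 70, height_cm = 165,
                            subject_id = "S2", patient = TRUE,
                            ohs_score = 25, pain_side = "left")
  expect_equal(rec2$group, "Pain")
  expect_equal(rec2$ohs_grade, 2L)
  df2 <- as.data.frame(rec2)
  expect_equal(df2$pain_this_side, c(TRUE, FALSE))
})
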