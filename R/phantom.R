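# run code under a local RNG state: deterministic given seed, and callers'
# RNG streams are left untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic Dixon phantom
#'
#' Describes a two-channel Dixon phantom: two ellipsoidal muscles (left
#' and right) on a 3D grid, a known voxelwise fat-fraction field, bone
#' landmarks delimiting the bulk, and a channel noise model. The signal
#' model is `W = PD * (1 - ff)`, `F = PD * ff`, so the noiseless
#' fat-fraction ratio reproduces the true field exactly.
#'
#' @param shape grid shape in voxels; default 96 x 96 x 48.
#' @param voxel_size_mm voxel size; default 0.47 x 0.47 x 1.95 mm.
#' @param centers_mm list with `left`/`right` ellipsoid centres (mm,
#'   world coordinates); defaults place the muscles symmetrically.
#' @param semi_axes_mm ellipsoid semi-axes (mm), shared by both sides;
#'   the default yields roughly 1.3e4 voxels per muscle.
#' @param lt_slice,asis_slice 0-based SI slice indices of the
#'   lesser-trochanter tip and ASIS landmarks (both sides).
#' @param ff_field fat-fraction field: `list(type = "constant", p = )`,
#'   `list(type = "gradient", p_inferior = , p_superior = )` (linear in
#'   the SI slice index), or `list(type = "textured", p = , sd_texture = )`
#'   (constant plus voxelwise Gaussian texture, clipped to `[0, 1]`).
#' @param proton_density signal scale PD (arbitrary units).
#' @param noise `list(type = "none")`, `list(type = "gaussian", sd = )` or
#'   `list(type = "rician", sd = )`, applied independently per channel;
#'   `sd` is in the same units as `proton_density`.
#' @param background_fat_shell logical; add a subcutaneous-fat-like
#'   elliptical shell (FF 0.9) around the muscles.
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 48L),
                         voxel_size_mm = c(0.47, 0.47, 1.95),
                         centers_mm = NULL,
                         semi_axes_mm = c(6.8, 6.8, 32),
                         lt_slice = 6L, asis_slice = 41L,
                         ff_field = list(type = "constant", p = 0.2),
                         proton_density = 100,
                         noise = list(type = "none"),
                         background_fat_shell = FALSE,
                         seed = 1L) {
  geom <- image_geometry(shape, voxel_size_mm)
  fov <- shape * voxel_size_mm
  if (is.null(centers_mm)) {
    centers_mm <- list(left = c(0.28 * fov[1], 0.5 * fov[2], 0.5 * fov[3]),
                       right = c(0.72 * fov[1], 0.5 * fov[2], 0.5 * fov[3]))
  }
  for (side in c("left", "right")) {
    c_vox <- centers_mm[[side]] / voxel_size_mm
    ext <- semi_axes_mm / voxel_size_mm
    if (any(c_vox - ext < 0) || any(c_vox + ext > shape)) {
      stop("ellipsoid (", side, ") extends outside the grid")
    }
  }
  if (!(lt_slice >= 0 && asis_slice <= shape[3] - 1L && lt_slice < asis_slice)) {
    stop("landmark slices must satisfy 0 <= LT < ASIS <= n_slices - 1")
  }
  p_vals <- switch(ff_field$type,
    constant = ff_field$p,
    gradient = c(ff_field$p_inferior, ff_field$p_superior),
    textured = ff_field$p,
    stop("unknown ff_field type: ", ff_field$type))
  if (any(p_vals < 0) || any(p_vals > 1)) stop("true ff must lie in [0, 1]")
  if (!noise$type %in% c("none", "gaussian", "rician")) {
    stop("unknown noise type: ", noise$type)
  }
  structure(list(shape = as.integer(shape), voxel_size_mm = voxel_size_mm,
                 geometry = geom, centers_mm = centers_mm,
                 semi_axes_mm = semi_axes_mm,
                 lt_slice = as.integer(lt_slice),
                 asis_slice = as.integer(asis_slice),
                 ff_field = ff_field, proton_density = proton_density,
                 noise = noise,
                 background_fat_shell = isTRUE(background_fat_shell),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipsoid_mask <- function(shape, center_vox, semi_axes_vox) {
  i <- (seq_len(shape[1]) - 0.5 - center_vox[1]) / semi_axes_vox[1]
  j <- (seq_len(shape[2]) - 0.5 - center_vox[2]) / semi_axes_vox[2]
  k <- (seq_len(shape[3]) - 0.5 - center_vox[3]) / semi_axes_vox[3]
  d2 <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  d2 <= 1
}

true_ff_volume <- function(spec) {
  shp <- spec$shape
  ff <- array(0, dim = shp)
  fld <- spec$ff_field
  if (fld$type == "constant") {
    ff[] <- fld$p
  } else if (fld$type == "gradient") {
    sl <- (seq_len(shp[3]) - 1) / (shp[3] - 1)
    prof <- fld$p_inferior + sl * (fld$p_superior - fld$p_inferior)
    ff <- array(rep(prof, each = shp[1] * shp[2]), dim = shp)
  } else if (fld$type == "textured") {
    ff[] <- pmin(pmax(fld$p + stats::rnorm(prod(shp), 0, fld$sd_texture), 0), 1)
  }
  ff
}

add_channel_noise <- function(x, noise) {
  if (noise$type == "none") return(x)
  n <- length(x)
  if (noise$type == "gaussian") {
    x <- x + stats::rnorm(n, 0, noise$sd)
    pmax(x, 0)
  } else { # rician: magnitude of complex signal + iid Gaussian per component
    re <- x + stats::rnorm(n, 0, noise$sd)
    im <- stats::rnorm(n, 0, noise$sd)
    sqrt(re^2 + im^2)
  }
}

#' Generate a synthetic Dixon phantom with known ground truth
#'
#' Builds the two-channel study, the left/right label map and the
#' landmark set from a [phantom_spec()], and records the exact truth:
#' per muscle, the bulk-mean true fat fraction (computed by direct
#' averaging of the generated field over the label within the landmark
#' slice range - a code path independent of the quantification module),
#' the bulk voxel count and the bulk volume.
#'
#' @param spec a [phantom_spec()].
#' @param subject_id identifier for the generated study.
#' @param ff_override optional per-side list `list(left = , right = )`
#'   of constant true FF values, overriding `spec$ff_field` (used when a
#'   cohort table dictates each subject's FF).
#' @return list of class `phantom_bundle`: `study` (`dixon_study`),
#'   `label` (`label_map`), `landmarks` (`landmark_set`), `truth`
#'   (data.frame, one row per side) and `spec`.
#' @export
generate_phantom <- function(spec, subject_id = "phantom", ff_override = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    shp <- spec$shape
    geom <- spec$geometry
    masks <- lapply(spec$centers_mm, function(ctr) {
      ellipsoid_mask(shp, ctr / spec$voxel_size_mm,
                     spec$semi_axes_mm / spec$voxel_size_mm)
    })
    labels <- array(0L, dim = shp)
    labels[masks$left] <- 1L
    labels[masks$right] <- 2L

    ff_true <- true_ff_volume(spec)
    if (!is.null(ff_override)) {
      for (side in c("left", "right")) {
        if (any(ff_override[[side]] < 0) || any(ff_override[[side]] > 1)) {
          stop("true ff must lie in [0, 1]")
        }
        ff_true[masks[[side]]] <- ff_override[[side]]
      }
    }

    pd <- array(0, dim = shp)
    pd[labels > 0L] <- spec$proton_density
    if (spec$background_fat_shell) {
      shell_out <- ellipsoid_mask(shp, shp / 2, shp * c(0.48, 0.48, 10))
      shell_in <- ellipsoid_mask(shp, shp / 2, shp * c(0.42, 0.42, 10))
      shell <- shell_out & !shell_in & labels == 0L
      pd[shell] <- spec$proton_density
      ff_true[shell] <- 0.9
    }

    water <- add_channel_noise(pd * (1 - ff_true), spec$noise)
    fat <- add_channel_noise(pd * ff_true, spec$noise)

    study <- dixon_study(subject_id, water, fat, geometry = geom)
    label <- label_map(labels, geom)
    mid <- round(shp[1:2] / 2)
    lm_pts <- function(side) {
      ctr <- round(spec$centers_mm[[side]] / spec$voxel_size_mm)
      list(LT_tip = c(ctr[1], mid[2], spec$lt_slice),
           ASIS = c(ctr[1], mid[2] - 2, spec$asis_slice))
    }
    landmarks <- landmark_set(lm_pts("left"), lm_pts("right"), geom)

    # truth by direct summation over label & slice range (independent of
    # the ff_quant masking/averaging code)
    keep <- seq(spec$lt_slice, spec$asis_slice) + 1L
    in_bulk <- array(FALSE, dim = shp)
    in_bulk[, , keep] <- TRUE
    truth <- do.call(rbind, lapply(c(left = 1L, right = 2L), function(code) {
      m <- labels == code & in_bulk
      data.frame(true_mean_ff = sum(ff_true[m]) / sum(m),
                 true_voxel_count = sum(m),
                 true_volume_ml = sum(m) * voxel_volume_mm3(geom) / 1000)
    }))
    truth <- cbind(subject_id = subject_id, side = c("left", "right"), truth,
                   seed = spec$seed, row.names = NULL)

    structure(list(study = study, label = label, landmarks = landmarks,
                   truth = truth, spec = spec),
              class = "phantom_bundle")
  })
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat("Synthetic Dixon phantom", x$study$subject_id, "-",
      paste(x$spec$shape, collapse = "x"), "grid, noise:", x$spec$noise$type, "\n")
  print(x$truth[, c("side", "true_mean_ff", "true_voxel_count")], row.names = FALSE)
  invisible(x)
}

#' Write a phantom bundle to disk
#'
#' Emits the NIfTI channels, the NIfTI label map, the landmarks JSON and
#' the truth record CSV for one phantom under `dir`.
#'
#' @param bundle a `phantom_bundle`.
#' @param dir output directory.
#' @return named vector of paths.
#' @export
write_phantom_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- bundle$study$subject_id
  paths <- write_dixon_study(bundle$study, dir)
  paths[["label"]] <- file.path(dir, paste0(id, "_label.nii.gz"))
  write_label_map(bundle$label, paths[["label"]])
  paths[["landmarks"]] <- file.path(dir, paste0(id, "_landmarks.json"))
  write_landmarks(bundle$landmarks, paths[["landmarks"]])
  paths[["truth"]] <- file.path(dir, paste0(id, "_truth.csv"))
  utils::write.csv(bundle$truth, paths[["truth"]], row.names = FALSE)
  paths
}
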