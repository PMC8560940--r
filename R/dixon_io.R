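#' @importFrom RNifti readNifti writeNifti asNifti pixdim xform orientation
#' @importFrom RNifti sform<- pixdim<-
#' @importFrom jsonlite fromJSON write_json
NULL

geometry_from_nifti <- function(img, axis_roles = NULL) {
  shape <- dim(img)
  if (length(shape) != 3L) stop("expected a 3D volume, got ", length(shape), "D")
  vox <- as.numeric(pixdim(img))[1:3]
  aff <- unname(structure(xform(img), imagedim = NULL, code = NULL))
  aff <- matrix(as.numeric(aff), 4L, 4L)
  if (is.null(axis_roles)) {
    ori <- try(orientation(img), silent = TRUE)
    axis_roles <- if (!inherits(ori, "try-error")) axis_roles_from_orientation(ori)
                  else c(LR = 1L, AP = 2L, SI = 3L)
  }
  image_geometry(shape, vox, axis_roles, aff)
}

# orientation string like "RAS": i-th letter says which anatomical axis the
# i-th array axis runs along
axis_roles_from_orientation <- function(ori) {
  letters3 <- strsplit(ori, "")[[1]]
  role_of <- c(R = "LR", L = "LR", A = "AP", P = "AP", S = "SI", I = "SI")
  roles <- role_of[letters3]
  if (length(roles) != 3L || anyNA(roles) || anyDuplicated(roles)) {
    return(c(LR = 1L, AP = 2L, SI = 3L))
  }
  out <- stats::setNames(seq_len(3L), roles)
  out[c("LR", "AP", "SI")]
}

check_channel <- function(x, name) {
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite voxels in ", name, " channel")
  if (any(x < 0)) stop("negative intensities in ", name, " channel")
  invisible(TRUE)
}

#' Read a two-point Dixon study from NIfTI files
#'
#' Loads co-registered water and fat volumes (and optionally the in-phase
#' volume) and verifies that all channels live on the same grid: identical
#' shape and affines equal within `tol` mm. Geometry-inconsistent channels
#' are rejected rather than resampled.
#'
#' @param water_path,fat_path paths to NIfTI volumes (`.nii`/`.nii.gz`).
#' @param in_phase_path optional path to the in-phase volume.
#' @param subject_id subject identifier; default derived from the water
#'   filename.
#' @param axis_roles optional override of the anatomical axis mapping,
#'   see [image_geometry()]; by default it is read from the NIfTI
#'   orientation code.
#' @param tol co-registration tolerance on affine entries, in mm.
#' @return An object of class `dixon_study` with elements `subject_id`,
#'   `water`, `fat`, `in_phase` (or `NULL`) and `geometry`.
#' @export
read_dixon_study <- function(water_path, fat_path, in_phase_path = NULL,
                             subject_id = NULL, axis_roles = NULL,
                             tol = 1e-4) {
  for (p in c(water_path, fat_path, in_phase_path)) {
    if (!file.exists(p)) stop("missing file: ", p)
  }
  w <- readNifti(water_path)
  f <- readNifti(fat_path)
  gw <- geometry_from_nifti(w, axis_roles)
  gf <- geometry_from_nifti(f, axis_roles)
  assert_same_geometry(gw, gf, "water/fat channels", tol)
  ip <- NULL
  if (!is.null(in_phase_path)) {
    ip <- readNifti(in_phase_path)
    assert_same_geometry(gw, geometry_from_nifti(ip, axis_roles),
                         "water/in-phase channels", tol)
    ip <- array(as.numeric(ip), dim = gw$shape)
    check_channel(ip, "in-phase")
  }
  water <- array(as.numeric(w), dim = gw$shape)
  fat <- array(as.numeric(f), dim = gw$shape)
  check_channel(water, "water")
  check_channel(fat, "fat")
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(water_path))
  }
  dixon_study(subject_id, water, fat, in_phase = ip, geometry = gw)
}

#' Construct a Dixon study from in-memory arrays
#'
#' @param subject_id subject identifier.
#' @param water,fat 3D non-negative arrays of equal shape.
#' @param in_phase optional 3D array.
#' @param geometry an [image_geometry()] shared by all channels.
#' @return `dixon_study` object.
#' @export
dixon_study <- function(subject_id, water, fat, in_phase = NULL, geometry) {
  stopifnot(inherits(geometry, "image_geometry"))
  if (!identical(dim(water), dim(fat)) ||
      !identical(as.integer(dim(water)), geometry$shape)) {
    stop("channel shape mismatch: water ", paste(dim(water), collapse = "x"),
         ", fat ", paste(dim(fat), collapse = "x"),
         ", geometry ", paste(geometry$shape, collapse = "x"))
  }
  if (!is.null(in_phase) && !identical(dim(in_phase), dim(water))) {
    stop("channel shape mismatch: in-phase")
  }
  check_channel(water, "water"); check_channel(fat, "fat")
  structure(list(subject_id = as.character(subject_id), water = water,
                 fat = fat, in_phase = in_phase, geometry = geometry),
            class = "dixon_study")
}

#' @export
print.dixon_study <- function(x, ...) {
  cat("Dixon study", x$subject_id, "-",
      paste(x$geometry$shape, collapse = "x"),
      if (is.null(x$in_phase)) "(water, fat)" else "(water, fat, in-phase)",
      "\n")
  invisible(x)
}

#' Write a Dixon study to NIfTI files
#'
#' Inverse of [read_dixon_study()]; used by the phantom generator and in
#' round-trip tests. Voxel data are preserved bit-exactly (float64).
#'
#' @param study a `dixon_study`.
#' @param dir output directory, created if needed.
#' @param gzip write `.nii.gz` (default) or plain `.nii`.
#' @return named character vector of the paths written.
#' @export
write_dixon_study <- function(study, dir, gzip = TRUE) {
  stopifnot(inherits(study, "dixon_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  paths <- c(water = file.path(dir, paste0(study$subject_id, "_water", ext)),
             fat = file.path(dir, paste0(study$subject_id, "_fat", ext)))
  write_volume(study$water, study$geometry, paths[["water"]])
  write_volume(study$fat, study$geometry, paths[["fat"]])
  if (!is.null(study$in_phase)) {
    paths[["in_phase"]] <- file.path(dir, paste0(study$subject_id, "_inphase", ext))
    write_volume(study$in_phase, study$geometry, paths[["in_phase"]])
  }
  paths
}

write_volume <- function(arr, geometry, path, datatype = "double") {
  img <- asNifti(arr)
  # pixdim must agree with the affine scales for the header to round-trip;
  # the writer emits axis-aligned affines only (synthetic data are RAS)
  pixdim(img) <- sqrt(colSums(geometry$affine[1:3, 1:3]^2))
  sform(img) <- structure(geometry$affine, code = 2L)
  writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a 3D muscle label map
#'
#' @param path NIfTI file of integer labels (0 = background).
#' @param expected_geometry geometry of the study the labels annotate; the
#'   file is rejected on any mismatch.
#' @param code_book named character vector mapping label codes to muscle
#'   names, e.g. `c("1" = "GMAX_left", "2" = "GMAX_right")`. Any nonzero
#'   code in the file that is absent from the code book is an error.
#' @param tol geometry tolerance in mm.
#' @return An object of class `label_map`.
#' @export
read_label_map <- function(path, expected_geometry,
                           code_book = c("1" = "GMAX_left", "2" = "GMAX_right"),
                           tol = 1e-4) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- readNifti(path)
  g <- geometry_from_nifti(img, axis_roles = expected_geometry$axis_roles)
  assert_same_geometry(expected_geometry, g, "study and label map", tol)
  labels <- array(as.integer(img), dim = g$shape)
  label_map(labels, expected_geometry, code_book)
}

#' Construct a label map from an integer array
#' @param labels 3D integer array (0 = background).
#' @param geometry an [image_geometry()].
#' @param code_book named character vector, label code -> muscle name.
#' @return `label_map` object.
#' @export
label_map <- function(labels, geometry,
                      code_book = c("1" = "GMAX_left", "2" = "GMAX_right")) {
  stopifnot(inherits(geometry, "image_geometry"))
  if (!identical(as.integer(dim(labels)), geometry$shape)) {
    stop("label map shape does not match geometry")
  }
  codes <- sort(unique(as.integer(labels)))
  codes <- codes[codes != 0L]
  unknown <- setdiff(codes, as.integer(names(code_book)))
  if (length(unknown)) {
    stop("label code(s) not in code book: ", paste(unknown, collapse = ", "))
  }
  structure(list(labels = array(as.integer(labels), dim = geometry$shape),
                 geometry = geometry, code_book = code_book),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  counts <- table(factor(x$labels[x$labels != 0L],
                         levels = names(x$code_book), labels = x$code_book))
  cat("Label map", paste(x$geometry$shape, collapse = "x"), "\n")
  for (nm in names(counts)) cat(" ", nm, ":", counts[[nm]], "voxels\n")
  invisible(x)
}

#' Write a label map to NIfTI
#' @param label a `label_map`.
#' @param path output path (`.nii`/`.nii.gz`).
#' @return the path, invisibly.
#' @export
write_label_map <- function(label, path) {
  stopifnot(inherits(label, "label_map"))
  write_volume(label$labels, label$geometry, path, datatype = "int16")
}

#' Read bone landmarks delimiting the muscle bulk
#'
#' The landmark file is JSON:
#' `{"convention": "voxel" | "world_mm",
#'   "left":  {"LT_tip": [i,j,k], "ASIS": [i,j,k]},
#'   "right": {"LT_tip": [i,j,k], "ASIS": [i,j,k]}}`.
#' Voxel coordinates are 0-based indices. World-mm coordinates are mapped
#' to voxel indices through the affine and rounded to the nearest voxel.
#' For each side the lesser-trochanter tip must lie strictly inferior to
#' the ASIS along the slice axis, and all points must fall inside the grid.
#'
#' @param path JSON landmark file.
#' @param geometry the study [image_geometry()] (needed for world-mm
#'   conversion and bounds checks).
#' @return An object of class `landmark_set`: per side, 0-based voxel
#'   coordinates of `LT_tip` and `ASIS`.
#' @export
read_landmarks <- function(path, geometry) {
  if (!file.exists(path)) stop("missing file: ", path)
  raw <- fromJSON(path, simplifyVector = TRUE)
  conv <- raw$convention
  if (is.null(conv) || !conv %in% c("voxel", "world_mm")) {
    stop("landmark file must declare convention 'voxel' or 'world_mm'")
  }
  sides <- list()
  for (side in c("left", "right")) {
    s <- raw[[side]]
    if (is.null(s) || is.null(s$LT_tip) || is.null(s$ASIS)) {
      stop("missing landmark: side '", side, "' needs LT_tip and ASIS")
    }
    pts <- lapply(s[c("LT_tip", "ASIS")], function(p) {
      p <- as.numeric(p)
      if (length(p) != 3L) stop("landmark must have 3 coordinates")
      if (conv == "world_mm") p <- world_to_voxel(geometry, p)
      round(p)
    })
    sides[[side]] <- pts
  }
  landmark_set(left = sides$left, right = sides$right, geometry = geometry)
}

#' Construct a landmark set from 0-based voxel coordinates
#' @param left,right lists with numeric triples `LT_tip` and `ASIS`
#'   (0-based voxel indices).
#' @param geometry the grid the coordinates refer to.
#' @return `landmark_set` object.
#' @export
landmark_set <- function(left, right, geometry) {
  stopifnot(inherits(geometry, "image_geometry"))
  ax <- si_axis(geometry)
  for (side in c("left", "right")) {
    pts <- if (side == "left") left else right
    for (nm in c("LT_tip", "ASIS")) {
      p <- pts[[nm]]
      if (is.null(p) || length(p) != 3L) stop("missing landmark: ", nm, " (", side, ")")
      if (any(p < 0) || any(p > geometry$shape - 1L)) {
        stop(nm, " (", side, ") lies outside the image grid")
      }
    }
    if (pts$LT_tip[ax] >= pts$ASIS[ax]) {
      stop("LT must be inferior to ASIS on the SI axis (side ", side, ")")
    }
  }
  structure(list(left = left, right = right, geometry = geometry),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  ax <- si_axis(x$geometry)
  for (side in c("left", "right")) {
    cat(sprintf("%-5s LT_tip slice %d, ASIS slice %d (SI axis %d, 0-based)\n",
                side, x[[side]]$LT_tip[ax], x[[side]]$ASIS[ax], ax))
  }
  invisible(x)
}

#' Write landmarks to JSON
#' @param landmarks a `landmark_set`.
#' @param path output path.
#' @param convention `"voxel"` (0-based indices) or `"world_mm"`.
#' @return the path, invisibly.
#' @export
write_landmarks <- function(landmarks, path, convention = "voxel") {
  stopifnot(inherits(landmarks, "landmark_set"))
  convention <- match.arg(convention, c("voxel", "world_mm"))
  enc <- function(p) {
    if (convention == "world_mm") voxel_to_world(landmarks$geometry, p) else p
  }
  obj <- list(convention = convention,
              left = lapply(landmarks$left, enc),
              right = lapply(landmarks$right, enc))
  write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read the subject metadata table
#'
#' CSV with columns `subject_id, sex, age_years, weight_kg, height_cm,
#' group, activity_hours_per_week, ohs_score, pain_side`. Missing values
#' are allowed in `activity_hours_per_week`, `ohs_score` and `pain_side`.
#'
#' @param path CSV file.
#' @return data.frame with validated columns.
#' @export
read_subject_metadata <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "sex", "age_years", "weight_kg", "height_cm",
                "group", "activity_hours_per_week", "ohs_score", "pain_side")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("metadata CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(df$sex %in% c("male", "female"))) stop("sex must be 'male' or 'female'")
  if (any(df$weight_kg <= 0 | df$height_cm <= 0, na.rm = TRUE)) {
    stop("non-positive anthropometrics in metadata")
  }
  df
}
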