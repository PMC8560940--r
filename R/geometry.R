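#' Image geometry of a 3D acquisition grid
#'
#' Bundles the voxel grid shape, the physical voxel size, the mapping from
#' array axes to anatomical axes, and the voxel-to-world affine. All
#' quantification in this package is grid-based; no resampling is ever
#' performed, so every volume entering a computation must carry an
#' identical geometry.
#'
#' @param shape integer vector of length 3, voxels per array axis.
#' @param voxel_size_mm positive numeric vector of length 3 (mm). Default is
#'   the axial Dixon protocol resolution 0.47 x 0.47 x 1.95 mm.
#' @param axis_roles named integer vector mapping anatomical axes to array
#'   axes; names must be exactly `LR`, `AP`, `SI` and values a permutation
#'   of 1:3. Default: third array axis is superior-inferior (axial slices).
#' @param affine 4x4 voxel-to-world (mm) matrix; default is a scaled
#'   identity built from `voxel_size_mm` (RAS).
#' @return An object of class `image_geometry`.
#' @export
image_geometry <- function(shape,
                           voxel_size_mm = c(0.47, 0.47, 1.95),
                           axis_roles = c(LR = 1L, AP = 2L, SI = 3L),
                           affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("shape must be three positive integers")
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    stop("voxel_size_mm must be three positive reals")
  }
  if (!setequal(names(axis_roles), c("LR", "AP", "SI")) ||
      !setequal(as.integer(axis_roles), 1:3)) {
    stop("axis_roles must be a bijection of {LR, AP, SI} onto array axes 1:3")
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- unname(as.matrix(affine))
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be 4x4")
  structure(
    list(shape = shape, voxel_size_mm = voxel_size_mm,
         axis_roles = axis_roles[c("LR", "AP", "SI")],
         affine = affine),
    class = "image_geometry"
  )
}

#' Voxel volume in cubic millimetres
#' @param geometry an [image_geometry()].
#' @return product of the three voxel dimensions (mm^3).
#' @export
voxel_volume_mm3 <- function(geometry) {
  stopifnot(inherits(geometry, "image_geometry"))
  prod(geometry$voxel_size_mm)
}

#' Array axis carrying the superior-inferior (slice) direction
#' @param geometry an [image_geometry()].
#' @return integer axis index in 1:3.
#' @export
si_axis <- function(geometry) {
  stopifnot(inherits(geometry, "image_geometry"))
  unname(geometry$axis_roles[["SI"]])
}

#' @export
print.image_geometry <- function(x, ...) {
  cat("Image geometry:", paste(x$shape, collapse = " x "), "voxels,",
      paste(format(x$voxel_size_mm), collapse = " x "), "mm\n")
  cat("  voxel volume:", format(voxel_volume_mm3(x)), "mm^3; SI axis:",
      si_axis(x), "\n")
  invisible(x)
}

# geometry equality used by every reader: shape exact, voxel size and
# affine within tol mm; inconsistent inputs are rejected, never resampled
geometry_compatible <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size_mm - b$voxel_size_mm)) <= tol &&
    max(abs(a$affine - b$affine)) <= tol
}

assert_same_geometry <- function(a, b, what = "volumes", tol = 1e-4) {
  if (!identical(a$shape, b$shape)) {
    stop(sprintf("channel shape mismatch between %s: %s vs %s", what,
                 paste(a$shape, collapse = "x"),
                 paste(b$shape, collapse = "x")))
  }
  if (!geometry_compatible(a, b, tol)) {
    stop(sprintf("geometry mismatch between %s (affine/voxel size differ beyond %g)",
                 what, tol))
  }
  invisible(TRUE)
}

# world mm -> 0-based voxel index through the affine inverse
world_to_voxel <- function(geometry, xyz_mm) {
  v <- solve(geometry$affine, c(xyz_mm, 1))
  v[1:3]
}

voxel_to_world <- function(geometry, ijk) {
  w <- geometry$affine %*% c(ijk, 1)
  w[1:3]
}
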