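#' A 3D scalar volume with physical voxel spacing
#'
#' `volume3d` is the universal image carrier of the package: a 3D numeric
#' array together with per-axis voxel spacing (mm) and the world position of
#' voxel `(1,1,1)` (mm). Voxel `i` (1-based) is centered at
#' `origin + (i - 1) * spacing`.
#'
#' @param values 3D numeric, logical or integer array.
#' @param spacing Numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin Numeric length-3, world coordinate (mm) of the first voxel.
#' @return An object of class `volume3d`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
#' voxel_volume(v)  # 0.125 mm^3
#' @export
volume3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  if (is.logical(values)) storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("`values` must be finite")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$values)

#' Physical volume of one voxel in mm^3
#' @param vol A `volume3d`.
#' @return Scalar mm^3.
#' @export
voxel_volume <- function(vol) {
  stopifnot(inherits(vol, "volume3d"))
  prod(vol$spacing)
}

#' Test whether two volumes share grid shape and spacing
#' @param a,b `volume3d` objects.
#' @param tol Relative tolerance on spacing/origin.
#' @return Logical.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  inherits(a, "volume3d") && inherits(b, "volume3d") &&
    identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(1, abs(a$spacing))) &&
    all(abs(a$origin - b$origin) <= tol * pmax(1, abs(a$origin), abs(b$origin)))
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on a common grid (shape/spacing/origin differ)",
                 what))
  invisible(TRUE)
}

# Coerce a volume's values to strict 0/1 doubles.
as_binary_values <- function(vol) {
  v <- vol$values
  if (any(!(v %in% c(0, 1)))) stop("mask values must be binary (0/1)")
  v
}

#' Write a volume to a NIfTI-1 file
#'
#' Spacing is stored in `pixdim` and the diagonal affine (with the origin as
#' translation) as the sform (code 2).
#'
#' @param vol A `volume3d`.
#' @param path Output path, typically ending in `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from a NIfTI-1 file
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return A `volume3d`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img, useQuaternionFirst = FALSE)
  org <- xf[1:3, 4]
  volume3d(vals, spacing = sp, origin = org)
}

# Construct a probability map on a volume grid.
probability_map <- function(values, template, provenance = list()) {
  v <- volume3d(values, template$spacing, template$origin)
  if (min(v$values) < -1e-9 || max(v$values) > 1 + 1e-9)
    stop("probability values must lie in [0, 1]")
  v$values <- pmin(pmax(v$values, 0), 1)
  v$provenance <- provenance
  class(v) <- c("probability_map", "volume3d")
  v
}

segmentation_mask <- function(values, template) {
  v <- volume3d(values, template$spacing, template$origin)
  as_binary_values(v)
  class(v) <- c("segmentation_mask", "volume3d")
  v
}
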