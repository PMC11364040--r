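#' 3D density map volume
#'
#' A `volume_grid` bundles a 3D array of real densities with the voxel size
#' (in Angstrom, isotropic) and the map origin (Angstrom). It is the common
#' currency of every map-level operation in the package: half-maps, denoised
#' maps, masks and synthetic ground truths are all `volume_grid` objects.
#'
#' @param values 3D numeric array; every element must be finite and every
#'   axis must have at least 8 voxels.
#' @param voxel_size positive scalar, Angstrom per voxel (isotropic).
#' @param origin numeric length-3, map origin in Angstrom.
#' @return A `volume_grid` object.
#' @examples
#' v <- volume_grid(array(rnorm(8^3), c(8, 8, 8)), voxel_size = 1.1)
#' dim(v$values)
#' @export
volume_grid <- function(values, voxel_size = 1, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(dim(values) < 8L))
    stop("every axis must have at least 8 voxels; got ",
         paste(dim(values), collapse = "x"))
  if (!all(is.finite(values)))
    stop("volume contains non-finite values")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a positive scalar (Angstrom)")
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be a finite length-3 numeric")
  structure(
    list(values = values, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid %dx%dx%d, voxel %.4g A, origin (%g, %g, %g)>\n",
              d[1], d[2], d[3], x$voxel_size,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  density range [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

is_volume_grid <- function(x) inherits(x, "volume_grid")

as_volume_like <- function(values, template) {
  volume_grid(values, voxel_size = template$voxel_size,
              origin = template$origin)
}

stop_if_geometry_mismatch <- function(a, b, what = "volumes") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("%s have different shapes: %s vs %s", what,
                 paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x")))
  if (abs(a$voxel_size - b$voxel_size) > 1e-6 * a$voxel_size)
    stop(sprintf("%s have different voxel sizes: %g vs %g", what,
                 a$voxel_size, b$voxel_size))
  invisible(TRUE)
}

require_cubic <- function(shape) {
  if (length(unique(shape)) != 1L)
    stop(sprintf(
      "Fourier-shell operations require a cubic volume; got axes %s",
      paste(shape, collapse = " x ")))
  invisible(shape[1])
}

#' Apply a mask to a volume
#'
#' Voxelwise multiplication by a `[0, 1]` mask on the same grid. Mask
#' geometry must match exactly; masks are never resampled.
#'
#' @param v a [volume_grid()].
#' @param mask a [volume_grid()] with values in `[0, 1]`, or `NULL` for a
#'   no-op.
#' @return The masked `volume_grid`.
#' @export
apply_mask <- function(v, mask) {
  if (is.null(mask)) return(v)
  stop_if_geometry_mismatch(v, mask, "map and mask")
  as_volume_like(v$values * mask$values, v)
}
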