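#' 3D count-rate image volume
#'
#' Container for a reconstructed emission-tomography volume.  Voxel values
#' are count rates (counts per second per voxel); `spacing` gives the voxel
#' size along each axis in mm.  The acquisition `duration` (seconds) is
#' carried as metadata: it is only consulted where integer counts are needed
#' (Poisson uncertainty of a calibration acquisition, binomial thinning).
#'
#' Physical coordinates follow the half-voxel convention: the centre of the
#' voxel with 0-based index `(i, j, k)` sits at `(i + 0.5, j + 0.5, k + 0.5)
#' * spacing`, measured from the volume corner.
#'
#' @param voxels numeric 3D array of count rates (cps per voxel).
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param duration acquisition time in seconds (metadata; default `NA`).
#' @return An object of class `image_volume`.
#' @examples
#' img <- image_volume(array(1, c(8, 8, 8)), spacing = c(4.8, 4.8, 4.8))
#' dim(img$voxels)
#' @export
image_volume <- function(voxels, spacing, duration = NA_real_) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  storage.mode(voxels) <- "double"
  if (any(!is.finite(voxels)))
    stop("all voxel values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  structure(
    list(voxels = voxels, spacing = spacing, duration = as.numeric(duration)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  voxel volume %.4g ml, total count rate %.6g cps",
              voxel_volume_ml(x), sum(x$voxels)))
  if (is.finite(x$duration)) cat(sprintf(", duration %g s", x$duration))
  cat("\n")
  invisible(x)
}

#' Voxel volume in millilitres
#'
#' @param image an [image_volume].
#' @return The volume of one voxel in ml (1 ml = 1000 mm^3).
#' @export
voxel_volume_ml <- function(image) {
  stopifnot(inherits(image, "image_volume"))
  prod(image$spacing) / 1000
}

# physical coordinates (mm) of voxel centres along each axis
voxel_centres <- function(image) {
  d <- dim(image$voxels)
  lapply(1:3, function(ax) (seq_len(d[ax]) - 0.5) * image$spacing[ax])
}

# physical extent of the grid, per axis, in mm
grid_extent <- function(image) dim(image$voxels) * image$spacing
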