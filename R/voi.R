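#' Logical mask of voxels inside a sphere
#'
#' A voxel belongs to the sphere iff its centre lies inside (or on) the
#' sphere surface.  The same inclusion rule is used for both the summed
#' count rate and the VOI volume, so ordinate and abscissa of the
#' counts-versus-volume regression are computed over identical voxel sets
#' and discretisation bias cancels from the fit.
#'
#' @param image an [image_volume].
#' @param center sphere centre, physical mm coordinates (length 3).
#' @param radius sphere radius in mm (> 0).
#' @return Logical 3D array of the image's dimensions.
#' @export
sphere_mask <- function(image, center, radius) {
  stopifnot(inherits(image, "image_volume"))
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("'center' must be a finite length-3 coordinate in mm")
  if (!is.finite(radius) || radius <= 0) stop("'radius' must be > 0")
  cc <- voxel_centres(image)
  d2 <- outer(outer((cc[[1]] - center[1])^2, (cc[[2]] - center[2])^2, `+`),
              (cc[[3]] - center[3])^2, `+`)
  d2 <= radius^2
}

# TRUE if the sphere pokes out of the physical grid extent
sphere_truncated <- function(image, center, radius) {
  ext <- grid_extent(image)
  any(center - radius < 0) || any(center + radius > ext)
}

#' Summed count rate and volume of a spherical VOI
#'
#' Sums voxel count rates over a spherical volume of interest and reports
#' the VOI volume as (number of included voxels) x (voxel volume), i.e. the
#' discrete volume actually summed over, not the analytic sphere volume.
#'
#' @inheritParams sphere_mask
#' @return A one-row data frame with columns `volume` (ml), `count_rate`
#'   (cps), `radius` (mm) and `truncated` (logical: sphere clipped by the
#'   grid boundary).
#' @examples
#' img <- image_volume(array(1, c(16, 16, 16)), spacing = 4)
#' extract_voi_count_rate(img, center = c(32, 32, 32), radius = 12)
#' @export
extract_voi_count_rate <- function(image, center, radius) {
  m <- sphere_mask(image, center, radius)
  k <- sum(m)
  if (k == 0L) stop("empty VOI: sphere includes no voxel centres")
  trunc <- sphere_truncated(image, center, radius)
  if (trunc)
    warning("VOI sphere truncated by the image boundary")
  data.frame(volume = k * voxel_volume_ml(image),
             count_rate = sum(image$voxels[m]),
             radius = radius,
             truncated = trunc)
}

#' Count rate and volume of a mask-defined VOI
#'
#' @param image an [image_volume].
#' @param mask logical 3D array on the same grid.
#' @return One-row data frame with `volume` (ml) and `count_rate` (cps).
#' @export
extract_mask_count_rate <- function(image, mask) {
  stopifnot(inherits(image, "image_volume"))
  if (!identical(dim(mask), dim(image$voxels)))
    stop("mask dimensions do not match the image grid")
  mask <- as.logical(mask)
  k <- sum(mask)
  if (k == 0L) stop("empty VOI: mask selects no voxels")
  data.frame(volume = k * voxel_volume_ml(image),
             count_rate = sum(image$voxels[mask]))
}

#' Build a concentric oversized-VOI series
#'
#' Delineates `n_vois` concentric spherical VOIs of strictly increasing
#' radius about a single centre and tabulates (volume, count rate) pairs.
#' The innermost sphere should already be oversized, i.e. enclose all
#' counts originating from the source; the outer spheres then sample the
#' linear growth of background counts with volume.
#'
#' @param image an [image_volume].
#' @param center shared sphere centre (mm, length 3).
#' @param base_radius radius of the innermost VOI (mm).
#' @param n_vois number of VOIs (>= 3, so the intercept uncertainty with
#'   its n - 2 degrees of freedom is defined).
#' @param radius_step radius increment between successive VOIs (mm).
#' @return A data frame of class `voi_series` with one row per VOI
#'   (columns `radius`, `volume`, `count_rate`, `truncated`), ordered by
#'   increasing volume.
#' @seealso [fit_intercept()] for the counts-versus-volume regression.
#' @export
build_concentric_series <- function(image, center, base_radius, n_vois = 4L,
                                    radius_step = base_radius / 3) {
  if (!is.finite(base_radius) || base_radius <= 0) stop("'base_radius' must be > 0")
  if (!is.finite(radius_step) || radius_step <= 0) stop("'radius_step' must be > 0")
  n_vois <- as.integer(n_vois)
  if (n_vois < 3L)
    stop("'n_vois' must be >= 3 (n - 2 degrees of freedom for the intercept uncertainty)")
  radii <- base_radius + (seq_len(n_vois) - 1L) * radius_step
  rows <- lapply(radii, function(r) extract_voi_count_rate(image, center, r))
  out <- do.call(rbind, rows)
  if (any(diff(out$volume) <= 0))
    stop("VOI volumes are not strictly increasing; radius_step too small for the voxel grid")
  class(out) <- c("voi_series", "data.frame")
  attr(out, "center") <- as.numeric(center)
  out
}

#' Construct a VOI series from raw (volume, count rate) pairs
#'
#' For measurements delineated outside this package (e.g. exported from a
#' clinical workstation).
#'
#' @param volume VOI volumes in ml, strictly increasing.
#' @param count_rate VOI count rates in cps.
#' @return A `voi_series` data frame.
#' @export
voi_series <- function(volume, count_rate) {
  volume <- as.numeric(volume); count_rate <- as.numeric(count_rate)
  if (length(volume) != length(count_rate))
    stop("'volume' and 'count_rate' must have equal length")
  if (any(!is.finite(volume)) || any(volume <= 0)) stop("volumes must be positive and finite")
  if (any(!is.finite(count_rate))) stop("count rates must be finite")
  if (is.unsorted(volume, strictly = TRUE)) stop("volumes must be strictly increasing")
  structure(data.frame(radius = NA_real_, volume = volume,
                       count_rate = count_rate, truncated = FALSE),
            class = c("voi_series", "data.frame"))
}
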