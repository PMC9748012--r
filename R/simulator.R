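# run code with a locally-set RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Digital phantom specification
#'
#' Describes a synthetic activity distribution on a voxel grid together
#' with the measurement-chain parameters used to render it into a
#' count-rate image.  Geometry elements are added with [phantom_cylinder()],
#' [phantom_sphere()], [phantom_ellipsoid()] and [phantom_point()]; each
#' carries either an activity concentration (MBq/ml) or a total activity
#' (MBq).
#'
#' @param dim grid dimensions (voxels, length 3).
#' @param spacing voxel size (mm, length 3 or scalar).
#' @param elements list of geometry elements.
#' @param psf_fwhm isotropic point-spread-function FWHM in mm (> 0).
#' @param sensitivity system sensitivity in cps/MBq.
#' @param duration acquisition duration in seconds.
#' @param seed integer seed recorded in the ground-truth manifest.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(48L, 48L, 48L), spacing = 4.8,
                         elements = list(), psf_fwhm = 15,
                         sensitivity = 28.9, duration = 4320,
                         seed = NULL) {
  spacing <- if (length(spacing) == 1L) rep(spacing, 3L) else as.numeric(spacing)
  stopifnot(length(dim) == 3L, all(dim >= 1), length(spacing) == 3L,
            all(spacing > 0), psf_fwhm > 0, sensitivity > 0, duration > 0)
  structure(list(dim = as.integer(dim), spacing = spacing, elements = elements,
                 psf_fwhm = psf_fwhm, sensitivity = sensitivity,
                 duration = duration, seed = seed),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %d x %d x %d @ %.3g mm, FWHM %.3g mm, Q %.3g cps/MBq, %g s\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing[1], x$psf_fwhm,
              x$sensitivity, x$duration))
  for (e in x$elements)
    cat(sprintf("  %-10s %-9s %s\n", e$name, e$type,
                if (!is.null(e$activity)) sprintf("%.4g MBq", e$activity)
                else sprintf("%.4g MBq/ml", e$concentration)))
  invisible(x)
}

#' Phantom geometry elements
#'
#' Constructors for the geometric primitives a [phantom_spec] is composed
#' of.  Cylinders are axis-aligned along z.  Exactly one of
#' `concentration` (MBq/ml) or `activity` (total MBq, spread uniformly over
#' the element's voxels) must be given; point sources take a total
#' activity deposited in the single nearest voxel.
#'
#' @param center element centre, physical mm coordinates.
#' @param radius radius in mm.
#' @param length cylinder length along z in mm.
#' @param semi_axes ellipsoid semi-axes in mm (length 3).
#' @param concentration activity concentration in MBq/ml.
#' @param activity total activity in MBq.
#' @param name element label for the ground-truth manifest.
#' @return A phantom element (list) for [phantom_spec()]'s `elements`.
#' @name phantom_elements
NULL

#' @rdname phantom_elements
#' @export
phantom_cylinder <- function(center, radius, length, concentration = NULL,
                             activity = NULL, name = "cylinder") {
  list(type = "cylinder", center = as.numeric(center), radius = radius,
       length = length, concentration = concentration, activity = activity,
       name = name)
}

#' @rdname phantom_elements
#' @export
phantom_sphere <- function(center, radius, concentration = NULL,
                           activity = NULL, name = "sphere") {
  list(type = "sphere", center = as.numeric(center), radius = radius,
       concentration = concentration, activity = activity, name = name)
}

#' @rdname phantom_elements
#' @export
phantom_ellipsoid <- function(center, semi_axes, concentration = NULL,
                              activity = NULL, name = "ellipsoid") {
  list(type = "ellipsoid", center = as.numeric(center),
       semi_axes = as.numeric(semi_axes), concentration = concentration,
       activity = activity, name = name)
}

#' @rdname phantom_elements
#' @export
phantom_point <- function(center, activity, name = "point") {
  list(type = "point", center = as.numeric(center), activity = activity,
       name = name)
}

element_mask <- function(e, centres, dim) {
  x <- centres[[1]]; y <- centres[[2]]; z <- centres[[3]]
  switch(e$type,
    cylinder = {
      r2 <- outer((x - e$center[1])^2, (y - e$center[2])^2, `+`)
      inplane <- r2 <= e$radius^2
      inz <- abs(z - e$center[3]) <= e$length / 2
      outer(inplane, inz, `&`)
    },
    sphere = {
      d2 <- outer(outer((x - e$center[1])^2, (y - e$center[2])^2, `+`),
                  (z - e$center[3])^2, `+`)
      d2 <= e$radius^2
    },
    ellipsoid = {
      d2 <- outer(outer(((x - e$center[1]) / e$semi_axes[1])^2,
                        ((y - e$center[2]) / e$semi_axes[2])^2, `+`),
                  ((z - e$center[3]) / e$semi_axes[3])^2, `+`)
      d2 <= 1
    },
    stop("unknown element type: ", e$type)
  )
}

#' Voxelize a phantom specification into an activity map
#'
#' Deterministically paints each geometry element onto the grid.
#' Concentration elements deposit `concentration x voxel volume` MBq into
#' every included voxel; total-activity elements spread their activity
#' uniformly over the included voxels (so the voxel sum matches the
#' specified total exactly); point sources deposit everything in the
#' nearest voxel.  Overlapping elements add.
#'
#' @param spec a [phantom_spec].
#' @return Object of class `activity_map`: list with `voxels` (MBq per
#'   voxel), `spacing`, and a ground-truth `manifest` data frame (element
#'   name, type, true activity in MBq, concentration, voxel count).
#' @export
voxelize <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim
  vol_ml <- prod(spec$spacing) / 1000
  centres <- lapply(1:3, function(ax) (seq_len(d[ax]) - 0.5) * spec$spacing[ax])
  ext <- d * spec$spacing
  map <- array(0, d)
  rows <- list()
  for (e in spec$elements) {
    if (e$type == "point") {
      idx <- pmin(pmax(ceiling(e$center / spec$spacing), 1L), d)
      if (any(e$center < 0) || any(e$center > ext))
        stop("point source '", e$name, "' lies outside the grid")
      map[idx[1], idx[2], idx[3]] <- map[idx[1], idx[2], idx[3]] + e$activity
      rows[[length(rows) + 1L]] <- data.frame(
        name = e$name, type = e$type, activity_MBq = e$activity,
        concentration_MBq_ml = e$activity / vol_ml, n_voxels = 1L)
      next
    }
    m <- element_mask(e, centres, d)
    k <- sum(m)
    if (k == 0L) stop("element '", e$name, "' lies entirely outside the grid")
    clipped <- switch(e$type,
      cylinder = any(e$center[1:2] - e$radius < 0) ||
        any(e$center[1:2] + e$radius > ext[1:2]) ||
        e$center[3] - e$length / 2 < 0 || e$center[3] + e$length / 2 > ext[3],
      sphere = any(e$center - e$radius < 0) || any(e$center + e$radius > ext),
      ellipsoid = any(e$center - e$semi_axes < 0) || any(e$center + e$semi_axes > ext))
    if (isTRUE(clipped))
      warning("element '", e$name, "' is clipped by the grid boundary")
    if (!is.null(e$concentration)) {
      per_vox <- e$concentration * vol_ml
      total <- per_vox * k
      conc <- e$concentration
    } else {
      per_vox <- e$activity / k
      total <- e$activity
      conc <- per_vox / vol_ml
    }
    map[m] <- map[m] + per_vox
    rows[[length(rows) + 1L]] <- data.frame(
      name = e$name, type = e$type, activity_MBq = total,
      concentration_MBq_ml = conc, n_voxels = k)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), type = character(), activity_MBq = numeric(),
               concentration_MBq_ml = numeric(), n_voxels = integer())
  structure(list(voxels = map, spacing = spec$spacing, manifest = manifest,
                 seed = spec$seed),
            class = "activity_map")
}

#' @export
print.activity_map <- function(x, ...) {
  cat(sprintf("activity_map: %s voxels, total %.5g MBq\n",
              paste(dim(x$voxels), collapse = " x "), sum(x$voxels)))
  print(x$manifest)
  invisible(x)
}

# separable 3D Gaussian blur; kernel normalised to sum 1 so interior counts
# are conserved; mass blurred past the boundary is lost (zero padding)
gaussian_blur3d <- function(a, spacing, fwhm) {
  sd_vox <- (fwhm / (2 * sqrt(2 * log(2)))) / spacing
  for (ax in 1:3) {
    s <- sd_vox[ax]
    if (s < 1e-6) next
    n <- dim(a)[ax]
    half <- ceiling(4 * s)
    k <- stats::dnorm(-half:half, sd = s)
    k <- k / sum(k)
    K <- matrix(0, n, n)
    for (off in -half:half) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[off + half + 1]
    }
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    ap <- K %*% matrix(ap, nrow = dp[1])
    dim(ap) <- dp
    a <- aperm(ap, order(perm))
  }
  a
}

#' Expected counts per voxel for an activity map
#'
#' The noiseless measurement model: per-voxel expected counts equal
#' activity x sensitivity x duration, convolved with an isotropic 3D
#' Gaussian point-spread function.  The convolution kernel is normalised,
#' so total expected counts are conserved up to mass blurred past the grid
#' boundary (reported as a warning when it exceeds 0.5 percent).
#'
#' @param map an [voxelize()]d `activity_map`.
#' @param psf_fwhm PSF full width at half maximum, mm.
#' @param sensitivity cps/MBq.
#' @param duration seconds.
#' @return 3D array of expected counts (not yet Poisson-sampled).
#' @export
expected_counts <- function(map, psf_fwhm, sensitivity, duration) {
  stopifnot(inherits(map, "activity_map"))
  lam <- map$voxels * sensitivity * duration
  tot0 <- sum(lam)
  lam <- gaussian_blur3d(lam, map$spacing, psf_fwhm)
  if (tot0 > 0) {
    lost <- 1 - sum(lam) / tot0
    if (lost > 0.005)
      warning(sprintf("%.2f%% of expected counts blurred past the grid boundary",
                      100 * lost))
  }
  lam
}

#' Render an activity map into a noisy count-rate image
#'
#' Draws independent Poisson voxel counts about the blurred expected-count
#' field and returns the image in cps (counts / duration).  Identical map,
#' parameters and seed give bit-identical output.
#'
#' @inheritParams expected_counts
#' @param seed integer RNG seed.
#' @param expected optionally, a precomputed [expected_counts()] field for
#'   this map (skips re-blurring in replicate loops).
#' @return An [image_volume] in cps with `duration` set.
#' @export
render <- function(map, psf_fwhm = 15, sensitivity = 28.9, duration = 4320,
                   seed = NULL, expected = NULL) {
  if (is.null(expected))
    expected <- expected_counts(map, psf_fwhm, sensitivity, duration)
  counts <- with_seed(seed, stats::rpois(length(expected), expected))
  img <- image_volume(array(counts / duration, dim(expected)),
                      spacing = map$spacing, duration = duration)
  attr(img, "manifest") <- map$manifest
  attr(img, "seed") <- seed
  img
}

#' Binomial thinning of a count image
#'
#' Keeps each recorded count independently with probability `p`, emulating
#' Poisson resampling of acquisition data: a thinned Poisson field is again
#' Poisson with mean scaled by `p`.  `p` may be a scalar (uniform
#' resampling), a vector along z (axial profile, e.g. a count gradient), or
#' a full 3D array.
#'
#' The image's voxel values times its duration must be (near-)integer
#' counts, as produced by [render()].
#'
#' @param image an [image_volume] whose counts are integers.
#' @param p keep-probability in \[0, 1\]: scalar, length-nz vector, or array.
#' @param seed integer RNG seed.
#' @return The thinned [image_volume]; the attached manifest gains a
#'   `thinning_factor` column with each element's count-weighted mean p.
#' @export
thin <- function(image, p, seed = NULL) {
  stopifnot(inherits(image, "image_volume"))
  if (!is.finite(image$duration) || image$duration <= 0)
    stop("image duration required to recover integer counts")
  counts <- image$voxels * image$duration
  if (max(abs(counts - round(counts))) > 1e-6)
    stop("image does not hold integer counts; thin() applies to rendered count data")
  counts <- round(counts)
  d <- dim(counts)
  pf <- if (length(p) == 1L) array(p, d)
        else if (is.null(dim(p)) && length(p) == d[3])
          aperm(array(rep(p, each = d[1] * d[2]), d), c(1, 2, 3))
        else if (identical(dim(p), d)) p
        else stop("'p' must be a scalar, a length-nz vector, or an array on the image grid")
  if (any(pf < 0) || any(pf > 1)) stop("thinning probabilities must lie in [0, 1]")
  thinned <- with_seed(seed,
    stats::rbinom(length(counts), size = as.integer(counts), prob = pf))
  out <- image_volume(array(thinned / image$duration, d),
                      spacing = image$spacing, duration = image$duration)
  man <- attr(image, "manifest")
  if (!is.null(man)) {
    # count-weighted mean keep-probability is a good per-element scale factor
    # only for elements of uniform concentration; exact for scalar p
    wmean <- sum(pf * counts) / max(sum(counts), 1)
    man$thinning_factor <- wmean
    man$activity_MBq <- man$activity_MBq * wmean
    attr(out, "manifest") <- man
  }
  attr(out, "seed") <- seed
  out
}

#' Axial thinning profiles
#'
#' Keep-probability profiles along the z axis for non-uniform background
#' construction: `thin_profile_linear` ramps linearly from `p_start` at the
#' first slice to `p_end` at the last; `thin_profile_half` holds 1 over the
#' first part of the volume and descends smoothly (cosine taper between
#' fractions 0.4 and 0.6 of the length) to `p_low`.
#'
#' @param nz number of z slices.
#' @param p_start,p_end,p_low keep-probabilities in \[0, 1\].
#' @return Numeric vector of length `nz`.
#' @export
thin_profile_linear <- function(nz, p_start = 1, p_end = 0.2) {
  seq(p_start, p_end, length.out = nz)
}

#' @rdname thin_profile_linear
#' @export
thin_profile_half <- function(nz, p_low = 0.2) {
  f <- (seq_len(nz) - 0.5) / nz
  w <- ifelse(f <= 0.4, 0, ifelse(f >= 0.6, 1, (1 - cos((f - 0.4) / 0.2 * pi)) / 2))
  1 - (1 - p_low) * w
}

#' Voxel-wise sum of two rendered images
#'
#' Emulates combining a separately acquired source dataset with a
#' (possibly resampled) background dataset.  Grids and durations must
#' match; ground-truth manifests are concatenated.
#'
#' @param source_image,background_image [image_volume]s on the same grid.
#' @return The composite [image_volume].
#' @export
composite <- function(source_image, background_image) {
  stopifnot(inherits(source_image, "image_volume"),
            inherits(background_image, "image_volume"))
  if (!identical(dim(source_image$voxels), dim(background_image$voxels)) ||
      max(abs(source_image$spacing - background_image$spacing)) > 1e-9)
    stop("grid mismatch between source and background images")
  out <- image_volume(source_image$voxels + background_image$voxels,
                      spacing = source_image$spacing,
                      duration = source_image$duration)
  m1 <- attr(source_image, "manifest"); m2 <- attr(background_image, "manifest")
  if (!is.null(m1) && !is.null(m2)) {
    for (col in setdiff(names(m2), names(m1))) m1[[col]] <- NA
    for (col in setdiff(names(m1), names(m2))) m2[[col]] <- NA
    attr(out, "manifest") <- rbind(m1, m2[names(m1)])
  } else attr(out, "manifest") <- m1 %||% m2
  out
}

#' Preset phantom scenarios
#'
#' Ready-made study configurations: a point-like capsule in the centre of a
#' 20-cm-diameter water cylinder with
#' \describe{
#'   \item{`cylinder-nobg`}{no background activity,}
#'   \item{`cylinder-uniform`}{a uniform 46 kBq/ml background,}
#'   \item{`cylinder-gradient`}{the uniform background thinned with an
#'     axial keep-probability ramp (1 to 0.2) to create a count gradient,}
#'   \item{`anthro`}{an anthropomorphic configuration: ellipsoidal torso
#'     background and liver/spleen/kidney organs (130.8, 77.2, 13.8, 17.0
#'     and 13.4 MBq) with four 0.12-ml point sources of 30 MBq/ml.}
#' }
#' Measurement-chain defaults: sensitivity 28.9 cps/MBq, duration 4320 s,
#' PSF FWHM 15 mm, 4.8 mm voxels.
#'
#' @param name preset name.
#' @param capsule_activity capsule activity in MBq (cylinder presets).
#' @param background_concentration background concentration, MBq/ml.
#' @param ... overrides passed to [phantom_spec()] (`dim`, `spacing`,
#'   `psf_fwhm`, `sensitivity`, `duration`).
#' @return A [phantom_spec].
#' @export
phantom_preset <- function(name = c("cylinder-nobg", "cylinder-uniform",
                                    "cylinder-gradient", "anthro"),
                           capsule_activity = 33.3,
                           background_concentration = 0.046, ...) {
  name <- match.arg(name)
  if (name == "anthro") {
    dim <- c(64L, 48L, 64L); spacing <- 4.8
    ext <- dim * spacing
    mid <- ext / 2
    torso <- phantom_ellipsoid(mid, semi_axes = c(145, 95, 145),
                               activity = 130.8, name = "background")
    liver <- phantom_ellipsoid(mid + c(55, 15, 35), semi_axes = c(70, 50, 55),
                               activity = 77.2, name = "liver")
    spleen <- phantom_ellipsoid(mid + c(-75, 10, 40), semi_axes = c(30, 25, 40),
                                activity = 13.8, name = "spleen")
    kidney_r <- phantom_ellipsoid(mid + c(45, -25, -45), semi_axes = c(25, 20, 45),
                                  activity = 17.0, name = "kidney_right")
    kidney_l <- phantom_ellipsoid(mid + c(-45, -25, -45), semi_axes = c(25, 20, 45),
                                  activity = 13.4, name = "kidney_left")
    pts <- Map(function(off, nm)
      phantom_point(mid + off, activity = 0.12 * 30, name = nm),
      list(c(100, 20, 60), c(-95, -15, -80), c(20, 55, -110), c(-30, -60, 100)),
      c("lesion_A", "lesion_B", "lesion_C", "lesion_D"))
    return(phantom_spec(dim = dim, spacing = spacing,
                        elements = c(list(torso, liver, spleen, kidney_r, kidney_l), pts),
                        ...))
  }
  spec <- phantom_spec(...)
  ext <- spec$dim * spec$spacing
  mid <- ext / 2
  elements <- list(phantom_point(mid, activity = capsule_activity, name = "capsule"))
  if (name %in% c("cylinder-uniform", "cylinder-gradient"))
    elements <- c(elements, list(
      phantom_cylinder(mid, radius = 100, length = 0.8 * ext[3],
                       concentration = background_concentration,
                       name = "background")))
  spec$elements <- elements
  attr(spec, "preset") <- name
  spec
}

#' Simulate a preset scenario end to end
#'
#' Voxelizes the preset, renders source and background separately (as in a
#' composite-acquisition protocol), applies axial thinning for the gradient
#' scenario, and sums.  Returns the image together with its ground-truth
#' manifest.
#'
#' @param name preset name, see [phantom_preset()].
#' @param seed integer seed controlling all Poisson/binomial draws.
#' @param thin_p keep-probability for the background (scalar or z profile);
#'   default 1 except for `cylinder-gradient`, which uses
#'   [thin_profile_linear()].
#' @param ... passed to [phantom_preset()].
#' @return List with `image` ([image_volume]) and `manifest` (data frame of
#'   per-element true activities, after any thinning).
#' @export
simulate_preset <- function(name, seed = 1L, thin_p = NULL, ...) {
  spec <- phantom_preset(name, ...)
  if (name == "anthro" || name == "cylinder-nobg" ||
      (is.null(thin_p) && name != "cylinder-gradient")) {
    map <- voxelize(spec)
    img <- render(map, spec$psf_fwhm, spec$sensitivity, spec$duration, seed = seed)
    return(list(image = img, manifest = attr(img, "manifest"), spec = spec))
  }
  # render source and background as separate acquisitions, thin bg, combine
  src_spec <- spec; src_spec$elements <- spec$elements[1]
  bg_spec <- spec; bg_spec$elements <- spec$elements[-1]
  src <- render(voxelize(src_spec), spec$psf_fwhm, spec$sensitivity,
                spec$duration, seed = seed)
  bg <- render(voxelize(bg_spec), spec$psf_fwhm, spec$sensitivity,
               spec$duration, seed = seed + 1000003L)
  if (is.null(thin_p) && name == "cylinder-gradient")
    thin_p <- thin_profile_linear(spec$dim[3])
  if (!is.null(thin_p) && !(length(thin_p) == 1L && all(thin_p == 1)))
    bg <- thin(bg, thin_p, seed = seed + 2000003L)
  img <- composite(src, bg)
  list(image = img, manifest = attr(img, "manifest"), spec = spec)
}
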