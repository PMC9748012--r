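test_that("voxelization deposits the specified activities", {
  spec <- phantom_spec(dim = c(24, 24, 24), spacing = 4.8,
                       elements = list(phantom_point(c(57.6, 57.6, 57.6), 33.3)))
  map <- voxelize(spec)
  expect_equal(sum(map$voxels), 33.3)
  expect_equal(map$manifest$n_voxels, 1L)

  # concentration-specified cylinder: total within 2% of the analytic volume
  spec2 <- phantom_spec(dim = c(48, 48, 48), spacing = 4.8,
                        elements = list(phantom_cylinder(c(115.2, 115.2, 115.2),
                                                         radius = 100, length = 180,
                                                         concentration = 0.046)))
  map2 <- voxelize(spec2)
  analytic <- 0.046 * pi * 100^2 * 180 / 1000
  expect_equal(sum(map2$voxels), analytic, tolerance = 0.02)
  expect_equal(map2$manifest$activity_MBq, sum(map2$voxels), tolerance = 1e-12)

  # total-activity ellipsoid: voxel sum matches the total exactly
  spec3 <- phantom_spec(dim = c(24, 24, 24), spacing = 4.8,
                        elements = list(phantom_ellipsoid(c(57.6, 57.6, 57.6),
                                                          c(40, 30, 35),
                                                          activity = 77.2)))
  expect_equal(sum(voxelize(spec3)$voxels), 77.2, tolerance = 1e-12)

  # empty spec -> all-zero map; out-of-grid element -> error
  expect_equal(sum(voxelize(phantom_spec(dim = c(8, 8, 8)))$voxels), 0)
  expect_error(voxelize(phantom_spec(dim = c(8, 8, 8), elements = list(
    phantom_sphere(c(500, 500, 500), 5, concentration = 1)))), "outside")
})

test_that("rendering conserves expected counts and is seed-deterministic", {
  spec <- phantom_spec(dim = c(32, 32, 32), spacing = 4.8,
                       elements = list(phantom_point(c(76.8, 76.8, 76.8), 33.3)))
  map <- voxelize(spec)
  lam <- expected_counts(map, psf_fwhm = 15, sensitivity = 28.9, duration = 4320)
  # convolution conserves counts (centred source, no boundary truncation)
  expect_equal(sum(lam) / 4320, 33.3 * 28.9, tolerance = 1e-6)

  img1 <- render(map, 15, 28.9, 4320, seed = 99)
  img2 <- render(map, 15, 28.9, 4320, seed = 99)
  expect_identical(img1$voxels, img2$voxels)          # bit-identical
  img3 <- render(map, 15, 28.9, 4320, seed = 100)
  expect_false(identical(img1$voxels, img3$voxels))

  # zero map renders to zero
  z <- voxelize(phantom_spec(dim = c(8, 8, 8)))
  expect_equal(sum(render(z, 15, 28.9, 60, seed = 1)$voxels), 0)
})

test_that("mean rendered count rate matches activity x sensitivity", {
  spec <- phantom_spec(dim = c(24, 24, 24), spacing = 4.8,
                       elements = list(phantom_point(c(57.6, 57.6, 57.6), 33.3)))
  map <- voxelize(spec)
  lam <- expected_counts(map, 15, 28.9, 600)
  totals <- vapply(1:100, function(s)
    sum(render(map, 15, 28.9, 600, seed = s, expected = lam)$voxels), numeric(1))
  expect_equal(mean(totals), 962.37, tolerance = 0.01)   # 33.3 x 28.9, within 1%
})

test_that("voxel counts are Poisson-dispersed across seeds", {
  # pooled index-of-dispersion test: for Poisson, (S-1) * var/mean per voxel
  # sums to a chi-square with V*(S-1) df
  map <- voxelize(phantom_spec(dim = c(12, 12, 12), spacing = 10, elements = list(
    phantom_sphere(c(60, 60, 60), 55, concentration = 0.002))))
  nseeds <- 60
  lam <- suppressWarnings(expected_counts(map, 20, 28.9, 300))
  counts <- vapply(seq_len(nseeds), function(s)
    as.vector(render(map, 20, 28.9, 300, seed = 7000 + s,
                     expected = lam)$voxels) * 300, numeric(length(lam)))
  keep <- rowMeans(counts) >= 5
  m <- rowMeans(counts[keep, ]); v <- apply(counts[keep, ], 1, var)
  stat <- sum((nseeds - 1) * v / m)
  df <- sum(keep) * (nseeds - 1)
  p <- pchisq(stat, df)
  expect_gt(p, 0.025); expect_lt(p, 0.975)
})

test_that("binomial thinning preserves counts at p = 1 and scales the mean", {
  map <- voxelize(phantom_spec(dim = c(16, 16, 16), spacing = 4.8, elements = list(
    phantom_sphere(c(38.4, 38.4, 38.4), 30, concentration = 0.05))))
  img <- suppressWarnings(render(map, 15, 28.9, 600, seed = 5))
  expect_identical(thin(img, 1, seed = 2)$voxels, img$voxels)
  th <- thin(img, 0.25, seed = 2)
  expect_equal(sum(th$voxels) / sum(img$voxels), 0.25, tolerance = 0.01)
  expect_error(thin(img, 1.2, seed = 1), "\\[0, 1\\]")
  # manifest activity rescales with the keep-probability
  expect_equal(attr(th, "manifest")$activity_MBq,
               attr(img, "manifest")$activity_MBq * 0.25, tolerance = 1e-12)
})

test_that("axial thinning imposes the requested count gradient", {
  nz <- 24L
  map <- voxelize(phantom_spec(dim = c(16, 16, nz), spacing = 4.8, elements = list(
    phantom_cylinder(c(38.4, 38.4, 57.6), radius = 35, length = 110,
                     concentration = 0.05))))
  p <- thin_profile_linear(nz, 1, 0.2)
  lam <- expected_counts(map, 0.001, 28.9, 600)   # negligible blur: crisp profile
  ratios <- matrix(NA_real_, 20, nz)
  base_profile <- apply(lam, 3, sum)
  for (s in 1:20) {
    img <- render(map, 0.001, 28.9, 600, seed = 300 + s, expected = lam)
    th <- thin(img, p, seed = 400 + s)
    ratios[s, ] <- apply(th$voxels * 600, 3, sum) / pmax(base_profile, 1)
  }
  inz <- which(base_profile > 1000)
  fitted_slope <- coef(lm(colMeans(ratios)[inz] ~ inz))[2]
  true_slope <- coef(lm(p[inz] ~ inz))[2]
  expect_equal(unname(fitted_slope), unname(true_slope), tolerance = 0.05)
  # half-volume profile: flat start, p_low end, within [p_low, 1]
  ph <- thin_profile_half(nz, 0.2)
  expect_equal(ph[1], 1); expect_equal(ph[nz], 0.2)
  expect_true(all(diff(ph) <= 1e-12))
})

test_that("composites add voxel-wise and concatenate manifests", {
  mapA <- voxelize(phantom_spec(dim = c(12, 12, 12), spacing = 4.8,
                                elements = list(phantom_point(c(28.8, 28.8, 28.8), 5))))
  mapB <- voxelize(phantom_spec(dim = c(12, 12, 12), spacing = 4.8, elements = list(
    phantom_sphere(c(28.8, 28.8, 28.8), 20, concentration = 0.01))))
  a <- render(mapA, 15, 28.9, 600, seed = 1)
  b <- suppressWarnings(render(mapB, 15, 28.9, 600, seed = 2))
  ab <- composite(a, b)
  expect_equal(ab$voxels, a$voxels + b$voxels)
  man <- attr(ab, "manifest")
  expect_equal(sum(man$activity_MBq),
               sum(attr(a, "manifest")$activity_MBq) +
                 sum(attr(b, "manifest")$activity_MBq))
  # Poisson additivity: variance of the summed render tracks the summed mean
  lamA <- expected_counts(mapA, 15, 28.9, 600)
  lamB <- suppressWarnings(expected_counts(mapB, 15, 28.9, 600))
  tot <- vapply(1:60, function(s) {
    x <- composite(render(mapA, 15, 28.9, 600, seed = s, expected = lamA),
                   render(mapB, 15, 28.9, 600, seed = 5000 + s, expected = lamB))
    sum(x$voxels) * 600
  }, numeric(1))
  expect_equal(var(tot), sum(lamA) + sum(lamB), tolerance = 0.45)
  expect_error(composite(a, render(voxelize(phantom_spec(dim = c(8, 8, 8))),
                                   15, 28.9, 600, seed = 1)), "mismatch")
})

test_that("preset scenarios carry a consistent ground-truth manifest", {
  sim <- simulate_preset("cylinder-uniform", seed = 3)
  man <- sim$manifest
  expect_setequal(man$name, c("capsule", "background"))
  expect_equal(man$activity_MBq[man$name == "capsule"], 33.3)
  expect_equal(man$concentration_MBq_ml[man$name == "background"], 0.046)
  # gradient preset: background activity reduced by the thinning profile
  simg <- simulate_preset("cylinder-gradient", seed = 3)
  bg <- simg$manifest
  expect_lt(bg$activity_MBq[bg$name == "background"],
            man$activity_MBq[man$name == "background"])
  expect_equal(bg$activity_MBq[bg$name == "capsule"], 33.3)
  # anthro preset: organs plus four 3.6 MBq point lesions
  spec <- phantom_preset("anthro")
  nm <- vapply(spec$elements, `[[`, "", "name")
  expect_setequal(nm, c("background", "liver", "spleen", "kidney_right",
                        "kidney_left", "lesion_A", "lesion_B", "lesion_C",
                        "lesion_D"))
  acts <- vapply(spec$elements,
                 function(e) if (is.null(e$activity)) NA_real_ else e$activity, 1)
  expect_equal(sort(acts[1:5]), sort(c(130.8, 77.2, 13.8, 17.0, 13.4)))
  expect_equal(unname(acts[6:9]), rep(0.12 * 30, 4))
})
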