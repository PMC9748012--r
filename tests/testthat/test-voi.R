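test_that("sphere VOI extraction sums count rates over centre-in-sphere voxels", {
  img <- uniform_image(1, c(16, 16, 16), spacing = 4)
  m <- extract_voi_count_rate(img, center = c(32, 32, 32), radius = 12)
  k <- sum(sphere_mask(img, c(32, 32, 32), 12))
  expect_equal(m$count_rate, k)                       # uniform field: K voxels -> K cps
  expect_equal(m$volume, k * 64 / 1000)
  expect_false(m$truncated)

  zero <- uniform_image(0)
  expect_equal(extract_voi_count_rate(zero, c(32, 32, 32), 15)$count_rate, 0)
})

test_that("sphere extraction matches an exhaustive voxel-loop oracle", {
  set.seed(11)
  img <- image_volume(array(runif(10 * 12 * 9), c(10, 12, 9)),
                      spacing = c(3, 4, 5))
  for (case in list(list(c = c(15, 24, 22), r = 9),
                    list(c = c(10.2, 30.1, 12.7), r = 13.5),
                    list(c = c(22, 18, 30), r = 6.1))) {
    got <- suppressWarnings(extract_voi_count_rate(img, case$c, case$r))
    want <- brute_force_voi(img, case$c, case$r)
    expect_equal(got$count_rate, want$count_rate, tolerance = 1e-12)
    expect_equal(got$volume, want$volume, tolerance = 1e-12)
  }
})

test_that("out-of-grid and truncated spheres are flagged", {
  img <- uniform_image(1, c(10, 10, 10), spacing = 4)
  expect_error(extract_voi_count_rate(img, c(200, 200, 200), 5), "empty VOI")
  expect_warning(extract_voi_count_rate(img, c(4, 20, 20), 10), "truncated")
})

test_that("concentric series has the planned radii and increasing volumes", {
  img <- uniform_image(0, c(32, 32, 32), spacing = 4)
  s <- build_concentric_series(img, c(64, 64, 64), base_radius = 20,
                               n_vois = 4, radius_step = 5)
  expect_equal(s$radius, c(20, 25, 30, 35))
  expect_true(all(diff(s$volume) > 0))
  expect_equal(s$count_rate, rep(0, 4))
  expect_error(build_concentric_series(img, c(64, 64, 64), 20, n_vois = 2), "n_vois")
})

test_that("uniform background gives count rates proportional to VOI volume", {
  conc_per_voxel <- 0.37
  img <- uniform_image(conc_per_voxel, c(32, 32, 32), spacing = 4)
  s <- build_concentric_series(img, c(64, 64, 64), 20, n_vois = 4, radius_step = 6)
  # same inclusion rule for numerator and denominator: exact proportionality
  expect_equal(s$count_rate, conc_per_voxel / (prod(rep(4, 3)) / 1000) * s$volume,
               tolerance = 1e-12)
})

test_that("mask-based VOIs agree with sphere-based extraction", {
  set.seed(4)
  img <- image_volume(array(rpois(16^3, 5), c(16, 16, 16)), spacing = 4)
  m <- sphere_mask(img, c(32, 32, 32), 14)
  a <- extract_mask_count_rate(img, m)
  b <- extract_voi_count_rate(img, c(32, 32, 32), 14)
  expect_equal(a$count_rate, b$count_rate)
  expect_equal(a$volume, b$volume)
  expect_error(extract_mask_count_rate(img, array(FALSE, c(16, 16, 16))), "empty")
  expect_error(extract_mask_count_rate(img, array(TRUE, c(8, 8, 8))), "dimensions")
})
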