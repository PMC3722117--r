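make_pet <- function(values, spacing = 4) {
  g <- image_geometry(dim(values), rep(spacing, 3),
                      origin = -(dim(values) - 1) * spacing / 2)
  suv_image(g, values)
}

full_region <- function(pet) {
  structure_mask(pet$geometry, array(TRUE, pet$geometry$shape), "region")
}

test_that("lesion SUVmax returns the maximum and a deterministic seed", {
  v <- array(0, c(6, 6, 6))
  v[3, 4, 2] <- 9.2
  pet <- make_pet(v)
  mx <- lesion_suv_max(pet, full_region(pet))
  expect_equal(mx$suv_max, 9.2)
  expect_equal(mx$seed, c(3L, 4L, 2L))

  # uniform region: max equals the constant, seed is some region voxel
  u <- make_pet(array(7, c(4, 4, 4)))
  expect_equal(lesion_suv_max(u, full_region(u))$suv_max, 7)

  # tie broken by lowest lexicographic (i, j, k) index
  v2 <- array(0, c(5, 5, 5))
  v2[4, 2, 3] <- 5; v2[2, 5, 5] <- 5
  pet2 <- make_pet(v2)
  expect_equal(lesion_suv_max(pet2, full_region(pet2))$seed, c(2L, 5L, 5L))

  empty <- structure_mask(pet$geometry, array(FALSE, c(6, 6, 6)))
  expect_error(lesion_suv_max(pet, empty), "empty")
})

test_that("percent thresholding keeps the supra-threshold seed component", {
  # 1-D profile [0,2,5,10,5,2,0] at 50%: 3 contiguous voxels >= 5
  v <- array(0, c(7, 3, 3))
  v[, 2, 2] <- c(0, 2, 5, 10, 5, 2, 0)
  pet <- make_pet(v)
  btv <- percent_threshold_btv(pet, full_region(pet),
                               threshold_spec("percent_of_max", 0.50))
  expect_equal(sum(btv$voxels), 3L)
  expect_true(all(btv$voxels[3:5, 2, 2]))
  expect_equal(attr(btv, "threshold"), 5)

  # noiseless two-level sphere: any percent returns exactly the sphere
  g <- geom_iso(16, 4)
  sph <- rasterize_sphere(voi_sphere(c(0, 0, 0), 20), g)
  vals <- array(0, g$shape); vals[sph$voxels] <- 10
  pet2 <- suv_image(g, vals)
  for (p in c(0.05, 0.38, 0.50, 1.0)) {
    btv2 <- percent_threshold_btv(pet2, full_region(pet2),
                                  threshold_spec("percent_of_max", p))
    expect_identical(btv2$voxels, sph$voxels)
  }
})

test_that("region growing keeps only the component containing the global max", {
  # two lesions, SUV 10 and 8; at 38% the threshold (3.8) passes both but
  # only the component of the global maximum is grown
  g <- geom_iso(24, 4)
  a <- rasterize_sphere(voi_sphere(c(-24, 0, 0), 15), g)
  b <- rasterize_sphere(voi_sphere(c(28, 0, 0), 15), g)
  vals <- array(0, g$shape)
  vals[a$voxels] <- 10; vals[b$voxels] <- 8
  pet <- suv_image(g, vals)
  btv <- percent_threshold_btv(pet, full_region(pet),
                               threshold_spec("percent_of_max", 0.38))
  expect_identical(btv$voxels, a$voxels)

  # brute-force connected-component oracle: grown mask is connected and
  # maximal among supra-threshold voxels reachable from the seed
  cand <- vals >= 3.8
  expect_true(all(btv$voxels[btv$voxels] %in% cand[btv$voxels]))
  expect_equal(sum(btv$voxels), sum(a$voxels))
})

test_that("connectivity options change what region growing can reach", {
  # two voxels touching only at a corner: connected at 26, not at 6
  v <- array(0, c(4, 4, 4))
  v[2, 2, 2] <- 10; v[3, 3, 3] <- 9
  pet <- make_pet(v)
  reg <- full_region(pet)
  spec <- threshold_spec("percent_of_max", 0.5)
  expect_equal(sum(percent_threshold_btv(pet, reg, spec, 26)$voxels), 2L)
  expect_equal(sum(percent_threshold_btv(pet, reg, spec, 6)$voxels), 1L)
  # edge-touching: connected at 18, not at 6
  v2 <- array(0, c(4, 4, 4))
  v2[2, 2, 2] <- 10; v2[3, 3, 2] <- 9
  pet2 <- make_pet(v2)
  expect_equal(sum(percent_threshold_btv(pet2, reg, spec, 18)$voxels), 2L)
  expect_equal(sum(percent_threshold_btv(pet2, reg, spec, 6)$voxels), 1L)
})

test_that("percent thresholds are scale invariant and nested", {
  set.seed(31)
  spec <- small_phantom_spec(seed = 31)
  ph <- generate_phantom(spec)
  reg <- bounding_region(ph$truth_mask, 16)
  specs <- lapply(c(0.38, 0.42, 0.47, 0.50),
                  function(p) threshold_spec("percent_of_max", p))
  masks <- lapply(specs, function(s) percent_threshold_btv(ph$pet, reg, s))
  # nestedness: higher percent is a subset of lower percent
  for (i in 2:4)
    expect_true(all(masks[[i]]$voxels <= masks[[i - 1]]$voxels))
  # scale invariance: multiplying the image by a positive constant
  pet_scaled <- suv_image(ph$pet$geometry, ph$pet$values * 3.7)
  for (i in seq_along(specs))
    expect_identical(percent_threshold_btv(pet_scaled, reg,
                                           specs[[i]])$voxels,
                     masks[[i]]$voxels)
})

test_that("background statistics use the sample SD over the hepatic VOI", {
  g <- geom_iso(20, 2)
  voi <- voi_sphere(c(0, 0, 0), 15)
  # constant liver
  pet <- suv_image(g, array(2.5, g$shape))
  bs <- background_stats(pet, voi)
  expect_equal(bs$mean_suv, 2.5)
  expect_equal(bs$sd_suv, 0)
  expect_gt(bs$n_voxels, 1500)  # ~15 ml / 0.008 ml

  # three-voxel VOI {1,2,3}: mean 2, sample SD 1 (n-1 denominator)
  g3 <- image_geometry(c(3, 1, 1), c(2, 2, 2), origin = c(-2, 0, 0))
  pet3 <- suv_image(g3, array(c(1, 2, 3), c(3, 1, 1)))
  bs3 <- background_stats(pet3, voi_sphere(c(0, 0, 0), 4 / 3 * pi * 0.25^3))
  expect_equal(bs3$n_voxels, 3L)
  expect_equal(bs3$mean_suv, 2)
  expect_equal(bs3$sd_suv, 1)

  # seeded Gaussian liver recovers its parameters
  set.seed(41)
  petg <- suv_image(g, array(rnorm(prod(g$shape), 2.0, 0.3), g$shape))
  bsg <- background_stats(petg, voi)
  expect_lt(abs(bsg$mean_suv - 2.0), 0.05)
  expect_lt(abs(bsg$sd_suv - 0.3), 0.05)

  # VOI with < 2 voxels in grid
  expect_error(suppressWarnings(
    background_stats(pet, voi_sphere(c(500, 0, 0), 15))), "VOI")
})

test_that("PERCIST-style threshold is liver mean + multiplier x SD", {
  expect_equal(percist_threshold(list(mean_suv = 2.0, sd_suv = 0.2), 3), 2.6)
  expect_equal(percist_threshold(list(mean_suv = 2.0, sd_suv = 0), 3), 2.0)
})

test_that("PERCIST segmentation recovers a noiseless lesion and flags
           PET-negative ones", {
  g <- geom_iso(24, 4)
  sph <- rasterize_sphere(voi_sphere(c(20, 20, 12), 20), g)
  liver_voi <- voi_sphere(c(-24, -24, -16), 10)
  vals <- array(0, g$shape)
  vals[sph$voxels] <- 10
  liver_mask <- rasterize_sphere(voi_sphere(c(-24, -24, -16), 40), g)
  vals[liver_mask$voxels] <- 2.0
  pet <- suv_image(g, vals)
  reg <- bounding_region(sph, 12)
  spec <- threshold_spec("percist_tlg", background_voi = liver_voi)
  btv <- percist_tlg_btv(pet, reg, spec)
  expect_equal(attr(btv, "threshold"), 2.0)
  expect_identical(btv$voxels, sph$voxels)
  expect_null(attr(btv, "flag"))

  # lesion below background threshold: empty mask + flag, no error
  vals2 <- vals; vals2[sph$voxels] <- 1.5
  btv2 <- percist_tlg_btv(suv_image(g, vals2), reg, spec)
  expect_false(any(btv2$voxels))
  expect_equal(attr(btv2, "flag"), "lesion not above background")
})

test_that("structure exclusion is plain set subtraction", {
  g <- geom_iso(8)
  set.seed(51)
  btv <- random_blob_mask(g, 2, c(1.5, 3))
  none <- structure_mask(g, array(FALSE, g$shape))
  expect_identical(exclude_structures(btv, none)$voxels, btv$voxels)
  all_mask <- structure_mask(g, array(TRUE, g$shape))
  expect_false(any(exclude_structures(btv, all_mask)$voxels))
  avoid <- random_blob_mask(g, 2, c(1.5, 3))
  out <- exclude_structures(btv, avoid)
  expect_equal(sum(out$voxels), sum(btv$voxels & !avoid$voxels))
  expect_lte(volume_ml(out), volume_ml(btv))
  g2 <- geom_iso(8, 2)
  expect_error(exclude_structures(btv, structure_mask(g2, array(FALSE, g2$shape))),
               "geometry")
})
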