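test_that("noiseless blur-free phantom is exactly two-valued with the
           analytic truth volume", {
  spec <- small_phantom_spec(seed = 5, radius_mm = 12, psf_fwhm_mm = 0,
                             noise_sd_suv = 0, liver_sd = 0)
  ph <- generate_phantom(spec)
  liver_vol_ml <- 4 / 3 * pi * (spec$liver$radius_mm / 10)^3
  liver <- rasterize_sphere(voi_sphere(spec$liver$centre, liver_vol_ml),
                            spec$geometry_pet)
  vals_outside_liver <- ph$pet$values[!liver$voxels]
  expect_true(all(vals_outside_liver %in% c(spec$background_suv,
                                            spec$lesions[[1]]$peak_suv)))
  analytic <- 4 / 3 * pi * 1.2^3  # r = 1.2 cm -> ml
  expect_lt(abs(volume_ml(ph$truth_mask) - analytic) / analytic, 0.12)
  # zero-error contouring: GTV equals the back-projected truth exactly
  expect_identical(ph$gtv_mask$voxels,
                   resample_mask(ph$truth_mask, spec$geometry_ct)$voxels)
})

test_that("a fixed seed reproduces the phantom bit-identically", {
  spec <- small_phantom_spec(seed = 99, gtv_error = list(
    offset_mm = 2, warp_amplitude_mm = 2, warp_knots = 5))
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$pet$values, b$pet$values)
  expect_identical(a$gtv_mask$voxels, b$gtv_mask$voxels)
  expect_identical(a$truth_mask$voxels, b$truth_mask$voxels)
})

test_that("phantom validation rejects off-grid and overlapping anatomy", {
  expect_error(generate_phantom(small_phantom_spec(centre = c(100, 0, 0))),
               "outside")
  bad <- small_phantom_spec()
  bad$lesions[[1]]$centre <- bad$liver$centre + c(10, 0, 0)
  expect_error(generate_phantom(bad), "overlap")
  expect_error(phantom_spec(lesions = list(list(centre = c(0, 0, 0),
                                                semiaxes = c(10, 10, 10),
                                                peak_suv = 0.5))),
               "background")
})

test_that("noise stays bounded: lesion SUVmax never exceeds peak + 5 SD", {
  for (s in 1:5) {
    ph <- generate_phantom(small_phantom_spec(seed = s))
    expect_lte(max(ph$pet$values[ph$truth_mask$voxels]),
               ph$suv_max_true + 5 * ph$spec$noise_sd_suv + 1e-9)
  }
})

test_that("GTV error model dilates and erodes by the requested margin", {
  r <- 12
  spec_d <- small_phantom_spec(seed = 3, radius_mm = r, psf_fwhm_mm = 0,
                               noise_sd_suv = 0,
                               gtv_error = list(offset_mm = 4,
                                                warp_amplitude_mm = 0,
                                                warp_knots = 5))
  ph_d <- generate_phantom(spec_d)
  ratio_d <- volume_ml(ph_d$gtv_mask) / volume_ml(ph_d$truth_mask)
  expect_gt(ratio_d, ((r + 2) / r)^3 * 0.85)
  expect_lt(ratio_d, ((r + 6) / r)^3)
  spec_e <- small_phantom_spec(seed = 3, radius_mm = r, psf_fwhm_mm = 0,
                               noise_sd_suv = 0,
                               gtv_error = list(offset_mm = -4,
                                                warp_amplitude_mm = 0,
                                                warp_knots = 5))
  ph_e <- generate_phantom(spec_e)
  expect_lt(volume_ml(ph_e$gtv_mask), volume_ml(ph_e$truth_mask))
})

test_that("hepatic compartment realises the requested liver statistics", {
  ph <- generate_phantom(small_phantom_spec(seed = 17))
  bs <- background_stats(ph$pet, ph$liver_voi)
  expect_lt(abs(bs$mean_suv - 2.0), 0.05)
  expect_lt(abs(bs$sd_suv - 0.3), 0.05)
})

test_that("cohort site allocation is deterministic largest-remainder", {
  coh <- generate_cohort(4, seed = 2,
                         geometry_pet = small_phantom_spec()$geometry_pet,
                         geometry_ct = small_phantom_spec()$geometry_ct)
  sites <- vapply(coh, `[[`, character(1), "site")
  expect_equal(sum(sites == "lung"), 2L)       # 1.6 -> 1 + largest remainder
  expect_equal(sum(sites == "oesophageal"), 1L)
  expect_equal(sum(sites == "pelvic"), 1L)
  coh1 <- generate_cohort(1, seed = 2,
                          geometry_pet = small_phantom_spec()$geometry_pet,
                          geometry_ct = small_phantom_spec()$geometry_ct)
  expect_equal(coh1[[1]]$site, "lung")          # highest proportion
  expect_error(generate_cohort(5, site_mix = c(0.5, 0.2, 0.2)), "sum")
})

test_that("cohort generation is seed-reproducible with peaks in 3.1-18.2", {
  gp <- small_phantom_spec()$geometry_pet
  gc <- small_phantom_spec()$geometry_ct
  a <- generate_cohort(3, seed = 7, geometry_pet = gp, geometry_ct = gc)
  b <- generate_cohort(3, seed = 7, geometry_pet = gp, geometry_ct = gc)
  for (i in 1:3) {
    expect_identical(a[[i]]$phantom$pet$values, b[[i]]$phantom$pet$values)
    peak <- a[[i]]$phantom$suv_max_true
    expect_gte(peak, 3.1); expect_lte(peak, 18.2)
  }
})

test_that("dilated GTVs give btv_in_gtv >= gtv_in_btv and eroded the
           reverse", {
  run_one <- function(offset, seed) {
    spec <- small_phantom_spec(seed = seed, gtv_error = list(
      offset_mm = offset, warp_amplitude_mm = 1, warp_knots = 5))
    run <- run_btv_pipeline(generate_phantom(spec))
    sapply(run$reports, function(r) c(big = r$b_in_a_pct, gib = r$a_in_b_pct))
  }
  dil <- rowMeans(sapply(1:3, function(s) rowMeans(run_one(5, s))))
  expect_gt(dil["big"], dil["gib"])
  ero <- rowMeans(sapply(1:3, function(s) rowMeans(run_one(-5, s))))
  expect_lt(ero["big"], ero["gib"])
})

test_that("segmented volumes shrink with increasing percent threshold and
           stay near truth under blur", {
  # 30 mm sphere, peak 10 over background 1, FWHM 7 mm, noise 0.2
  spec <- small_phantom_spec(seed = 19, radius_mm = 15, peak_suv = 10,
                             centre = c(12, 12, 8))
  ph <- generate_phantom(spec)
  run <- run_btv_pipeline(ph)
  v <- sapply(run$btv_pet[c("SUV38", "SUV42", "SUV47", "SUV50")], volume_ml)
  expect_true(all(diff(v) <= 1e-12))
  truth_v <- volume_ml(ph$truth_mask)
  for (nm in c("SUV42", "SUV47", "SUV50"))
    expect_lt(abs(volume_ml(run$btv_pet[[nm]]) - truth_v) / truth_v, 0.30)
})
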