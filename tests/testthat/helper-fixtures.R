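# Shared fixture builders and independent brute-force oracles.

# small isotropic geometry centred on the origin
geom_iso <- function(n, spacing = 1) {
  image_geometry(rep(n, 3), rep(spacing, 3),
                 origin = rep(-(n - 1) * spacing / 2, 3))
}

# integer refinement of a geometry: spacing / f, voxel centres tiling the
# original voxels
refine_geometry <- function(geometry, f) {
  image_geometry(geometry$shape * f, geometry$spacing / f,
                 origin = geometry$origin - geometry$spacing / 2 +
                   geometry$spacing / (2 * f),
                 direction = geometry$direction)
}

# compact phantom spec for fast tests: 32^3 PET at 4 mm (extent +/-64 mm),
# 48^3 CT at 2.66 mm sharing the extent
small_phantom_spec <- function(seed = 1, radius_mm = 11, peak_suv = 9.2,
                               psf_fwhm_mm = 7, noise_sd_suv = 0.2,
                               liver_sd = 0.3,
                               gtv_error = list(offset_mm = 0,
                                                warp_amplitude_mm = 0,
                                                warp_knots = 5),
                               centre = c(18, 18, 10)) {
  pet <- image_geometry(rep(32, 3), rep(4, 3), origin = rep(-62, 3))
  ct <- image_geometry(rep(48, 3), rep(8 / 3, 3),
                       origin = rep(-62 - 2 + 4 / 3, 3))
  phantom_spec(
    geometry_pet = pet, geometry_ct = ct,
    lesions = list(list(centre = centre, semiaxes = rep(radius_mm, 3),
                        peak_suv = peak_suv)),
    liver = list(centre = c(-36, -36, -24), radius_mm = 16, mean_suv = 2.0,
                 sd_suv = liver_sd, voi_ml = 10),
    psf_fwhm_mm = psf_fwhm_mm, noise_sd_suv = noise_sd_suv,
    gtv_error = gtv_error, seed = seed)
}

# random blobby mask: union of a few random spheres on a small grid
random_blob_mask <- function(geometry, n_spheres = 3, r_range = c(2.5, 5)) {
  vox <- array(FALSE, geometry$shape)
  extent <- (geometry$shape - 1) * geometry$spacing / 2
  for (s in seq_len(n_spheres)) {
    centre <- stats::runif(3, -extent * 0.5, extent * 0.5) + geometry$origin +
      extent
    r <- stats::runif(1, r_range[1], r_range[2])
    sph <- voi_sphere(centre, 4 / 3 * pi * (r / 10)^3)
    vox <- vox | suppressWarnings(rasterize_sphere(sph, geometry))$voxels
  }
  structure_mask(geometry, vox, "blob")
}

# independent voxel-set overlap oracle: works on which() index sets
overlap_oracle <- function(a, b) {
  ia <- which(a$voxels); ib <- which(b$voxels)
  inter <- length(intersect(ia, ib))
  uni <- length(union(ia, ib))
  list(jaccard_pct = if (uni > 0) 100 * inter / uni else 0,
       dice_pct = if (length(ia) + length(ib) > 0)
         100 * 2 * inter / (length(ia) + length(ib)) else 0,
       btv_in_gtv_pct = if (length(ib) > 0) 100 * inter / length(ib)
         else NA_real_,
       gtv_in_btv_pct = if (length(ia) > 0) 100 * inter / length(ia)
         else NA_real_)
}

# literal 2^n enumeration oracle for the two-sided signed-rank p-value
wilcoxon_enum_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_plus <- as.numeric(signs %*% r)
  min(1, 2 * mean(w_plus <= w_obs + 1e-12))
}

# brute-force nearest-neighbour resampling oracle (half-up rounding of the
# continuous source index, matching the documented voxel model)
resample_oracle <- function(mask, target) {
  out <- array(FALSE, target$shape)
  src <- mask$geometry
  for (k in seq_len(target$shape[3]))
    for (j in seq_len(target$shape[2]))
      for (i in seq_len(target$shape[1])) {
        w <- voxel_to_world(target, c(i, j, k) - 1)
        ci <- floor(world_to_voxel(src, w) + 0.5)
        if (all(ci >= 0) && all(ci < src$shape))
          out[i, j, k] <- mask$voxels[ci[1] + 1, ci[2] + 1, ci[3] + 1]
      }
  structure_mask(target, out, mask$label)
}
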