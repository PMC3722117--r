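#' Synthetic PET/CT phantom specification
#'
#' Generative description of one synthetic patient: a coarse PET grid and a
#' finer planning-CT grid, one or more focal lesions (spheres or axis-aligned
#' ellipsoids) of stated peak SUV over a soft-tissue background, a spherical
#' hepatic compartment supplying the PERCIST background VOI, a Gaussian
#' point-spread blur emulating partial-volume effects, additive Gaussian
#' noise, and an error model for the simulated "manual" GTV contour.
#'
#' @param geometry_pet,geometry_ct \code{image_geometry} of the PET and CT
#'   grids; defaults are a 48^3 grid at 4 mm and a 96^3 grid at 2 mm sharing
#'   the same centred world extent.
#' @param lesions list of lesions, each a list with \code{centre} (mm),
#'   \code{semiaxes} (3 positive mm; equal for a sphere) and \code{peak_suv}.
#' @param background_suv soft-tissue background SUV (default 1.0).
#' @param liver list with \code{centre} (mm), \code{radius_mm} (compartment
#'   radius), \code{mean_suv}, \code{sd_suv}, \code{voi_ml} (measurement VOI
#'   volume, default 15 ml). Liver voxels are assigned their seeded Gaussian
#'   SUV field after blur and noise, so the compartment realises exactly the
#'   stated measured statistics (SD 0 gives a constant field).
#' @param psf_fwhm_mm Gaussian PSF full width at half maximum, mm (>= 0).
#' @param noise_sd_suv additive Gaussian noise SD in SUV units (>= 0).
#' @param gtv_error list with \code{offset_mm} (positive dilates, negative
#'   erodes the true contour), \code{warp_amplitude_mm} (SD of a smooth
#'   low-frequency boundary perturbation) and \code{warp_knots} (coarse knots
#'   per axis of the warp field, default 5).
#' @param seed integer RNG seed; fixes all randomness end-to-end.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(geometry_pet = default_pet_geometry(),
                         geometry_ct = default_ct_geometry(),
                         lesions = list(list(centre = c(25, 25, 15),
                                             semiaxes = c(17, 17, 17),
                                             peak_suv = 9.2)),
                         background_suv = 1.0,
                         liver = list(centre = c(-50, -50, -30),
                                      radius_mm = 25, mean_suv = 2.0,
                                      sd_suv = 0.3, voi_ml = 15),
                         psf_fwhm_mm = 7, noise_sd_suv = 0.2,
                         gtv_error = list(offset_mm = 0,
                                          warp_amplitude_mm = 0,
                                          warp_knots = 5),
                         seed = 1L) {
  stopifnot(inherits(geometry_pet, "image_geometry"),
            inherits(geometry_ct, "image_geometry"))
  if (length(lesions) < 1) stop("at least one lesion is required")
  for (l in lesions) {
    if (length(l$semiaxes) != 3 || any(l$semiaxes <= 0))
      stop("lesion semiaxes must be 3 positive mm values")
    if (!is.finite(l$peak_suv) || l$peak_suv <= background_suv)
      stop("lesion peak_suv must exceed background_suv")
  }
  if (background_suv < 0 || liver$mean_suv < 0 || liver$sd_suv < 0)
    stop("SUV parameters must be non-negative")
  if (psf_fwhm_mm < 0 || noise_sd_suv < 0)
    stop("psf_fwhm_mm and noise_sd_suv must be non-negative")
  if (is.null(gtv_error$warp_knots)) gtv_error$warp_knots <- 5
  if (is.null(liver$voi_ml)) liver$voi_ml <- 15
  structure(list(geometry_pet = geometry_pet, geometry_ct = geometry_ct,
                 lesions = lesions, background_suv = background_suv,
                 liver = liver, psf_fwhm_mm = psf_fwhm_mm,
                 noise_sd_suv = noise_sd_suv, gtv_error = gtv_error,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom grid geometries
#'
#' A 48^3 PET grid at 4 mm isotropic and a 96^3 CT grid at 2 mm isotropic,
#' both centred on the world origin (LPS mm).
#'
#' @return An \code{image_geometry}.
#' @export
default_pet_geometry <- function() {
  image_geometry(c(48, 48, 48), c(4, 4, 4), origin = rep(-47 * 4 / 2, 3))
}

#' @rdname default_pet_geometry
#' @export
default_ct_geometry <- function() {
  image_geometry(c(96, 96, 96), c(2, 2, 2), origin = rep(-95 * 2 / 2, 3))
}

# normalized ellipsoid radius (<= 1 inside) for all voxel centres
lesion_support <- function(geometry, lesion) {
  centres <- voxel_centre_grid(geometry)
  rho2 <- ((centres[, 1] - lesion$centre[1]) / lesion$semiaxes[1])^2 +
    ((centres[, 2] - lesion$centre[2]) / lesion$semiaxes[2])^2 +
    ((centres[, 3] - lesion$centre[3]) / lesion$semiaxes[3])^2
  array(rho2 <= 1, dim = geometry$shape)
}

# separable Gaussian blur with replicate-edge padding; fwhm in mm
gaussian_blur3d <- function(values, spacing, fwhm_mm) {
  if (fwhm_mm == 0) return(values)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    sigma <- sigma_mm / spacing[ax]
    r <- max(1L, ceiling(3 * sigma))
    w <- stats::dnorm(-r:r, sd = sigma)
    w <- w / sum(w)
    n <- dim(values)[ax]
    out <- array(0, dim(values))
    for (off in -r:r) {
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      sl <- switch(ax, values[idx, , , drop = FALSE],
                   values[, idx, , drop = FALSE],
                   values[, , idx, drop = FALSE])
      out <- out + w[off + r + 1] * sl
    }
    values <- out
  }
  values
}

# smooth zero-mean random field: iid N(0, amplitude) on a coarse knot grid,
# trilinearly interpolated to the full grid (low-frequency by construction)
smooth_random_field <- function(shape, amplitude, knots = 5) {
  if (amplitude == 0) return(array(0, shape))
  coarse <- array(stats::rnorm(knots^3, 0, amplitude), rep(knots, 3))
  idx <- all_voxel_indices(shape)
  u <- sweep(idx, 2, pmax(shape - 1L, 1L), `/`) * (knots - 1)
  i0 <- pmin(floor(u), knots - 2)
  fr <- u - i0
  val <- numeric(nrow(idx))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    lin <- (i0[, 1] + dx) + knots * ((i0[, 2] + dy) + knots * (i0[, 3] + dz))
    val <- val + wgt * coarse[lin + 1]
  }
  array(val, shape)
}

# apply a signed offset field (mm; positive dilates) to a binary mask.
# The signed distance of a voxel centre to the mask surface is estimated as
# its distance to the nearest boundary voxel centre minus half the voxel
# spacing (the surface runs midway between inside and outside centres), so
# sub-voxel offsets act on the correct mm scale; computed only inside a band
# wide enough for the largest offset; voxels outside the band keep their
# original membership. offset 0 returns the mask unchanged.
offset_mask <- function(mask, spacing, offset_mm) {
  if (is.null(dim(offset_mm)))
    offset_mm <- array(offset_mm, dim(mask))
  max_off <- max(abs(offset_mm))
  if (max_off == 0) return(mask)
  inv <- !mask
  if (!any(mask) || !any(inv)) return(mask)
  touches <- function(a) {
    out <- array(FALSE, dim(a))
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      d <- integer(3); d[ax] <- s
      out <- out | shift_logical(a, d)
    }
    out
  }
  b_in <- mask & touches(inv)    # boundary voxels inside the mask
  b_out <- inv & touches(mask)   # boundary voxels outside the mask
  band <- b_in | b_out
  k <- ceiling(max_off / min(spacing)) + 1L
  for (i in seq_len(k)) band <- band | touches(band)
  cand <- which(band)
  coord <- function(lin) {
    sweep(all_voxel_indices(dim(mask))[lin, , drop = FALSE], 2, spacing, `*`)
  }
  dist_to <- function(pts, ref) {
    d2 <- outer(pts[, 1], ref[, 1], `-`)^2 +
      outer(pts[, 2], ref[, 2], `-`)^2 +
      outer(pts[, 3], ref[, 3], `-`)^2
    sqrt(apply(d2, 1, min))
  }
  pts <- coord(cand)
  in_cand <- mask[cand]
  half <- mean(spacing) / 2
  sdist <- numeric(length(cand))
  if (any(in_cand))
    sdist[in_cand] <- -pmax(dist_to(pts[in_cand, , drop = FALSE],
                                    coord(which(b_out))) - half, 0)
  if (any(!in_cand))
    sdist[!in_cand] <- pmax(dist_to(pts[!in_cand, , drop = FALSE],
                                    coord(which(b_in))) - half, 1e-9)
  out <- mask
  out[cand] <- sdist <= offset_mm[cand]
  out
}

#' Generate one synthetic PET/CT phantom
#'
#' Paints the lesions (peak SUV) and the hepatic compartment (mean SUV) over
#' the soft-tissue background on the PET grid, applies the Gaussian PSF blur,
#' adds seeded Gaussian noise and clips at zero; liver voxels are then
#' assigned their seeded Gaussian field so the hepatic compartment realises
#' the stated measured statistics exactly. The ground-truth mask is the
#' pre-blur lesion support on the PET grid. The simulated manual GTV is the
#' truth contour offset by \code{gtv_error$offset_mm} plus a smooth random
#' boundary warp, back-projected onto the CT grid (with zero error it equals
#' the back-projected truth exactly). A schematic HU volume is painted on the
#' CT grid.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return An object of class \code{phantom_output}: list with \code{pet}
#'   (\code{suv_image}), \code{ct} (list of geometry + HU array),
#'   \code{truth_mask} (PET grid), \code{gtv_mask} (CT grid),
#'   \code{gtv_mask_pet} (PET grid), \code{liver_voi} (\code{voi_sphere}),
#'   \code{suv_max_true} and \code{spec} (provenance echo).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gp <- spec$geometry_pet
  extent_lo <- voxel_to_world(gp, c(0, 0, 0)) - gp$spacing / 2
  extent_hi <- voxel_to_world(gp, gp$shape - 1) + gp$spacing / 2
  for (l in spec$lesions) {
    if (any(l$centre - l$semiaxes < extent_lo) ||
        any(l$centre + l$semiaxes > extent_hi))
      stop("lesion extends outside the PET grid")
    if (sqrt(sum((l$centre - spec$liver$centre)^2)) <=
        max(l$semiaxes) + spec$liver$radius_mm)
      stop("lesion overlaps the hepatic compartment")
  }
  liver_sphere <- voi_sphere(spec$liver$centre,
                             4 / 3 * pi * (spec$liver$radius_mm / 10)^3)
  liver_mask <- rasterize_sphere(liver_sphere, gp, "liver")$voxels
  if (!any(liver_mask)) stop("hepatic compartment lies outside the PET grid")

  set.seed(spec$seed)
  truth <- array(FALSE, gp$shape)
  ideal <- array(spec$background_suv, gp$shape)
  for (l in spec$lesions) {
    sup <- lesion_support(gp, l)
    truth <- truth | sup
    ideal[sup] <- l$peak_suv
  }
  if (!any(truth)) stop("no lesion covers any PET voxel centre")
  ideal[liver_mask] <- spec$liver$mean_suv

  vals <- gaussian_blur3d(ideal, gp$spacing, spec$psf_fwhm_mm)
  if (spec$noise_sd_suv > 0)
    vals <- vals + array(stats::rnorm(prod(gp$shape), 0, spec$noise_sd_suv),
                         gp$shape)
  vals <- pmax(vals, 0)
  n_liver <- sum(liver_mask)
  vals[liver_mask] <- pmax(
    stats::rnorm(n_liver, spec$liver$mean_suv, spec$liver$sd_suv), 0)
  pet <- suv_image(gp, vals)

  peak <- max(vapply(spec$lesions, `[[`, numeric(1), "peak_suv"))
  stopifnot(max(vals[truth]) <= peak + 5 * spec$noise_sd_suv + 1e-9)

  offset_field <- spec$gtv_error$offset_mm +
    smooth_random_field(gp$shape, spec$gtv_error$warp_amplitude_mm,
                        spec$gtv_error$warp_knots)
  gtv_pet_vox <- offset_mask(truth, gp$spacing, offset_field)
  if (!any(gtv_pet_vox))
    stop("GTV error model removed the whole contour; reduce erosion/warp")
  truth_mask <- structure_mask(gp, truth, "truth")
  gtv_mask_pet <- structure_mask(gp, gtv_pet_vox, "GTV")
  gtv_mask <- resample_mask(gtv_mask_pet, spec$geometry_ct)

  truth_ct <- resample_mask(truth_mask, spec$geometry_ct)
  liver_ct <- resample_mask(structure_mask(gp, liver_mask, "liver"),
                            spec$geometry_ct)
  hu <- array(40, spec$geometry_ct$shape)  # schematic soft tissue
  hu[liver_ct$voxels] <- 55
  hu[truth_ct$voxels] <- 60

  structure(list(pet = pet,
                 ct = list(geometry = spec$geometry_ct, values = hu),
                 truth_mask = truth_mask, gtv_mask = gtv_mask,
                 gtv_mask_pet = gtv_mask_pet,
                 liver_voi = voi_sphere(spec$liver$centre, spec$liver$voi_ml),
                 suv_max_true = peak, spec = spec),
            class = "phantom_output")
}

#' @export
print.phantom_output <- function(x, ...) {
  cat(sprintf(
    "phantom: truth %.1f ml (PET grid), GTV %.1f ml (CT grid), peak SUV %.1f\n",
    volume_ml(x$truth_mask), volume_ml(x$gtv_mask), x$suv_max_true))
  invisible(x)
}

# largest-remainder allocation of n items to proportions; ties and the n=1
# case resolve toward the larger proportion (earlier index on exact ties)
allocate_sites <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(-(raw - counts), -proportions, seq_along(proportions))
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

site_lesion_preset <- function(site) {
  switch(site,
    lung = {                              # medium sphere
      r <- stats::runif(1, 12, 22)
      c(r, r, r)
    },
    oesophageal = {                       # small elongated ellipsoid
      a <- stats::runif(1, 7, 10)
      c(a, a, stats::runif(1, 20, 32))
    },
    pelvic = stats::runif(3, 15, 28),     # large irregular ellipsoid
    stop("unknown site: ", site))
}

#' Generate a synthetic patient cohort
#'
#' Generates \code{n} phantoms with site labels allocated deterministically
#' by largest remainder from \code{site_mix} (so n = 20 with mix
#' 0.40/0.25/0.35 gives 8 lung, 5 oesophageal and 7 pelvic). Lesion shapes
#' follow per-site presets (lung: medium spheres; oesophageal: small
#' elongated ellipsoids; pelvic: large irregular ellipsoids); peak SUVs are
#' drawn log-normally around a median of 9.2 and clamped to [3.1, 18.2];
#' simulated manual GTVs are dilated by a per-patient offset (default
#' U(1, 4) mm, emulating systematically generous manual contours) plus a
#' 2 mm smooth boundary warp. All randomness derives from \code{seed}.
#'
#' @param n number of patients (>= 1).
#' @param site_mix named proportions for sites lung/oesophageal/pelvic;
#'   must sum to 1.
#' @param seed integer RNG seed.
#' @param gtv_offset_mm optional fixed GTV contour offset in mm (positive
#'   dilation) overriding the per-patient U(1, 4) mm draw; use e.g. 5 for a
#'   cohort with systematically oversized manual contours.
#' @param gtv_warp_mm amplitude of the smooth GTV boundary warp (default 2).
#' @param geometry_pet,geometry_ct grids passed to every phantom.
#' @return List of length \code{n}; each element has \code{phantom}
#'   (\code{phantom_output}) and \code{site}.
#' @export
generate_cohort <- function(n,
                            site_mix = c(lung = 0.40, oesophageal = 0.25,
                                         pelvic = 0.35),
                            seed = 1L, gtv_offset_mm = NULL,
                            gtv_warp_mm = 2,
                            geometry_pet = default_pet_geometry(),
                            geometry_ct = default_ct_geometry()) {
  if (n < 1) stop("n must be >= 1")
  if (length(site_mix) != 3 || abs(sum(site_mix) - 1) > 1e-8)
    stop("site_mix must be 3 proportions summing to 1")
  sites_all <- c("lung", "oesophageal", "pelvic")
  if (is.null(names(site_mix))) names(site_mix) <- sites_all
  counts <- allocate_sites(n, as.numeric(site_mix[sites_all]))
  site_seq <- rep(sites_all, counts)
  set.seed(seed)
  phantom_seeds <- sample.int(2^31 - 2, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    site <- site_seq[i]
    semi <- site_lesion_preset(site)
    peak <- min(max(exp(stats::rnorm(1, log(9.2), 0.45)), 3.1), 18.2)
    centre <- c(25, 25, 15) + stats::runif(3, -8, 8)
    offset <- if (is.null(gtv_offset_mm)) stats::runif(1, 1, 4)
              else gtv_offset_mm
    spec <- phantom_spec(
      geometry_pet = geometry_pet, geometry_ct = geometry_ct,
      lesions = list(list(centre = centre, semiaxes = semi,
                          peak_suv = peak)),
      gtv_error = list(offset_mm = offset, warp_amplitude_mm = gtv_warp_mm,
                       warp_knots = 5),
      seed = phantom_seeds[i])
    out[[i]] <- list(phantom = generate_phantom(spec), site = site)
  }
  out
}
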