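#' Segmentation recipe
#'
#' Describes one automatic BTV delineation algorithm: either a fixed
#' percentage of the lesion SUVmax (the 38/42/47/50 percent family) or the
#' PERCIST-style background-adaptive absolute threshold
#' \code{liver mean + sd_multiplier x liver SD} measured in a hepatic
#' reference VOI.
#'
#' @param mode \code{"percent_of_max"} or \code{"percist_tlg"}.
#' @param percent fraction of SUVmax in (0, 1]; required for
#'   \code{percent_of_max}.
#' @param sd_multiplier non-negative multiplier of the liver SD
#'   (default 3); used in \code{percist_tlg} mode.
#' @param background_voi a \code{\link{voi_sphere}} for the hepatic reference
#'   region (conventionally 15 ml); required for \code{percist_tlg}.
#' @param label optional label for the resulting masks; defaults to
#'   \code{"BTV_SUV<pct>"} or \code{"BTV_PERCIST"}.
#' @return An object of class \code{threshold_spec}.
#' @export
threshold_spec <- function(mode = c("percent_of_max", "percist_tlg"),
                           percent = NULL, sd_multiplier = 3,
                           background_voi = NULL, label = NULL) {
  mode <- match.arg(mode)
  if (mode == "percent_of_max") {
    if (is.null(percent) || !is.finite(percent) || percent <= 0 || percent > 1)
      stop("percent must be in (0, 1] for percent_of_max mode")
    if (is.null(label)) label <- sprintf("BTV_SUV%d", round(100 * percent))
  } else {
    if (!is.finite(sd_multiplier) || sd_multiplier < 0)
      stop("sd_multiplier must be >= 0")
    if (is.null(background_voi) || !inherits(background_voi, "voi_sphere"))
      stop("percist_tlg mode requires a voi_sphere background_voi")
    if (is.null(label)) label <- "BTV_PERCIST"
  }
  structure(list(mode = mode, percent = percent,
                 sd_multiplier = sd_multiplier,
                 background_voi = background_voi, label = label),
            class = "threshold_spec")
}

#' The default five-algorithm threshold set
#'
#' The four fixed percentages 38, 42, 47 and 50 percent of SUVmax plus the
#' PERCIST-style threshold (liver mean + 3 SD in a 15 ml hepatic VOI).
#'
#' @param liver_centre world coordinates (mm) of the hepatic reference VOI.
#' @param liver_volume_ml hepatic VOI volume, default 15 ml.
#' @param sd_multiplier liver SD multiplier, default 3.
#' @return Named list of five \code{threshold_spec}s
#'   (\code{SUV38, SUV42, SUV47, SUV50, PERCIST}).
#' @export
default_threshold_set <- function(liver_centre, liver_volume_ml = 15,
                                  sd_multiplier = 3) {
  specs <- lapply(c(0.38, 0.42, 0.47, 0.50), function(p)
    threshold_spec("percent_of_max", percent = p))
  specs <- c(specs, list(threshold_spec(
    "percist_tlg", sd_multiplier = sd_multiplier,
    background_voi = voi_sphere(liver_centre, liver_volume_ml))))
  names(specs) <- c("SUV38", "SUV42", "SUV47", "SUV50", "PERCIST")
  specs
}

#' Lesion SUVmax and seed voxel
#'
#' Maximum SUV inside a search region together with the (1-based) array index
#' of one attaining voxel. Ties are broken by lowest lexicographic voxel
#' index, so the seed is deterministic.
#'
#' @param pet an \code{suv_image}.
#' @param region a \code{structure_mask} restricting the search (nonempty, on
#'   the PET grid).
#' @return List with \code{suv_max} and \code{seed} (integer (i,j,k),
#'   1-based).
#' @export
lesion_suv_max <- function(pet, region) {
  stopifnot(inherits(pet, "suv_image"), inherits(region, "structure_mask"))
  if (!geometry_equal(pet$geometry, region$geometry))
    stop("region must be on the PET grid")
  if (!any(region$voxels))
    stop("search region is empty")
  vals <- pet$values
  vals[!region$voxels] <- -Inf
  mx <- max(vals)
  cand <- which(vals == mx, arr.ind = TRUE)
  ord <- order(cand[, 1], cand[, 2], cand[, 3])
  list(suv_max = mx, seed = as.integer(cand[ord[1], ]))
}

# shift a logical array by integer offset d, filling with FALSE
shift_logical <- function(a, d) {
  dm <- dim(a)
  out <- array(FALSE, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      if (d[ax] >= dm[ax]) return(out)
      src[[ax]] <- 1:(dm[ax] - d[ax]); dst[[ax]] <- (1 + d[ax]):dm[ax]
    } else {
      if (-d[ax] >= dm[ax]) return(out)
      src[[ax]] <- (1 - d[ax]):dm[ax]; dst[[ax]] <- 1:(dm[ax] + d[ax])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

neighbour_offsets <- function(connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  ord <- abs(g$di) + abs(g$dj) + abs(g$dk)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(g)))
  as.matrix(g[keep, ])
}

# connected component of `candidates` containing voxel `seed` (1-based ijk),
# by iterative frontier dilation
grow_component <- function(candidates, seed, connectivity = 26) {
  stopifnot(candidates[seed[1], seed[2], seed[3]])
  offs <- neighbour_offsets(connectivity)
  comp <- array(FALSE, dim(candidates))
  comp[seed[1], seed[2], seed[3]] <- TRUE
  repeat {
    grown <- comp
    for (r in seq_len(nrow(offs)))
      grown <- grown | shift_logical(comp, offs[r, ])
    grown <- grown & candidates
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}

#' Percentage-of-SUVmax BTV segmentation
#'
#' Thresholds the PET at \code{percent x SUVmax(region)} (inclusive, so the
#' seed always qualifies) and keeps the connected component containing the
#' SUVmax seed voxel — region growing from the maximum.
#'
#' @param pet an \code{suv_image}.
#' @param region nonempty \code{structure_mask} search region on the PET grid.
#' @param spec a \code{threshold_spec} with mode \code{percent_of_max}.
#' @param connectivity 6, 18 or 26 (3-D neighbourhood for region growing).
#' @return A \code{structure_mask} on the PET grid, with attributes
#'   \code{threshold} (absolute SUV) and \code{suv_max}.
#' @export
percent_threshold_btv <- function(pet, region, spec, connectivity = 26) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (spec$mode != "percent_of_max")
    stop("spec mode must be percent_of_max")
  mx <- lesion_suv_max(pet, region)
  thr <- spec$percent * mx$suv_max
  candidates <- (pet$values >= thr) & region$voxels
  stopifnot(candidates[mx$seed[1], mx$seed[2], mx$seed[3]])
  comp <- grow_component(candidates, mx$seed, connectivity)
  out <- structure_mask(pet$geometry, comp, spec$label)
  attr(out, "threshold") <- thr
  attr(out, "suv_max") <- mx$suv_max
  out
}

#' Hepatic background statistics
#'
#' Mean and sample SD (n-1 denominator) of the SUV over the voxels of a
#' spherical reference VOI, conventionally 15 ml in the right hepatic lobe.
#'
#' @param pet an \code{suv_image}.
#' @param voi a \code{voi_sphere}.
#' @return List with \code{mean_suv}, \code{sd_suv}, \code{n_voxels}.
#' @export
background_stats <- function(pet, voi) {
  stopifnot(inherits(pet, "suv_image"), inherits(voi, "voi_sphere"))
  m <- rasterize_sphere(voi, pet$geometry)
  n <- sum(m$voxels)
  if (n < 2)
    stop("background VOI covers fewer than 2 voxels inside the grid")
  vals <- pet$values[m$voxels]
  list(mean_suv = mean(vals), sd_suv = stats::sd(vals), n_voxels = n)
}

#' PERCIST-style absolute threshold
#'
#' @param stats background statistics as returned by
#'   \code{\link{background_stats}}.
#' @param sd_multiplier liver SD multiplier (default 3).
#' @return Absolute SUV threshold \code{mean + sd_multiplier * sd}.
#' @export
percist_threshold <- function(stats, sd_multiplier = 3) {
  stats$mean_suv + sd_multiplier * stats$sd_suv
}

#' PERCIST-style background-adaptive BTV segmentation
#'
#' The lesion boundary is the absolute SUV level
#' \code{liver mean + sd_multiplier x liver SD}, with liver statistics taken
#' from the spec's hepatic background VOI; the mask is the connected
#' component of supra-threshold voxels containing the region SUVmax seed.
#' A lesion whose SUVmax lies below the background threshold gives an empty
#' mask flagged \code{"lesion not above background"} (a PET-negative lesion),
#' never an error.
#'
#' @inheritParams percent_threshold_btv
#' @param spec a \code{threshold_spec} with mode \code{percist_tlg}.
#' @return A \code{structure_mask} with attributes \code{threshold},
#'   \code{suv_max}, \code{background} (the liver statistics) and, when the
#'   lesion is PET-negative, \code{flag = "lesion not above background"}.
#' @export
percist_tlg_btv <- function(pet, region, spec, connectivity = 26) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (spec$mode != "percist_tlg")
    stop("spec mode must be percist_tlg")
  bg <- background_stats(pet, spec$background_voi)
  thr <- percist_threshold(bg, spec$sd_multiplier)
  mx <- lesion_suv_max(pet, region)
  if (mx$suv_max < thr) {
    out <- structure_mask(pet$geometry, array(FALSE, pet$geometry$shape),
                          spec$label)
    attr(out, "flag") <- "lesion not above background"
  } else {
    candidates <- (pet$values >= thr) & region$voxels
    comp <- grow_component(candidates, mx$seed, connectivity)
    out <- structure_mask(pet$geometry, comp, spec$label)
  }
  attr(out, "threshold") <- thr
  attr(out, "suv_max") <- mx$suv_max
  attr(out, "background") <- bg
  out
}

#' Segment one lesion with any threshold recipe
#'
#' Dispatches to \code{\link{percent_threshold_btv}} or
#' \code{\link{percist_tlg_btv}} according to the spec mode.
#'
#' @inheritParams percent_threshold_btv
#' @param spec a \code{threshold_spec}.
#' @return A \code{structure_mask}.
#' @export
segment_lesion <- function(pet, region, spec, connectivity = 26) {
  if (spec$mode == "percent_of_max")
    percent_threshold_btv(pet, region, spec, connectivity)
  else
    percist_tlg_btv(pet, region, spec, connectivity)
}

#' Mask out avoided structures from a BTV
#'
#' Removes voxels belonging to adjacent high-physiologic-uptake structures
#' (heart, bladder, brain, ...) from a BTV: \code{btv AND NOT avoid}.
#'
#' @param btv,avoid \code{structure_mask}s on the same geometry.
#' @return A \code{structure_mask}; volume never increases.
#' @export
exclude_structures <- function(btv, avoid) {
  stopifnot(inherits(btv, "structure_mask"), inherits(avoid, "structure_mask"))
  if (!geometry_equal(btv$geometry, avoid$geometry))
    stop("btv and avoid masks must share the same geometry")
  structure_mask(btv$geometry, btv$voxels & !avoid$voxels, btv$label)
}

#' Bounding-box search region around a mask
#'
#' Expands the bounding box of a mask by a margin (mm, per axis) and returns
#' it as a search-region mask on the same grid. Used to emulate the
#' interactive placement of a generous lesion VOI.
#'
#' @param mask a nonempty \code{structure_mask}.
#' @param margin_mm margin added on each side, mm.
#' @return A \code{structure_mask} labelled \code{"search_region"}.
#' @export
bounding_region <- function(mask, margin_mm = 20) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!any(mask$voxels)) stop("mask is empty")
  idx <- which(mask$voxels, arr.ind = TRUE)
  marg <- ceiling(margin_mm / mask$geometry$spacing)
  lo <- pmax(apply(idx, 2, min) - marg, 1)
  hi <- pmin(apply(idx, 2, max) + marg, mask$geometry$shape)
  box <- array(FALSE, mask$geometry$shape)
  box[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  structure_mask(mask$geometry, box, "search_region")
}
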