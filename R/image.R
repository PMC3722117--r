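#' SUV image
#'
#' A 3-D scalar field of standardized uptake values (body-weight convention,
#' dimensionless g/ml) on a stated grid geometry.
#'
#' @param geometry an \code{image_geometry}.
#' @param values numeric 3-D array matching \code{geometry$shape}; finite and
#'   non-negative.
#' @return An object of class \code{suv_image}.
#' @export
suv_image <- function(geometry, values) {
  stopifnot(inherits(geometry, "image_geometry"))
  values <- as.array(values)
  if (!all(dim(values) == geometry$shape))
    stop("values dimensions do not match geometry shape")
  if (any(!is.finite(values)))
    stop("SUV values must be finite")
  if (any(values < 0))
    stop("SUV values must be non-negative")
  structure(list(geometry = geometry, values = values), class = "suv_image")
}

#' @export
print.suv_image <- function(x, ...) {
  cat("suv_image on", paste(x$geometry$shape, collapse = " x "),
      "grid; SUV range", paste(signif(range(x$values), 4), collapse = " - "),
      "\n")
  invisible(x)
}

#' Binary structure mask
#'
#' A binary voxel mask (GTV, BTV, VOI, ground truth, ...) on a stated grid.
#'
#' @param geometry an \code{image_geometry}.
#' @param voxels logical 3-D array matching \code{geometry$shape}.
#' @param label free-text structure name, e.g. \code{"GTV"}, \code{"BTV_SUV38"}.
#' @return An object of class \code{structure_mask}.
#' @export
structure_mask <- function(geometry, voxels, label = "mask") {
  stopifnot(inherits(geometry, "image_geometry"))
  voxels <- as.array(voxels)
  if (!all(dim(voxels) == geometry$shape))
    stop("mask dimensions do not match geometry shape")
  if (any(is.na(voxels)))
    stop("mask must not contain NA")
  storage.mode(voxels) <- "logical"
  structure(list(geometry = geometry, voxels = voxels,
                 label = as.character(label)[1]),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("structure_mask '%s': %d voxels, %.2f ml\n", x$label,
              sum(x$voxels), volume_ml(x)))
  invisible(x)
}

#' Mask volume in ml
#'
#' Voxel-counting volume: number of true voxels times the voxel volume.
#' An empty mask has volume 0.
#'
#' @param mask a \code{structure_mask}.
#' @return Volume in ml.
#' @export
volume_ml <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$voxels) * voxel_volume_ml(mask$geometry)
}

#' Spherical volume of interest
#'
#' A sphere specified by its world centre and target volume, used e.g. for the
#' 15 ml hepatic reference VOI of the PERCIST-style threshold.
#'
#' @param centre world coordinates of the sphere centre, mm.
#' @param volume_ml target volume in ml; the radius follows as
#'   \eqn{r = (3V/4\pi)^{1/3}}.
#' @return An object of class \code{voi_sphere}.
#' @export
voi_sphere <- function(centre, volume_ml) {
  centre <- as.numeric(centre)
  if (length(centre) != 3L || any(!is.finite(centre)))
    stop("centre must be 3 finite world coordinates (mm)")
  if (!is.finite(volume_ml) || volume_ml <= 0)
    stop("volume_ml must be strictly positive")
  structure(list(centre = centre, volume_ml = as.numeric(volume_ml)),
            class = "voi_sphere")
}

#' Radius of a spherical VOI in mm
#'
#' @param sphere a \code{voi_sphere}.
#' @return Radius in mm (volume in ml = cm^3, so r_cm = (3V/4pi)^(1/3)).
#' @export
sphere_radius_mm <- function(sphere) {
  stopifnot(inherits(sphere, "voi_sphere"))
  (3 * sphere$volume_ml / (4 * pi))^(1 / 3) * 10
}

#' Convert an activity concentration map to SUV
#'
#' Body-weight SUV normalization:
#' \deqn{SUV = activity[kBq/ml] \times weight[kg] / dose[MBq]}
#' (equivalently activity divided by injected dose per gram of body weight,
#' assuming unit tissue density). The geometry is unchanged.
#'
#' @param activity numeric 3-D array of activity concentration, kBq/ml.
#' @param geometry an \code{image_geometry} for the activity map.
#' @param injected_dose_mbq injected tracer dose, MBq, > 0.
#' @param body_weight_kg body weight, kg, > 0.
#' @return An \code{suv_image}.
#' @export
suv_from_activity <- function(activity, geometry, injected_dose_mbq,
                              body_weight_kg) {
  if (!is.finite(injected_dose_mbq) || injected_dose_mbq <= 0)
    stop("injected_dose_mbq must be strictly positive")
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("body_weight_kg must be strictly positive")
  activity <- as.array(activity)
  if (any(!is.finite(activity)) || any(activity < 0))
    stop("activity must be finite and non-negative")
  suv_image(geometry, activity * body_weight_kg / injected_dose_mbq)
}

#' Rasterize a spherical VOI onto a grid
#'
#' A voxel is inside iff its centre lies within the sphere radius of the
#' centre (centre-in / centre-out voxel model, boundary inclusive).
#'
#' @param sphere a \code{voi_sphere}.
#' @param geometry target \code{image_geometry}.
#' @param label label for the resulting mask.
#' @return A \code{structure_mask}; empty with a warning if the sphere
#'   contains no voxel centre.
#' @export
rasterize_sphere <- function(sphere, geometry, label = "VOI") {
  stopifnot(inherits(sphere, "voi_sphere"))
  r <- sphere_radius_mm(sphere)
  centres <- voxel_centre_grid(geometry)
  d2 <- (centres[, 1] - sphere$centre[1])^2 +
    (centres[, 2] - sphere$centre[2])^2 +
    (centres[, 3] - sphere$centre[3])^2
  inside <- array(d2 <= r^2, dim = geometry$shape)
  if (!any(inside))
    warning("sphere contains no voxel centre; returning empty mask")
  structure_mask(geometry, inside, label)
}

#' Resample a binary mask onto another grid (nearest neighbour)
#'
#' Each target voxel takes the value of the source voxel whose centre is
#' nearest to the target voxel centre in world coordinates; target voxels
#' mapping outside the source grid extent become false. Nearest-neighbour
#' sampling preserves binarity and is the back-projection used to carry
#' PET-defined volumes onto the planning-CT grid.
#'
#' @param mask source \code{structure_mask}.
#' @param target target \code{image_geometry}.
#' @return A \code{structure_mask} on \code{target}. If the grids' world
#'   extents do not overlap at all, an all-false mask with a warning.
#' @export
resample_mask <- function(mask, target) {
  stopifnot(inherits(mask, "structure_mask"),
            inherits(target, "image_geometry"))
  if (geometry_equal(mask$geometry, target))
    return(structure_mask(target, mask$voxels, mask$label))
  # axis-aligned grids resample separably (per-axis index lookup)
  if (max(abs(mask$geometry$direction - diag(3))) < 1e-12 &&
      max(abs(target$direction - diag(3))) < 1e-12) {
    src_shape <- mask$geometry$shape
    axmap <- vector("list", 3L)
    any_valid <- TRUE
    for (ax in 1:3) {
      world <- target$origin[ax] +
        (seq_len(target$shape[ax]) - 1) * target$spacing[ax]
      idx <- round_half_up((world - mask$geometry$origin[ax]) /
                             mask$geometry$spacing[ax])
      valid <- idx >= 0 & idx < src_shape[ax]
      if (!any(valid)) any_valid <- FALSE
      idx[!valid] <- 0L
      axmap[[ax]] <- list(idx = idx + 1L, valid = valid)
    }
    if (!any_valid) {
      warning("source and target grids do not overlap; returning empty mask")
      return(structure_mask(target, array(FALSE, target$shape), mask$label))
    }
    out <- mask$voxels[axmap[[1]]$idx, axmap[[2]]$idx, axmap[[3]]$idx,
                       drop = FALSE]
    out[!axmap[[1]]$valid, , ] <- FALSE
    out[, !axmap[[2]]$valid, ] <- FALSE
    out[, , !axmap[[3]]$valid] <- FALSE
    return(structure_mask(target, out, mask$label))
  }
  centres <- voxel_centre_grid(target)
  cont <- world_to_voxel(mask$geometry, centres)
  idx <- round_half_up(cont)
  src_shape <- mask$geometry$shape
  valid <- idx[, 1] >= 0 & idx[, 1] < src_shape[1] &
    idx[, 2] >= 0 & idx[, 2] < src_shape[2] &
    idx[, 3] >= 0 & idx[, 3] < src_shape[3]
  out <- logical(nrow(idx))
  if (!any(valid)) {
    warning("source and target grids do not overlap; returning empty mask")
  } else {
    lin <- idx[valid, 1] + src_shape[1] * (idx[valid, 2] +
                                             src_shape[2] * idx[valid, 3])
    out[valid] <- mask$voxels[lin + 1]
  }
  structure_mask(target, array(out, dim = target$shape), mask$label)
}
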