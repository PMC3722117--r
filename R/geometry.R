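#' Voxel grid geometry
#'
#' Describes the geometry of a 3-D voxel grid: voxel counts, voxel spacing in
#' mm, the world position (mm, LPS convention) of the centre of voxel
#' \code{(0,0,0)}, and an orthonormal direction cosine matrix. Voxel indices
#' are 0-based throughout the world-coordinate mapping; a voxel is represented
#' by its centre.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing numeric vector of length 3, mm per voxel, all positive.
#' @param origin numeric vector of length 3, world coordinates (mm) of the
#'   centre of voxel (0,0,0).
#' @param direction 3x3 orthonormal direction cosine matrix (columns are the
#'   world directions of the voxel axes). Defaults to identity.
#' @return An object of class \code{image_geometry}.
#' @export
image_geometry <- function(shape, spacing, origin = c(0, 0, 0),
                           direction = diag(3)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be 3 positive integers")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  if (!all(dim(direction) == c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction must be a 3x3 orthonormal matrix (tolerance 1e-6)")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image_geometry")
}

#' @export
print.image_geometry <- function(x, ...) {
  cat("image_geometry:", paste(x$shape, collapse = " x "),
      "voxels,", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  cat("  origin (mm):", paste(signif(x$origin, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Volume of one voxel in ml
#'
#' @param geometry an \code{image_geometry}.
#' @return Voxel volume in ml (= cm^3): product of spacings in mm / 1000.
#' @export
voxel_volume_ml <- function(geometry) {
  stopifnot(inherits(geometry, "image_geometry"))
  prod(geometry$spacing) / 1000
}

geometry_equal <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

#' Convert 0-based voxel indices to world coordinates (mm)
#'
#' @param geometry an \code{image_geometry}.
#' @param ijk numeric matrix (n x 3) of 0-based voxel indices (may be
#'   fractional), or a length-3 vector.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(geometry, ijk) {
  ijk <- rbind_coerce(ijk)
  scaled <- sweep(ijk, 2L, geometry$spacing, `*`)
  out <- scaled %*% t(geometry$direction)
  sweep(out, 2L, geometry$origin, `+`)
}

#' Convert world coordinates (mm) to continuous 0-based voxel indices
#'
#' @inheritParams voxel_to_world
#' @param xyz numeric matrix (n x 3) of world coordinates, or length-3 vector.
#' @return n x 3 matrix of continuous 0-based voxel indices.
#' @export
world_to_voxel <- function(geometry, xyz) {
  xyz <- rbind_coerce(xyz)
  centred <- sweep(xyz, 2L, geometry$origin, `-`)
  idx <- centred %*% geometry$direction  # == t(direction) %*% x, row-wise
  sweep(idx, 2L, geometry$spacing, `/`)
}

rbind_coerce <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3L) else
    matrix(as.numeric(x), ncol = 3L, dimnames = NULL,
           nrow = nrow(x), byrow = FALSE)
}

# n x 3 matrix of 0-based indices of every voxel, in column-major array order
all_voxel_indices <- function(shape) {
  cbind(
    rep_len(seq_len(shape[1]) - 1L, prod(shape)),
    rep(rep(seq_len(shape[2]) - 1L, each = shape[1]), times = shape[3]),
    rep(seq_len(shape[3]) - 1L, each = shape[1] * shape[2])
  )
}

# world coordinates of every voxel centre, rows in array (column-major) order
voxel_centre_grid <- function(geometry) {
  voxel_to_world(geometry, all_voxel_indices(geometry$shape))
}

# deterministic half-up rounding (avoids banker's rounding of round())
round_half_up <- function(x) floor(x + 0.5)
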