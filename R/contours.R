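#' Planar contour set for a structure
#'
#' A structure represented as closed planar polygons on axial slices (the
#' DICOM RT structure set representation): per slice, ordered vertex loops in
#' world mm. Polygons are implicitly closed (the first vertex is not
#' repeated); outer boundaries run counter-clockwise in voxel-index space and
#' holes are emitted as separate polygons (even-odd semantics, no keyhole
#' convention).
#'
#' @param name structure name.
#' @param contours list of contours, each a list with \code{slice_k}
#'   (0-based axial voxel index) and \code{points} (n x 3 matrix, world mm).
#' @param geometry reference \code{image_geometry}.
#' @return An object of class \code{contour_set}.
#' @export
contour_set <- function(name, contours, geometry) {
  stopifnot(inherits(geometry, "image_geometry"))
  structure(list(name = as.character(name)[1], contours = contours,
                 geometry = geometry),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("contour_set '%s': %d polygons on %d slices\n", x$name,
              length(x$contours),
              length(unique(vapply(x$contours, `[[`, numeric(1),
                                   "slice_k")))))
  invisible(x)
}

# boundary loops of one binary slice: the polygons follow the voxel edges
# (the 0.5 iso-surface of the binary field under nearest-neighbour
# interpolation), with vertices at voxel corners (half-integer index
# coordinates). Each exposed voxel edge is emitted as a directed segment
# keeping the inside on the left (outer loops CCW in index space); segments
# are stitched into closed loops, and at a corner where two diagonal voxels
# touch the left turn is taken, so loops stay simple and the diagonal
# neighbours end up in separate polygons. Returns a list of m x 2 matrices
# of 0-based continuous (i, j) index coordinates.
slice_contours <- function(slice) {
  nx <- nrow(slice); ny <- ncol(slice)
  idx <- which(slice, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- slice
  from <- to <- NULL
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1] - 1; j <- idx[r, 2] - 1  # 0-based centre
    pi <- idx[r, 1] + 1; pj <- idx[r, 2] + 1  # padded index
    if (!pad[pi - 1, pj])  # left edge, heading -y
      { from <- rbind(from, c(i - 0.5, j + 0.5)); to <- rbind(to, c(i - 0.5, j - 0.5)) }
    if (!pad[pi + 1, pj])  # right edge, heading +y
      { from <- rbind(from, c(i + 0.5, j - 0.5)); to <- rbind(to, c(i + 0.5, j + 0.5)) }
    if (!pad[pi, pj - 1])  # bottom edge, heading +x
      { from <- rbind(from, c(i - 0.5, j - 0.5)); to <- rbind(to, c(i + 0.5, j - 0.5)) }
    if (!pad[pi, pj + 1])  # top edge, heading -x
      { from <- rbind(from, c(i + 0.5, j + 0.5)); to <- rbind(to, c(i - 0.5, j + 0.5)) }
  }
  key <- sprintf("%d_%d", round(2 * from[, 1]), round(2 * from[, 2]))
  starts_at <- split(seq_len(nrow(from)), key)
  used <- logical(nrow(from))
  loops <- list()
  for (s0 in seq_len(nrow(from))) {
    if (used[s0]) next
    pts <- NULL
    cur <- s0
    repeat {
      used[cur] <- TRUE
      pts <- rbind(pts, from[cur, ])
      k <- sprintf("%d_%d", round(2 * to[cur, 1]), round(2 * to[cur, 2]))
      cand <- starts_at[[k]]
      cand <- cand[!used[cand] | cand == s0]
      if (length(cand) > 1) {
        # ambiguous corner: take the left turn relative to travel direction
        d <- to[cur, ] - from[cur, ]
        left <- c(-d[2], d[1])
        dirs <- to[cand, , drop = FALSE] - from[cand, , drop = FALSE]
        cand <- cand[which.max(dirs %*% left)]
      }
      if (length(cand) == 0 || cand[1] == s0) break
      cur <- cand[1]
    }
    loops[[length(loops) + 1L]] <- pts
  }
  loops
}

#' Convert a binary mask to axial boundary contours
#'
#' Extracts, per axial slice, the boundary polygons of the true region at the
#' 0.5 iso-level of the binary field under the voxel-centre convention: the
#' polygons follow the voxel edges, running midway between inside and outside
#' voxel centres (a single voxel yields its square outline). Multiple
#' polygons per slice are allowed; holes become separate polygons.
#'
#' @param mask a \code{structure_mask} on an axially sliced geometry.
#' @return A \code{\link{contour_set}} (empty for an empty mask).
#' @export
mask_to_contours <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  geom <- mask$geometry
  contours <- list()
  for (k in seq_len(geom$shape[3])) {
    sl <- mask$voxels[, , k]
    if (!any(sl)) next
    for (loop in slice_contours(sl)) {
      pts <- voxel_to_world(geom, cbind(loop, k - 1))
      contours[[length(contours) + 1L]] <-
        list(slice_k = k - 1L, points = pts)
    }
  }
  contour_set(mask$label, contours, geom)
}

# flip even-odd parity inside one polygon (continuous 0-based (i,j) coords)
# on an nx x ny grid of integer voxel centres
flip_polygon_parity <- function(parity, poly) {
  nx <- nrow(parity); ny <- ncol(parity)
  m <- nrow(poly)
  for (e in seq_len(m)) {
    x1 <- poly[e, 1]; y1 <- poly[e, 2]
    e2 <- if (e == m) 1L else e + 1L
    x2 <- poly[e2, 1]; y2 <- poly[e2, 2]
    if (y1 == y2) next
    for (j in seq(ceiling(min(y1, y2)), floor(max(y1, y2)))) {
      if ((y1 > j) == (y2 > j)) next
      xint <- x1 + (j - y1) * (x2 - x1) / (y2 - y1)
      imax <- min(ceiling(xint) - 1, nx - 1)
      if (imax < 0 || j < 0 || j > ny - 1) next
      idx <- 1:(imax + 1)
      parity[idx, j + 1] <- !parity[idx, j + 1]
    }
  }
  parity
}

#' Rasterize a contour set onto a grid
#'
#' A voxel becomes true iff its centre lies inside an odd number of its
#' slice's polygons (even-odd rule), so holes emitted as separate polygons
#' are honoured. Mask-to-contours-to-mask round trips are exact under the
#' package's contouring conventions.
#'
#' @param contours a \code{\link{contour_set}}.
#' @param geometry target \code{image_geometry}; contour planes must coincide
#'   with its axial slice planes, otherwise a geometry-mismatch error is
#'   raised.
#' @return A \code{structure_mask}.
#' @export
contours_to_mask <- function(contours, geometry) {
  stopifnot(inherits(contours, "contour_set"),
            inherits(geometry, "image_geometry"))
  vox <- array(FALSE, geometry$shape)
  nx <- geometry$shape[1]; ny <- geometry$shape[2]; nz <- geometry$shape[3]
  by_slice <- list()
  for (cn in contours$contours) {
    idx <- world_to_voxel(geometry, cn$points)
    kk <- idx[, 3]
    if (any(abs(kk - round_half_up(kk[1])) > 0.01))
      stop("geometry mismatch: contour does not lie on an axial slice ",
           "plane of the target geometry")
    k <- round_half_up(kk[1])
    if (k < 0 || k >= nz) {
      warning("contour lies outside the target grid; ignored")
      next
    }
    off <- idx[, 1] < -0.5 | idx[, 1] > nx - 0.5 |
      idx[, 2] < -0.5 | idx[, 2] > ny - 0.5
    if (any(off)) {
      warning("contour vertices outside the target grid were ignored")
      idx <- idx[!off, , drop = FALSE]
      if (nrow(idx) < 3) next
    }
    key <- as.character(k)
    by_slice[[key]] <- c(by_slice[[key]], list(idx[, 1:2, drop = FALSE]))
  }
  for (key in names(by_slice)) {
    parity <- matrix(FALSE, nx, ny)
    for (poly in by_slice[[key]])
      parity <- flip_polygon_parity(parity, poly)
    vox[, , as.integer(key) + 1L] <- parity
  }
  structure_mask(geometry, vox, contours$name)
}

# signed area (shoelace) of a polygon in index coords; > 0 means CCW
polygon_area <- function(poly) {
  m <- nrow(poly)
  nxt <- c(2:m, 1L)
  sum(poly[, 1] * poly[nxt, 2] - poly[nxt, 1] * poly[, 2]) / 2
}

#' Volume of a contour set from slice areas
#'
#' Sums signed polygon areas per slice (so holes subtract) times the slice
#' thickness; a consistency check against voxel-counting volume.
#'
#' @param contours a \code{\link{contour_set}}.
#' @return Volume in ml.
#' @export
contour_volume_ml <- function(contours) {
  stopifnot(inherits(contours, "contour_set"))
  geom <- contours$geometry
  area <- 0
  for (cn in contours$contours) {
    idx <- world_to_voxel(geom, cn$points)
    area <- area + abs_signed_area_mm2(idx[, 1:2, drop = FALSE],
                                       geom$spacing[1:2])
  }
  area * geom$spacing[3] / 1000
}

abs_signed_area_mm2 <- function(poly_idx, spacing_xy) {
  scaled <- sweep(poly_idx, 2, spacing_xy, `*`)
  polygon_area(scaled)  # CCW outer positive, CW hole negative
}
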