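#' Conformity index between two structures
#'
#' Ratio between intersection and conjunction (union) of the two volumes,
#' expressed as a percentage: the Jaccard index x 100. Defined as 0 (with an
#' \code{"both empty"} attribute flag) when both masks are empty.
#'
#' @param a,b \code{structure_mask}s on the same geometry (resample first
#'   otherwise, see \code{\link{resample_mask}}).
#' @return Percentage in [0, 100].
#' @export
conformity_index <- function(a, b) {
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  if (!geometry_equal(a$geometry, b$geometry))
    stop("masks are on different grids; resample_mask() one onto the other first")
  inter <- sum(a$voxels & b$voxels)
  uni <- sum(a$voxels | b$voxels)
  if (uni == 0) {
    out <- 0
    attr(out, "flag") <- "both empty"
    return(out)
  }
  100 * inter / uni
}

#' Inclusion ratios between a GTV and a BTV
#'
#' Both directions of inclusion are reported explicitly:
#' \code{btv_in_gtv_pct} = 100 x |GTV n BTV| / |BTV| (how much of the
#' automatic volume lies inside the manual gold standard) and
#' \code{gtv_in_btv_pct} = 100 x |GTV n BTV| / |GTV|. An empty denominator
#' yields \code{NA} with an \code{"undefined"} flag rather than NaN.
#'
#' @param gtv,btv \code{structure_mask}s on the same geometry.
#' @return List with \code{btv_in_gtv_pct} and \code{gtv_in_btv_pct}.
#' @export
inclusion_ratios <- function(gtv, btv) {
  stopifnot(inherits(gtv, "structure_mask"), inherits(btv, "structure_mask"))
  if (!geometry_equal(gtv$geometry, btv$geometry))
    stop("masks are on different grids; resample_mask() one onto the other first")
  inter <- sum(gtv$voxels & btv$voxels)
  n_btv <- sum(btv$voxels)
  n_gtv <- sum(gtv$voxels)
  out <- list(
    btv_in_gtv_pct = if (n_btv > 0) 100 * inter / n_btv else NA_real_,
    gtv_in_btv_pct = if (n_gtv > 0) 100 * inter / n_gtv else NA_real_
  )
  if (n_btv == 0 || n_gtv == 0) attr(out, "flag") <- "undefined"
  out
}

#' Full overlap report for one GTV/BTV pair
#'
#' Bundles voxel-counting volumes, intersection and union volumes, the
#' conformity index and both inclusion ratios for one pair of structures on a
#' common grid.
#'
#' @param gtv,btv \code{structure_mask}s on the same geometry.
#' @return An object of class \code{overlap_report}: list with
#'   \code{label_a}, \code{label_b}, \code{volume_a_ml}, \code{volume_b_ml},
#'   \code{intersection_ml}, \code{union_ml}, \code{conformity_index_pct},
#'   \code{a_in_b_pct} (|A n B|/|A|), \code{b_in_a_pct} (|A n B|/|B|), where
#'   A is the GTV and B the BTV.
#' @export
compare_pair <- function(gtv, btv) {
  stopifnot(inherits(gtv, "structure_mask"), inherits(btv, "structure_mask"))
  if (!geometry_equal(gtv$geometry, btv$geometry))
    stop("masks are on different grids; resample_mask() one onto the other first")
  vv <- voxel_volume_ml(gtv$geometry)
  inter <- sum(gtv$voxels & btv$voxels)
  uni <- sum(gtv$voxels | btv$voxels)
  incl <- inclusion_ratios(gtv, btv)
  structure(list(
    label_a = gtv$label, label_b = btv$label,
    volume_a_ml = sum(gtv$voxels) * vv,
    volume_b_ml = sum(btv$voxels) * vv,
    intersection_ml = inter * vv,
    union_ml = uni * vv,
    conformity_index_pct = as.numeric(conformity_index(gtv, btv)),
    a_in_b_pct = incl$gtv_in_btv_pct,
    b_in_a_pct = incl$btv_in_gtv_pct
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap %s vs %s:\n", x$label_a, x$label_b))
  cat(sprintf("  volumes %.1f / %.1f ml, intersection %.1f ml, union %.1f ml\n",
              x$volume_a_ml, x$volume_b_ml, x$intersection_ml, x$union_ml))
  cat(sprintf("  conformity index %.1f%%; %s-in-%s %.1f%%, %s-in-%s %.1f%%\n",
              x$conformity_index_pct, x$label_a, x$label_b, x$a_in_b_pct,
              x$label_b, x$label_a, x$b_in_a_pct))
  invisible(x)
}

#' Write an overlap report as JSON
#'
#' @param report an \code{overlap_report}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_overlap_json <- function(report, path) {
  stopifnot(inherits(report, "overlap_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
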