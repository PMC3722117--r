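#' Run the five-algorithm BTV pipeline on one phantom (or patient)
#'
#' For each threshold recipe: segment the lesion on the native PET grid
#' (region growing from the SUVmax seed inside a generous bounding-box search
#' region around the lesion), back-project the BTV onto the planning-CT grid
#' by nearest-neighbour resampling, and compare it against the manual GTV on
#' the CT grid.
#'
#' @param phantom a \code{\link{generate_phantom}} output, or any list with
#'   \code{pet} (\code{suv_image}), \code{gtv_mask} (CT grid),
#'   \code{truth_mask} (PET grid; used only to place the search region) and
#'   \code{liver_voi}.
#' @param thresholds named list of \code{threshold_spec}s; defaults to
#'   \code{\link{default_threshold_set}} centred on the phantom's liver VOI.
#' @param region optional explicit search-region \code{structure_mask} on the
#'   PET grid; defaults to the truth bounding box + \code{region_margin_mm}.
#' @param region_margin_mm search-region margin, mm (default 20).
#' @param connectivity region-growing connectivity (default 26).
#' @return List with \code{reports} (named \code{overlap_report}s, GTV vs
#'   each BTV on the CT grid), \code{btv_ct} and \code{btv_pet} (named mask
#'   lists), \code{suv_max} and \code{region}.
#' @export
run_btv_pipeline <- function(phantom, thresholds = NULL, region = NULL,
                             region_margin_mm = 20, connectivity = 26) {
  pet <- phantom$pet
  gtv <- phantom$gtv_mask
  if (is.null(thresholds))
    thresholds <- default_threshold_set(phantom$liver_voi$centre,
                                        phantom$liver_voi$volume_ml)
  if (is.null(region))
    region <- bounding_region(phantom$truth_mask, region_margin_mm)
  suv_max <- lesion_suv_max(pet, region)$suv_max
  ct_geom <- gtv$geometry
  btv_pet <- btv_ct <- reports <- list()
  for (nm in names(thresholds)) {
    btv <- segment_lesion(pet, region, thresholds[[nm]], connectivity)
    btv_pet[[nm]] <- btv
    btv_ct[[nm]] <- resample_mask(btv, ct_geom)
    reports[[nm]] <- compare_pair(gtv, btv_ct[[nm]])
  }
  list(reports = reports, btv_ct = btv_ct, btv_pet = btv_pet,
       suv_max = suv_max, region = region)
}

#' Run the pipeline over a cohort and assemble the records table
#'
#' Applies \code{\link{run_btv_pipeline}} to every phantom of a
#' \code{\link{generate_cohort}} result and assembles the long-format cohort
#' records (one row per patient x algorithm) ready for
#' \code{\link{summarize_cohort}}.
#'
#' @param cohort list as returned by \code{\link{generate_cohort}}.
#' @param ... passed on to \code{\link{run_btv_pipeline}}.
#' @return A cohort records data.frame (see \code{\link{cohort_records}}).
#' @export
analyze_cohort <- function(cohort, ...) {
  runs <- lapply(cohort, function(p) run_btv_pipeline(p$phantom, ...))
  cohort_records(
    patient_id = sprintf("P%02d", seq_along(cohort)),
    site = vapply(cohort, `[[`, character(1), "site"),
    suv_max = vapply(runs, `[[`, numeric(1), "suv_max"),
    reports = lapply(runs, `[[`, "reports"))
}
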