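#' Sample median
#'
#' Standard sample median (mean of the two central order statistics for even
#' n), via \code{stats::median}; errors on empty input instead of returning
#' NA so cohort summaries fail loudly.
#'
#' @param values nonempty numeric vector.
#' @return The median.
#' @export
cohort_median <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("median of an empty set is undefined")
  if (any(is.na(values))) stop("values must not contain NA")
  stats::median(values)
}

#' Assemble cohort records from per-patient overlap reports
#'
#' Builds the long-format cohort table (one row per patient x algorithm) from
#' per-patient lists of \code{\link{compare_pair}} reports.
#'
#' @param patient_id character vector of patient identifiers.
#' @param site character vector of tumour sites
#'   (\code{"lung"}, \code{"oesophageal"}, \code{"pelvic"}).
#' @param suv_max numeric vector of lesion SUVmax values.
#' @param reports list (one element per patient) of named lists of
#'   \code{overlap_report}s, names = algorithm labels.
#' @return A data.frame with columns \code{patient_id, site, suv_max,
#'   algorithm, gtv_ml, btv_ml, conformity_index_pct, btv_in_gtv_pct,
#'   gtv_in_btv_pct}.
#' @export
cohort_records <- function(patient_id, site, suv_max, reports) {
  stopifnot(length(patient_id) == length(site),
            length(site) == length(suv_max),
            length(suv_max) == length(reports))
  rows <- lapply(seq_along(reports), function(i) {
    reps <- reports[[i]]
    do.call(rbind, lapply(names(reps), function(alg) {
      r <- reps[[alg]]
      data.frame(patient_id = patient_id[i], site = site[i],
                 suv_max = suv_max[i], algorithm = alg,
                 gtv_ml = r$volume_a_ml, btv_ml = r$volume_b_ml,
                 conformity_index_pct = r$conformity_index_pct,
                 btv_in_gtv_pct = r$b_in_a_pct,
                 gtv_in_btv_pct = r$a_in_b_pct,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Cohort summary table
#'
#' Per-algorithm medians and paired Wilcoxon tests of BTV vs GTV volume, for
#' the whole cohort and for each tumour-site subgroup: rows are the
#' algorithms (plus a manual-GTV row), column blocks are
#' cohort / lung / oesophageal / pelvic, each block holding the median volume
#' (ml), the two-sided Wilcoxon p-value of the paired BTV-vs-GTV volume
#' comparison, the median conformity index (%) and the median inclusion
#' ratios (%). No multiple-comparison correction is applied.
#'
#' @param records long-format cohort data.frame as produced by
#'   \code{\link{cohort_records}} (or read with \code{\link{read_cohort_csv}}).
#' @param alpha two-sided significance level for the Wilcoxon tests
#'   (default 0.05).
#' @param sites subgroup order; subgroups of size 0 give NA cells.
#' @return An object of class \code{cohort_summary}: a data.frame with one
#'   row per algorithm (first row \code{GTV}) and, per group \code{g} in
#'   cohort/lung/oesophageal/pelvic, columns \code{<g>_median_ml},
#'   \code{<g>_p_vs_gtv}, \code{<g>_median_ci_pct},
#'   \code{<g>_median_btv_in_gtv_pct}, \code{<g>_median_gtv_in_btv_pct}.
#'   Attribute \code{n_patients} holds per-group patient counts.
#' @export
summarize_cohort <- function(records, alpha = 0.05,
                             sites = c("lung", "oesophageal", "pelvic")) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a nonempty cohort data.frame")
  needed <- c("patient_id", "site", "algorithm", "gtv_ml", "btv_ml",
              "conformity_index_pct", "btv_in_gtv_pct", "gtv_in_btv_pct")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  algorithms <- unique(records$algorithm)
  groups <- c("cohort", sites)
  out <- data.frame(algorithm = c("GTV", algorithms),
                    stringsAsFactors = FALSE)
  n_patients <- integer(length(groups)); names(n_patients) <- groups
  for (g in groups) {
    sub <- if (g == "cohort") records else records[records$site == g, ]
    pat <- unique(sub$patient_id)
    n_patients[g] <- length(pat)
    med_ml <- p_vs <- med_ci <- med_big <- med_gib <-
      rep(NA_real_, nrow(out))
    if (length(pat) > 0) {
      # one GTV volume per patient (repeated across algorithm rows)
      gtv_per_pat <- sub$gtv_ml[match(pat, sub$patient_id)]
      med_ml[1] <- cohort_median(gtv_per_pat)
      for (i in seq_along(algorithms)) {
        a <- sub[sub$algorithm == algorithms[i], ]
        a <- a[match(pat, a$patient_id), ]  # align pairs by patient
        med_ml[i + 1] <- cohort_median(a$btv_ml)
        p_vs[i + 1] <- wilcoxon_signed_rank(a$btv_ml, a$gtv_ml,
                                            alpha = alpha)$p_two_sided
        med_ci[i + 1] <- cohort_median(a$conformity_index_pct)
        med_big[i + 1] <- cohort_median(a$btv_in_gtv_pct)
        med_gib[i + 1] <- cohort_median(a$gtv_in_btv_pct)
      }
    }
    out[[paste0(g, "_median_ml")]] <- med_ml
    out[[paste0(g, "_p_vs_gtv")]] <- p_vs
    out[[paste0(g, "_median_ci_pct")]] <- med_ci
    out[[paste0(g, "_median_btv_in_gtv_pct")]] <- med_big
    out[[paste0(g, "_median_gtv_in_btv_pct")]] <- med_gib
  }
  attr(out, "n_patients") <- n_patients
  attr(out, "alpha") <- alpha
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Render a cohort summary as a text table
#'
#' Formats a \code{\link{summarize_cohort}} result as fixed-width text:
#' algorithm rows, and per group the median volume, the p-value of the paired
#' volume comparison against the GTV, and the median conformity index (one
#' decimal place; small p-values shown as \code{<0.001}).
#'
#' @param summary a \code{cohort_summary}.
#' @return Character vector of table lines, invisibly; also printed.
#' @export
format_cohort_table <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  groups <- sub("_median_ml$", "",
                grep("_median_ml$", names(summary), value = TRUE))
  fmt_p <- function(p) ifelse(is.na(p), "--",
                              ifelse(p < 0.001, "<0.001", sprintf("%.2f", p)))
  fmt_v <- function(v) ifelse(is.na(v), "--", sprintf("%.1f", v))
  header <- sprintf("%-10s", "Volume")
  for (g in groups)
    header <- paste0(header, sprintf(" | %10s %8s %8s",
                                     paste0(g, " [ml]"), "p(GTV)", "CI [%]"))
  lines <- c(header, strrep("-", nchar(header)))
  for (r in seq_len(nrow(summary))) {
    line <- sprintf("%-10s", summary$algorithm[r])
    for (g in groups) {
      line <- paste0(line, sprintf(
        " | %10s %8s %8s",
        fmt_v(summary[[paste0(g, "_median_ml")]][r]),
        if (summary$algorithm[r] == "GTV") "--"
        else fmt_p(summary[[paste0(g, "_p_vs_gtv")]][r]),
        if (summary$algorithm[r] == "GTV") "--"
        else fmt_v(summary[[paste0(g, "_median_ci_pct")]][r])))
    }
    lines <- c(lines, line)
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Read / write cohort records as CSV
#'
#' One row per patient x algorithm, columns as in
#' \code{\link{cohort_records}}.
#'
#' @param records cohort data.frame.
#' @param path CSV file path.
#' @return \code{write_cohort_csv}: the path, invisibly;
#'   \code{read_cohort_csv}: the data.frame.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
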