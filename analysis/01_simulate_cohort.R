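#!/usr/bin/env Rscript
# Step 1: simulate the 20-patient planning PET/CT cohort.
#
# Generates 20 synthetic patients (8 lung, 5 oesophageal, 7 pelvic) with
# SUV-calibrated PET on a 4 mm grid, a schematic planning CT on a 2 mm grid,
# a ground-truth lesion mask, a hepatic background compartment for the
# PERCIST reference VOI, and a simulated manually contoured GTV (dilated by
# 1-4 mm plus a smooth boundary warp, emulating generous manual contours).
# Volumes go to scratch/ (regenerable); the cohort object feeds steps 2-4.

library(btvseg)

seed <- 42
dir.create("scratch/phantoms", showWarnings = FALSE, recursive = TRUE)

cohort <- generate_cohort(20, seed = seed)
saveRDS(cohort, "scratch/cohort.rds")

cat(sprintf("Simulated %d patients (seed %d):\n", length(cohort), seed))
for (i in seq_along(cohort)) {
  ph <- cohort[[i]]$phantom
  cat(sprintf("  P%02d %-12s peak SUV %5.1f  truth %6.1f ml  GTV %6.1f ml\n",
              i, cohort[[i]]$site, ph$suv_max_true,
              volume_ml(ph$truth_mask), volume_ml(ph$gtv_mask)))
  write_nifti_image(ph$pet, sprintf("scratch/phantoms/P%02d_pet.nii.gz", i))
  write_nifti_mask(ph$gtv_mask, sprintf("scratch/phantoms/P%02d_gtv.nii.gz", i))
  write_nifti_mask(ph$truth_mask,
                   sprintf("scratch/phantoms/P%02d_truth.nii.gz", i))
}
sites <- table(vapply(cohort, `[[`, character(1), "site"))
cat("Site mix:", paste(names(sites), sites, sep = "=", collapse = ", "), "\n")
cat("Wrote PET/GTV/truth NIfTI volumes to scratch/phantoms/\n")
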