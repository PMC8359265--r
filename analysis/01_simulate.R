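#!/usr/bin/env Rscript
# Stage 1 — simulate the two study cohorts.
#
# Cohort I: early PD (99 PD / 41 HV, ~2-year follow-up of both groups,
# PRISMA). Cohort II: progressing PD (41 PD / 23 HV, PD-only follow-up,
# TRIO). Writes the subject-visit tables and the imaging ground truth, and
# renders one example midbrain phantom to NIfTI.

suppressPackageStartupMessages(library(nmsn))
dir.create("results", showWarnings = FALSE)
seed <- 20210310

for (cohort in c("cohort1", "cohort2")) {
  design <- cohort_design(cohort)
  co <- generate_cohort(design, seed = seed)
  print(design)
  cat(sprintf("  %d subject-visit rows (%d at follow-up)\n",
              nrow(co$subjects), sum(co$subjects$visit == "V2")))
  write.csv(co$subjects, sprintf("results/%s_subjects.csv", cohort),
            row.names = FALSE)
  write.csv(co$truth, sprintf("results/%s_truth.csv", cohort),
            row.names = FALSE)
}

# one rendered scan as a visual/format check
co1 <- generate_cohort(cohort_design("cohort1"), seed = seed)
row <- co1$truth[1, ]
ph <- generate_phantom(phantom_spec_for(row), seed = seed)
write_nm_scan(ph$image, ph$masks,
              "results/example_scan.nii.gz", "results/example_labels.nii.gz")
cat(sprintf("rendered %s %s: SN %d voxels over slices %s, truth Vol %.1f mm3\n",
            row$subject_id, row$visit, sum(ph$masks$sn_mask),
            paste(range(ph$sn_slices), collapse = "-"), row$vol_true_mm3))
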