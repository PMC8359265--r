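#!/usr/bin/env Rscript
# Stage 3 — rater reliability of tracings and measurements.
#
# Emulates a second examiner by perturbing SN mask boundaries (Dice) and by
# an independent measurement pass over the same scans (ICC, two-way random
# effects, absolute agreement).

suppressPackageStartupMessages(library(nmsn))
dir.create("results", showWarnings = FALSE)
seed <- 20210310

co <- generate_cohort(cohort_design("cohort1", n_pd = 20, n_hv = 10),
                      seed = seed)

# Dice against boundary-perturbed re-tracings at three disagreement levels
dice_rows <- do.call(rbind, lapply(c(0.05, 0.15, 0.30), function(p) {
  ds <- sapply(1:10, function(i) {
    ph <- generate_phantom(phantom_spec_for(co$truth[i, ]), seed = seed + i)
    dice(ph$masks$sn_mask,
         perturb_mask(ph$masks$sn_mask, p, seed = seed + 50 + i))
  })
  data.frame(boundary_shift_prob = p, mean_dice = mean(ds), sd_dice = sd(ds))
}))
print(dice_rows, row.names = FALSE)

# ICC between two measurement passes (independent tracing noise)
m1 <- measure_cohort(co, seed = seed + 1)
m2 <- measure_cohort(co, seed = seed + 2)
k <- order(m1$subject_id, m1$visit); k2 <- order(m2$subject_id, m2$visit)
icc_rows <- data.frame(
  measure = c("vol_mm3", "snr"),
  icc21 = c(icc(cbind(m1$vol_mm3[k], m2$vol_mm3[k2])),
            icc(cbind(m1$snr[k], m2$snr[k2]))))
print(icc_rows, row.names = FALSE)

write.csv(dice_rows, "results/reliability_dice.csv", row.names = FALSE)
write.csv(icc_rows, "results/reliability_icc.csv", row.names = FALSE)
cat("\nhigh overlap and ICC at tracing-scale noise; Dice falls as the\n")
cat("simulated inter-rater boundary disagreement grows.\n")
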