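#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic study inputs.
#
# Generates the 106-patient cohort with the reference subtype mix, tidy
# viability plates (mono and drug + 4 Gy IR arms) for a small organoid
# panel, three per-caller somatic call sets with known truth, and a bulk
# expression matrix with subtype-structured signature blocks tied to a
# continuous IC50 phenotype. Everything downstream reads these files.

suppressPackageStartupMessages(library(npcpgx))

seed <- 2026L
dir.create("results", showWarnings = FALSE)

## cohort ------------------------------------------------------------------
cohort <- gen_cohort(106, seed = stage_seed(seed, "cohort"))
write.csv(cohort, "results/cohort.csv", row.names = FALSE)
cat("Cohort of", nrow(cohort), "patients; subtype percentages:\n")
print(subtype_proportions(cohort))
cat("Observed organoid establishment:",
    percent_of(sum(cohort$has_pdo), nrow(cohort), 0), "%\n\n")

## drug screen plates -------------------------------------------------------
set.seed(stage_seed(seed, "truths"))
panel <- data.frame(
  sample = sprintf("PDO%02d", 1:6),
  ic50 = exp(runif(6, log(0.2), log(10))),
  hill = runif(6, 0.8, 2)
)
write.csv(panel, "results/dr_truth.csv", row.names = FALSE)
plates <- do.call(rbind, lapply(1:6, function(i) {
  gen_dose_response(list(ic50 = panel$ic50[i], hill = panel$hill[i]),
                    n_reps = 3, noise_sd = 5,
                    seed = stage_seed(seed, paste0("plate", i)),
                    sample = panel$sample[i], drug = "docetaxel")
}))
write_plate_csv(plates, "results/plates_mono.csv")

## chemoradiotherapy arms: three drugs at different true synergy offsets ----
offsets <- c(drug1 = 0.25, drug2 = 0.2, drug3 = 0)
crt <- do.call(rbind, lapply(seq_along(offsets), function(i) {
  truth <- list(ic50 = 2, hill = 1.2)
  mono <- gen_dose_response(truth, n_reps = 3, noise_sd = 5,
                            seed = stage_seed(seed, paste0("crt_mono", i)),
                            sample = "PDO01", drug = names(offsets)[i])
  combo <- gen_combo_screen(truth, ir_inhibition = 0.25,
                            synergy_offset = offsets[[i]],
                            n_reps = 3, noise_sd = 5,
                            seed = stage_seed(seed, paste0("crt_combo", i)),
                            sample = "PDO01", drug = names(offsets)[i])
  rbind(mono, combo)
}))
write_plate_csv(crt, "results/plates_crt.csv")
cat("Simulated", length(unique(plates$sample)), "mono plates and",
    length(offsets), "drug x IR pairs (true offsets:",
    paste(offsets, collapse = ", "), ")\n\n")

## somatic call sets ---------------------------------------------------------
wes_samples <- sprintf("T%02d", 1:8)
sim <- gen_caller_callsets(n_true = 30 * 8, fp_per_caller = c(40, 40, 40),
                           sample_ids = wes_samples,
                           seed = stage_seed(seed, "wes"))
for (cl in names(sim$callsets)) {
  write_calls_tsv(sim$callsets[[cl]], sprintf("results/calls_%s.tsv", cl))
}
write.table(sim$context_lookup, "results/context_lookup.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Simulated", sum(sim$truth$is_true), "true somatic variants plus",
    sum(!sim$truth$is_true), "caller-private false positives across",
    length(sim$callsets), "callers\n\n")

## expression + phenotype ----------------------------------------------------
expr <- gen_expression(n_genes = 1500, n_samples = 14, group_log2fc = 3,
                       seed = stage_seed(seed, "expr"))
write_expression_tsv(expr$counts, "results/counts_organoids.tsv")
write.csv(expr$phenotype, "results/phenotype_organoids.csv", row.names = FALSE)
write_gmt(expr$signature_sets, "results/true_signature_sets.gmt")
val <- gen_expression(n_genes = 1500, n_samples = 120, group_log2fc = 3,
                      seed = stage_seed(seed, "validation"))
write_expression_tsv(val$counts, "results/counts_validation.tsv")
write.csv(val$phenotype, "results/phenotype_validation.csv", row.names = FALSE)
cat("Simulated expression: 1500 genes x 14 organoids (discovery)",
    "and x 120 samples (validation)\n")
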