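#!/usr/bin/env Rscript
# Stage 4 — somatic variant consensus, filtering, burden and signatures.
#
# Merges the three per-caller call sets with the >= 2-caller rule, applies
# the filter cascade (pop AF < 0.0004, depth > 20, alt reads > 3, normal
# alt < 1, VAF > 5%), summarizes per-sample burden and consequence
# classes, builds the 96-context catalog and refits it against the
# bundled synthetic reference signatures.

suppressPackageStartupMessages(library(npcpgx))

callsets <- lapply(c("callerA", "callerB", "callerC"), function(cl) {
  read_calls_tsv(sprintf("results/calls_%s.tsv", cl))
})
names(callsets) <- c("callerA", "callerB", "callerC")
lookup <- read.delim("results/context_lookup.tsv")

consensus <- merge_callers(callsets)
filtered <- apply_filters(consensus)
rejected <- attr(filtered, "rejected")
cat("Union of caller calls:", length(unique(unlist(lapply(callsets, function(x)
  paste(x$chrom, x$pos))))), "sites;",
    "consensus (>= 2 callers):", nrow(consensus), ";",
    "after filters:", nrow(filtered), "\n")
cat("Rejection reasons:\n")
print(table(rejected$reason))

samples <- sprintf("T%02d", 1:8)
burden <- burden_summary(filtered, samples)
cat("\nMean somatic SNVs per sample:", burden$mean_per_sample, "\n")
cat("Consequence classes:\n")
print(burden$by_class)
write.csv(burden$per_sample, "results/burden_per_sample.csv", row.names = FALSE)

freq <- gene_frequencies(filtered, n_cohort = length(samples))
write.csv(freq, "results/gene_frequencies.csv", row.names = FALSE)

catalog <- trinucleotide_contexts(filtered, lookup)
ref <- read_signature_ref(system.file("extdata",
                                      "synthetic_signatures_96x5.tsv",
                                      package = "npcpgx"))
fit <- refit_signatures(catalog, ref)
cat("\nSignature refit exposures (cosine similarity",
    sprintf("%.3f):\n", fit$cosine))
print(round(fit$weights, 3))
write_json_report(list(total = burden$total,
                       mean_per_sample = burden$mean_per_sample,
                       by_class = as.list(burden$by_class),
                       signature_weights = as.list(round(fit$weights, 4)),
                       signature_cosine = fit$cosine),
                  "results/variant_summary.json")
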