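#!/usr/bin/env Rscript
# Stage 5 — differential expression and pathway signature assembly.
#
# Normalizes the organoid count matrix (median-of-ratios), runs the two
# independent tests (moderated location test; rank-sum), BH-adjusts, and
# keeps genes passing |log2FC| > 1, p < 0.05, padj < 0.05 in BOTH
# methods. The survivors are intersected with five mechanism pathway
# sets; the union forms the combined drug-response signature.

suppressPackageStartupMessages(library(npcpgx))

counts <- read_expression_tsv("results/counts_organoids.tsv")
pheno <- read.csv("results/phenotype_organoids.csv")
true_sets <- read_gmt("results/true_signature_sets.gmt")

norm <- normalize_counts(counts)
cat("Size factors span",
    sprintf("%.2f-fold\n", max(norm$size_factors) / min(norm$size_factors)))

res_a <- de_test(norm$log2_normalized, pheno$group, "moderated")
res_b <- de_test(norm$log2_normalized, pheno$group, "ranksum")
write.csv(res_a, "results/de_moderated.csv", row.names = FALSE)
write.csv(res_b, "results/de_ranksum.csv", row.names = FALSE)

sig <- overlap_filter(res_a, res_b)
cat("Survivors: moderated",
    sum(abs(res_a$log2fc) > 1 & res_a$p < 0.05 & res_a$padj < 0.05),
    "| rank-sum",
    sum(abs(res_b$log2fc) > 1 & res_b$p < 0.05 & res_b$padj < 0.05),
    "| overlap", nrow(sig), "\n")
truth_genes <- unlist(true_sets)
cat(sprintf("Recovery of true signature genes: %.0f%%\n",
            100 * mean(truth_genes %in% sig$gene)))
write.csv(sig, "results/signature_genes.csv", row.names = FALSE)

# five mechanism pathways: chunks of the true blocks plus background
set.seed(stage_seed(2026L, "pathways"))
chunks <- split(truth_genes, rep(1:5, length.out = length(truth_genes)))
background <- setdiff(rownames(counts), truth_genes)
pathways <- setNames(lapply(chunks, function(g) c(g, sample(background, 20))),
                     c("apoptosis", "microtubule", "mitotic_cell_cycle",
                       "androgen_response", "tnfa_nfkb"))
write_gmt(pathways, "results/pathways.gmt")
asm <- assemble_pathway_signature(sig, pathways)
cat("Per-pathway signature sizes:\n")
print(asm$counts)

# direction-resolved signatures for scoring: up in sensitive vs resistant
sens_up <- intersect(sig$gene[sig$direction == "up_in_B"], asm$combined)
resist_up <- intersect(sig$gene[sig$direction == "up_in_A"], asm$combined)
write_gmt(list(combined = asm$combined, sensitive_up = sens_up,
               resistant_up = resist_up),
          "results/assembled_signature.gmt")
cat("Combined signature:", length(asm$combined), "genes (",
    length(sens_up), "up in sensitive,", length(resist_up),
    "up in resistant )\n")
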