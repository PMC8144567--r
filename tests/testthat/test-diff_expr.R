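test_that("median-of-ratios size factors behave like library-size estimates", {
  m <- matrix(c(10, 100, 50, 10, 100, 50), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  nf <- normalize_counts(m)
  expect_equal(unname(nf$size_factors), c(1, 1))
  # doubling one sample doubles its factor
  m2 <- m
  m2[, 2] <- m2[, 2] * 2
  sf2 <- normalize_counts(m2)$size_factors
  expect_equal(unname(sf2), c(1 / sqrt(2), sqrt(2))) # geometric mean 1
  expect_equal(unname(sf2[2] / sf2[1]), 2)
  # adding an all-zero gene changes nothing (zeros excluded from the reference)
  m3 <- rbind(m2, g4 = c(0, 0))
  expect_equal(normalize_counts(m3)$size_factors, normalize_counts(m2)$size_factors)
  # no all-nonzero gene: total-count fallback with warning
  m4 <- matrix(c(5, 0, 0, 7), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(nf4 <- normalize_counts(m4), "total-count")
  expect_equal(unname(nf4$size_factors), c(5, 7) / 6)
})

test_that("BH adjustment reproduces the step-up hand calculation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  # monotone transform of p, never smaller than p, capped at 1
  set.seed(1)
  p <- stats::runif(50)
  padj <- bh_adjust(p)
  expect_true(all(padj >= p - 1e-12))
  expect_true(all(padj <= 1))
  expect_true(all(diff(padj[order(p)]) >= -1e-12))
  # permutation invariance up to reordering
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), padj[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("both DE tests share the effect estimate and respect label symmetry", {
  sim <- gen_expression(n_genes = 300, n_samples = 14, group_log2fc = 2,
                        seed = 21)
  norm <- normalize_counts(sim$counts)$log2_normalized
  g <- sim$phenotype$group
  res_a <- de_test(norm, g, "moderated")
  res_b <- de_test(norm, g, "ranksum")
  expect_equal(res_a$log2fc, res_b$log2fc)
  expect_true(all(res_a$padj >= res_a$p - 1e-12))
  # swapping which group is the baseline flips the fold change, keeps p-values
  res_sw <- de_test(norm, factor(g, levels = c("B", "A")), "moderated")
  expect_equal(res_sw$log2fc, -res_a$log2fc)
  expect_equal(res_sw$p, res_a$p)
  expect_error(de_test(norm[, 1:3], g[1:3], "moderated"), "at least two samples")
})

test_that("strong signature genes are detected by both methods", {
  sim <- gen_expression(n_genes = 400, n_samples = 14, group_log2fc = 3,
                        dispersion = c(0.02, 0.05), seed = 22)
  norm <- normalize_counts(sim$counts)$log2_normalized
  g <- sim$phenotype$group
  res_a <- de_test(norm, g, "moderated")
  res_b <- de_test(norm, g, "ranksum")
  target <- sim$signature_sets$up_in_A
  expect_gt(mean(res_a$p[res_a$gene %in% target] < 1e-3), 0.9)
  expect_gt(mean(res_b$p[res_b$gene %in% target] < 0.01), 0.9)
})

test_that("null p-values from the moderated test are approximately uniform", {
  sim <- gen_expression(n_genes = 2000, n_samples = 14, group_log2fc = 0,
                        seed = 23)
  norm <- normalize_counts(sim$counts)$log2_normalized
  res <- de_test(norm, sim$phenotype$group, "moderated")
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.05)
  # about alpha of null genes reach p < 0.05 before FDR control
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.02)
})

test_that("the overlap filter keeps only genes passing both methods", {
  mk <- function(lfc, p, padj) {
    data.frame(gene = paste0("g", seq_along(lfc)), log2fc = lfc, p = p,
               padj = padj, stringsAsFactors = FALSE)
  }
  res_a <- mk(c(2.5, 2.0, 0.5, -3), c(1e-6, 1e-4, 1e-6, 1e-5),
              c(1e-4, 1e-3, 1e-4, 1e-4))
  # g2 passes A only (fails B's padj); g3 fails the fold-change cut
  res_b <- mk(c(2.4, 1.8, 0.4, -2.8), c(1e-5, 0.01, 1e-5, 1e-4),
              c(1e-3, 0.2, 1e-3, 1e-3))
  sig <- overlap_filter(res_a, res_b)
  expect_setequal(sig$gene, c("g1", "g4"))
  expect_equal(sig$direction[sig$gene == "g1"], "up_in_A")
  expect_equal(sig$direction[sig$gene == "g4"], "up_in_B")
  # output is a subset of each method's own survivor set
  pass <- function(r) r$gene[abs(r$log2fc) > 1 & r$p < 0.05 & r$padj < 0.05]
  expect_true(all(sig$gene %in% pass(res_a)))
  expect_true(all(sig$gene %in% pass(res_b)))
  # empty in, empty out; mismatched universes rejected
  expect_equal(nrow(overlap_filter(res_a[0, ], res_b[0, ])), 0)
  expect_error(overlap_filter(res_a, res_b[-1, ]), "universe")
})

test_that("signature recovery is near-complete for strong effects", {
  sim <- gen_expression(n_genes = 500, n_samples = 14, group_log2fc = 3,
                        dispersion = c(0.02, 0.05), seed = 24)
  norm <- normalize_counts(sim$counts)$log2_normalized
  g <- sim$phenotype$group
  sig <- overlap_filter(de_test(norm, g, "moderated"),
                        de_test(norm, g, "ranksum"))
  truth_genes <- unlist(sim$signature_sets)
  expect_gte(mean(truth_genes %in% sig$gene), 0.9)
})

test_that("pathway signatures are intersections with a combined union", {
  sig <- c("a", "b", "c", "d", "e")
  sets <- list(p1 = c("a", "b", "x"), p2 = c("c", "y"), p3 = c("z", "w"))
  asm <- assemble_pathway_signature(sig, sets)
  expect_equal(asm$per_pathway$p1, c("a", "b"))
  expect_equal(asm$per_pathway$p3, character(0))
  expect_setequal(asm$combined, c("a", "b", "c"))
  expect_equal(unname(asm$counts["combined"]), 3L)
  # pathway fully inside the signature comes back whole
  asm2 <- assemble_pathway_signature(sig, list(p = c("a", "e")))
  expect_equal(asm2$per_pathway$p, c("a", "e"))
  # disjoint everywhere: empty combined signature with a warning
  expect_warning(asm3 <- assemble_pathway_signature(sig, list(p = "q")),
                 "empty")
  expect_equal(length(asm3$combined), 0)
  # a run configured for a 105-gene combined signature scores 105 genes
  sig105 <- sprintf("s%03d", 1:105)
  five <- split(sig105, rep(1:5, each = 21))
  asm105 <- assemble_pathway_signature(sig105, five)
  expect_equal(unname(asm105$counts["combined"]), 105L)
})
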