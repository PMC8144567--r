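toy_callset <- function(keys, caller, t_depth = 50) {
  n <- length(keys)
  data.frame(
    chrom = "chr1", pos = match(keys, LETTERS) * 100L,
    ref = "C", alt = "T", caller = caller, sample = "S1",
    t_depth = rep_len(t_depth, n), t_alt = 10L, n_alt = 0L,
    pop_af = 0, vaf = 0.2, stringsAsFactors = FALSE
  )
}

test_that("consensus keeps exactly the variants seen by >= 2 callers", {
  sets <- list(c1 = toy_callset(c("A", "B", "C"), "c1"),
               c2 = toy_callset(c("B", "C", "D"), "c2"),
               c3 = toy_callset(c("C", "E"), "c3"))
  cons <- merge_callers(sets)
  expect_setequal(cons$pos, c(200, 300)) # B and C
  expect_equal(sort(cons$n_callers), c(2L, 3L))
  # three identical sets: consensus equals the set
  same <- list(a = toy_callset(c("A", "B"), "a"), b = toy_callset(c("A", "B"), "b"),
               c = toy_callset(c("A", "B"), "c"))
  expect_setequal(merge_callers(same)$pos, c(100, 200))
  # pairwise-disjoint sets: empty consensus
  disj <- list(a = toy_callset("A", "a"), b = toy_callset("B", "b"),
               c = toy_callset("C", "c"))
  expect_equal(nrow(merge_callers(disj)), 0)
  expect_error(merge_callers(list(toy_callset("A", "a"))), "two callers")
})

test_that("consensus annotation comes from the deepest caller, monotone in callers", {
  shallow <- toy_callset("A", "c1", t_depth = 30)
  deep <- toy_callset("A", "c2", t_depth = 90)
  cons <- merge_callers(list(c1 = shallow, c2 = deep))
  expect_equal(cons$t_depth, 90)
  expect_equal(cons$caller, "c2")
  # ties broken by caller name order
  tie <- merge_callers(list(z = toy_callset("A", "z", 50),
                            a = toy_callset("A", "a", 50)))
  expect_equal(tie$caller, "a")
  # superset monotonicity: adding a caller never removes consensus variants
  base <- merge_callers(list(c1 = toy_callset(c("A", "B"), "c1"),
                             c2 = toy_callset(c("B", "C"), "c2")))
  more <- merge_callers(list(c1 = toy_callset(c("A", "B"), "c1"),
                             c2 = toy_callset(c("B", "C"), "c2"),
                             c3 = toy_callset(c("A", "C"), "c3")))
  expect_true(all(paste(base$chrom, base$pos) %in% paste(more$chrom, more$pos)))
})

test_that("the filter cascade applies the printed thresholds strictly", {
  v <- function(t_depth = 25, t_alt = 4, n_alt = 0, pop_af = 0, vaf = 0.10) {
    data.frame(chrom = "chr1", pos = 100L, ref = "C", alt = "T", sample = "S1",
               t_depth = t_depth, t_alt = t_alt, n_alt = n_alt,
               pop_af = pop_af, vaf = vaf, stringsAsFactors = FALSE)
  }
  expect_equal(nrow(apply_filters(v())), 1) # all thresholds cleared
  cases <- list(
    list(df = v(t_depth = 15), reason = "depth"),
    list(df = v(pop_af = 0.001), reason = "pop_af"),
    list(df = v(t_alt = 3), reason = "alt_reads"),   # strict: needs > 3
    list(df = v(n_alt = 1), reason = "normal_alt"),  # strict: needs < 1
    list(df = v(vaf = 0.05), reason = "vaf")         # strict: needs > 5%
  )
  for (case in cases) {
    out <- apply_filters(case$df)
    expect_equal(nrow(out), 0)
    expect_equal(attr(out, "rejected")$reason, case$reason)
  }
  # boundary values that just clear the strict thresholds
  expect_equal(nrow(apply_filters(v(t_depth = 21, t_alt = 4, vaf = 0.051))), 1)
  # missing annotation is a per-variant rejection with its own reason
  miss <- v(); miss$vaf <- NA_real_
  out <- apply_filters(miss)
  expect_equal(attr(out, "rejected")$reason, "missing_annotation")
})

test_that("filtering is idempotent and masks low-mappability intervals", {
  sim <- gen_caller_callsets(40, fp_per_caller = c(10, 10, 10), seed = 3)
  cons <- merge_callers(sim$callsets)
  once <- apply_filters(cons)
  twice <- apply_filters(once)
  expect_equal(nrow(once), nrow(twice))
  expect_equal(once$pos, twice$pos)
  # a mask covering one variant removes exactly that variant
  target <- once[1, ]
  mask <- data.frame(chrom = target$chrom, start = target$pos - 1L,
                     end = target$pos)
  masked <- apply_filters(cons, mask = mask)
  expect_equal(nrow(masked), nrow(once) - 1)
  expect_true("low_mappability" %in% attr(masked, "rejected")$reason)
})

test_that("BED overlap uses the 0-based half-open convention", {
  bed <- data.frame(chrom = "chr1", start = 10L, end = 20L)
  # [10, 20) covers 1-based positions 11..20
  expect_false(bed_overlaps(bed, "chr1", 10))
  expect_true(bed_overlaps(bed, "chr1", 11))
  expect_true(bed_overlaps(bed, "chr1", 20))
  expect_false(bed_overlaps(bed, "chr1", 21))
  expect_false(bed_overlaps(bed, "chr2", 15))
})

test_that("burden summaries reproduce the reporting arithmetic", {
  # 6 variants over 2 samples -> mean 3.0
  small <- data.frame(sample = rep(c("a", "b"), 3),
                      consequence = rep("missense", 6))
  bs <- burden_summary(small, c("a", "b"))
  expect_equal(bs$mean_per_sample, 3.0)
  expect_equal(sum(bs$by_class), bs$total)
  # empty set -> mean 0.0
  expect_equal(burden_summary(small[0, ], c("a", "b"))$mean_per_sample, 0)
  expect_error(burden_summary(small, character(0)), "non-empty")
})

test_that("per-gene frequencies count unique mutated samples", {
  v <- data.frame(gene = c("EGFR", "TP53", "TP53", "TP53"),
                  sample = c("P1", "P1", "P2", "P2"), stringsAsFactors = FALSE)
  freq <- gene_frequencies(v, n_cohort = 106)
  expect_equal(freq$frequency_pct[freq$gene == "EGFR"], 0.94) # 1/106
  expect_equal(freq$n_samples[freq$gene == "TP53"], 2) # duplicate sample counted once
})

test_that("trinucleotide catalog respects the pyrimidine strand convention", {
  lookup <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                       pos = c(100, 200, 300),
                       context = c("ACA", "TGC", "AAA"), stringsAsFactors = FALSE)
  snv <- function(chrom, pos, ref, alt) {
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }
  # C>T with A_A flanks
  cat1 <- trinucleotide_contexts(snv("chr1", 100, "C", "T"), lookup)
  expect_equal(sum(cat1), 1)
  expect_equal(unname(cat1["A[C>T]A"]), 1L)
  # G>A with T_C flanks collapses to G[C>T]A by reverse complement
  cat2 <- trinucleotide_contexts(snv("chr1", 200, "G", "A"), lookup)
  expect_equal(unname(cat2["G[C>T]A"]), 1L)
  # middle base disagreeing with ref is rejected and counted
  cat3 <- trinucleotide_contexts(snv("chr2", 300, "C", "T"), lookup)
  expect_equal(sum(cat3), 0)
  expect_equal(attr(cat3, "n_rejected"), 1L)
  # indels are excluded; catalog total equals the number of usable SNVs
  mixed <- rbind(snv("chr1", 100, "C", "T"), snv("chr1", 200, "G", "A"),
                 snv("chr1", 100, "CT", "C"))
  expect_equal(sum(trinucleotide_contexts(mixed, lookup)), 2)
  expect_equal(length(context_classes()), 96)
})

test_that("signature refitting recovers exact mixtures", {
  ref <- synthetic_reference_signatures(k = 5, seed = 42)
  # pure membership
  fit1 <- refit_signatures(100 * ref[, 3], ref)
  expect_equal(unname(fit1$weights[3]), 1, tolerance = 1e-8)
  expect_equal(fit1$cosine, 1, tolerance = 1e-9)
  # noiseless 0.6/0.4 mixture, checked against the independent oracle
  mix <- 0.6 * ref[, 1] + 0.4 * ref[, 2]
  fit2 <- refit_signatures(mix * 1e4, ref)
  expect_equal(unname(fit2$weights[1:2]), c(0.6, 0.4), tolerance = 1e-6)
  oracle <- nnls_oracle(ref, mix / sum(mix))
  expect_equal(unname(fit2$weights), oracle, tolerance = 1e-4)
  # exome2genome with unit ratios equals no normalization
  fit3 <- refit_signatures(mix * 1e4, ref, "exome2genome", ratio = rep(1, 96))
  expect_equal(fit3$weights, fit2$weights)
  # a non-trivial ratio changes the effective catalog
  fit4 <- refit_signatures(mix * 1e4, ref, "exome2genome",
                           ratio = seq(0.5, 2, length.out = 96))
  expect_false(isTRUE(all.equal(fit4$weights, fit2$weights)))
  expect_error(refit_signatures(rep(0, 96), ref), "empty")
  expect_error(refit_signatures(mix, ref * 2), "sum to 1")
})

test_that("consensus on caller-private-FP simulations has precision 1", {
  sim <- gen_caller_callsets(60, fp_per_caller = c(15, 15, 15), seed = 9,
                             sample_ids = c("T1", "T2", "T3"))
  cons <- merge_callers(sim$callsets)
  key <- paste(cons$chrom, cons$pos, cons$ref, cons$alt, sep = ":")
  truth <- sim$truth
  precision <- mean(key %in% truth$key[truth$is_true])
  expect_equal(precision, 1.0)
  # recall after filtering equals the fraction of true variants passing
  filt <- apply_filters(cons)
  fkey <- paste(filt$chrom, filt$pos, filt$ref, filt$alt, sep = ":")
  expect_true(all(fkey %in% truth$key[truth$is_true]))
  expect_equal(length(fkey) / sum(truth$is_true),
               nrow(filt) / 60)
})
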