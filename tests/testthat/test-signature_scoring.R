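test_that("ssGSEA matches a step-by-step running-sum evaluation", {
  expr <- matrix(c(5, 4, 3, 2, 1,
                   1, 3, 5, 2, 4), 5, 2,
                 dimnames = list(paste0("g", 1:5), c("s1", "s2")))
  set2 <- c("g1", "g3")
  got <- ssgsea_score(expr, set2, alpha = 0.25)
  for (j in 1:2) {
    expect_equal(got[1, j],
                 running_sum_ssgsea(expr[, j], set2, alpha = 0.25))
  }
  # random matrices against the oracle, several set sizes
  set.seed(4)
  for (i in 1:10) {
    m <- matrix(stats::rnorm(40 * 3), 40, 3,
                dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:3)))
    gs <- sample(rownames(m), sample(3:10, 1))
    got_i <- ssgsea_score(m, gs, alpha = 0.25)
    for (j in 1:3) {
      expect_equal(got_i[1, j], running_sum_ssgsea(m[, j], gs, 0.25))
    }
  }
})

test_that("ssGSEA ranks set genes: top-loaded beats bottom-loaded", {
  genes <- sprintf("g%02d", 1:30)
  top <- stats::setNames(c(seq(30, 21), seq(20, 1)), genes) # set genes highest
  bottom <- stats::setNames(c(seq(10, 1), seq(30, 11)), genes) # set genes lowest
  expr <- cbind(top_sample = top, bottom_sample = bottom)
  rownames(expr) <- genes
  s <- ssgsea_score(expr, genes[1:10])
  expect_gt(s[1, "top_sample"], s[1, "bottom_sample"])
  expect_error(ssgsea_score(expr, genes[1]), ">= 2 genes")
})

test_that("ssGSEA is invariant under strictly increasing transforms", {
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(stats::rnorm(60 * 4), 60, 4,
                dimnames = list(sprintf("g%02d", 1:60), paste0("s", 1:4)))
    gs <- sample(rownames(m), 12)
    expect_equal(ssgsea_score(exp(m), gs), ssgsea_score(m, gs))
    expect_equal(ssgsea_score(m * 10 + 3, gs), ssgsea_score(m, gs))
  }
})

test_that("quantile labeling takes floor(q*n) per tail in stable order", {
  set.seed(8)
  ic50 <- stats::setNames(stats::rlnorm(20), sprintf("s%02d", 1:20))
  lab <- label_by_ic50(ic50, q = 0.10)
  expect_equal(as.integer(table(lab$label)), c(2L, 16L, 2L))
  # sensitive IC50s all below resistant IC50s
  expect_lt(max(lab$ic50[lab$label == "sensitive"]),
            min(lab$ic50[lab$label == "resistant"]))
  # the cell-line-scale case: 880 samples -> 88 per class
  big <- stats::setNames(stats::rlnorm(880), sprintf("c%03d", 1:880))
  lab_big <- label_by_ic50(big, q = 0.10)
  expect_equal(sum(lab_big$label == "sensitive"), 88L)
  expect_equal(sum(lab_big$label == "resistant"), 88L)
  # boundary ties resolved by stable input order
  tied <- stats::setNames(c(1, 1, 1, 2, 3, 4, 5, 6, 7, 8), letters[1:10])
  expect_no_warning(lab_t <- label_by_ic50(tied, q = 0.10)) # n = 10, no warning
  expect_equal(lab_t$sample[lab_t$label == "sensitive"], "a")
  expect_error(label_by_ic50(rep(2, 20)), "identical")
})

test_that("midrank AUC equals brute-force pairwise concordance", {
  expect_equal(roc_auc(c(0.9, 0.7, 0.6, 0.2), c("pos", "neg", "pos", "neg"),
                       positive = "pos", negative = "neg")$auc, 0.75)
  # perfect separation and full ties
  expect_equal(roc_auc(c(3, 4, 1, 2), c("s", "s", "r", "r"),
                       positive = "s", negative = "r")$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("s", "r"), 3),
                       positive = "s", negative = "r")$auc, 0.5)
  # random vectors with ties against the oracle
  set.seed(9)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    scores <- sample(1:4, n, replace = TRUE) + 0 # discrete: forces ties
    is_pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(is_pos) || all(is_pos)) next
    labels <- ifelse(is_pos, "sensitive", "resistant")
    expect_equal(roc_auc(scores, labels)$auc, brute_force_auc(scores, is_pos))
  }
  expect_error(roc_auc(1:3, rep("sensitive", 3)), "at least one")
})

test_that("ROC curve is anchored and label reversal maps AUC to 1 - AUC", {
  set.seed(10)
  scores <- stats::rnorm(30)
  labels <- ifelse(stats::runif(30) < 0.4, "sensitive", "resistant")
  roc <- roc_auc(scores, labels)
  expect_equal(unlist(roc$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc$points[nrow(roc$points), ]), c(fpr = 1, tpr = 1))
  flipped <- roc_auc(scores, labels, positive = "resistant",
                     negative = "sensitive")
  expect_equal(flipped$auc, 1 - roc$auc)
  # agreement with an independent ROC implementation when available
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("resistant", "sensitive"),
      direction = "<")))
    expect_equal(roc$auc, as.numeric(ref))
  }
})

test_that("point-biserial correlation handles signal, null and degenerate cases", {
  labels <- c(rep("sensitive", 5), rep("resistant", 5))
  scores <- rbind(perfect = c(5:1 + 10, 5:1), flat = rep(1, 10))
  # perfectly ordered scores -> r = 1 is not expected (point-biserial < 1),
  # but the sign convention is higher score with sensitive
  out <- score_response_correlation(scores, labels)
  expect_gt(out$r[out$feature == "perfect"], 0.8)
  expect_true(is.na(out$r[out$feature == "flat"]))
  expect_equal(out$note[out$feature == "flat"], "zero variance")
  # binary scores ordered exactly with labels do give r = 1
  bin <- matrix(c(rep(1, 5), rep(0, 5)), 1,
                dimnames = list("indicator", NULL))
  expect_equal(score_response_correlation(bin, labels)$r, 1)
  # null: scores independent of labels average to r ~ 0
  set.seed(11)
  rs <- replicate(200, {
    s <- matrix(stats::rnorm(10), 1, dimnames = list("p", NULL))
    score_response_correlation(s, labels)$r
  })
  expect_lt(abs(mean(rs)), 0.05)
  # subtype rows appear when subtypes are supplied
  st <- rep(c("EC", "SC"), 5)
  out2 <- score_response_correlation(bin, labels, subtype = st)
  expect_setequal(out2$feature[out2$kind == "subtype"], c("EC", "SC"))
})

test_that("random-signature null is reproducible and centered near 0.5", {
  sim <- gen_expression(n_genes = 400, n_samples = 60, group_log2fc = 2,
                        seed = 30)
  set.seed(31)
  ic50_indep <- stats::setNames(stats::rlnorm(60), colnames(sim$counts))
  labels <- label_by_ic50(ic50_indep, q = 0.2)
  one <- random_signature_null(sim$counts, labels, n_genes = 40, n_iter = 1,
                               seed = 5)
  two <- random_signature_null(sim$counts, labels, n_genes = 40, n_iter = 1,
                               seed = 5)
  expect_identical(one$aucs, two$aucs)
  null <- random_signature_null(sim$counts, labels, n_genes = 40, n_iter = 60,
                                seed = 6)
  expect_lt(abs(null$mean - 0.5), 0.05)
  expect_error(random_signature_null(sim$counts, labels, n_genes = 1e5), "universe")
})

test_that("the generative signature outperforms the random null", {
  sim <- gen_expression(n_genes = 400, n_samples = 60, group_log2fc = 3,
                        seed = 32)
  labels <- label_by_ic50(stats::setNames(sim$phenotype$ic50,
                                          sim$phenotype$sample), q = 0.2)
  # genes up in the sensitive (low-IC50) group are the informative signature
  s <- ssgsea_score(sim$counts, sim$signature_sets$up_in_B)
  auc_sig <- roc_auc(s[1, ], labels)$auc
  null <- random_signature_null(sim$counts, labels, n_genes = 60, n_iter = 40,
                                seed = 7)
  expect_gt(auc_sig, null$mean)
  expect_gt(auc_sig, 0.8)
})

test_that("strong IC50-signature coupling yields high AUC across cohorts", {
  hits <- vapply(1:50, function(i) {
    sim <- gen_expression(n_genes = 300, n_samples = 60, group_log2fc = 3,
                          seed = 400 + i)
    labels <- label_by_ic50(stats::setNames(sim$phenotype$ic50,
                                            sim$phenotype$sample), q = 0.2)
    s <- ssgsea_score(sim$counts, sim$signature_sets$up_in_B)
    roc_auc(s[1, ], labels)$auc >= 0.85
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
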