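# Independent oracles used across the suite. Each re-derives the expected
# quantity by brute force or a different algorithm than the implementation.

# AUC as the fraction of concordant (positive, negative) pairs, ties 1/2
brute_force_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# ssGSEA running sum evaluated step by step, one position at a time
running_sum_ssgsea <- function(x, geneset, alpha) {
  r <- unname(rank(x, ties.method = "average"))
  ord <- order(x, decreasing = TRUE)
  genes <- names(x)[ord]
  in_set <- genes %in% geneset
  denom_in <- sum(r[ord][in_set]^alpha)
  denom_out <- sum(!in_set)
  p_in <- 0
  p_out <- 0
  score <- 0
  for (i in seq_along(genes)) {
    if (in_set[i]) {
      p_in <- p_in + r[ord][i]^alpha / denom_in
    } else {
      p_out <- p_out + 1 / denom_out
    }
    score <- score + (p_in - p_out)
  }
  score
}

# nonnegative least squares by general-purpose box-constrained optimization
# (independent of the active-set solver behind refit_signatures)
nnls_oracle <- function(A, b) {
  fn <- function(w) sum((A %*% w - b)^2)
  gr <- function(w) as.numeric(2 * t(A) %*% (A %*% w - b))
  fit <- stats::optim(rep(0.1, ncol(A)), fn, gr, method = "L-BFGS-B",
                      lower = 0, control = list(maxit = 500, factr = 1e4))
  fit$par
}

# simulate one mono + combo chemoradiotherapy pair and classify it
simulate_and_classify <- function(offset, noise_sd, seed,
                                  ir_inhibition = 0.25,
                                  truth = list(ic50 = 2, hill = 1.2)) {
  mono <- gen_dose_response(truth, noise_sd = noise_sd, seed = seed)
  combo <- gen_combo_screen(truth, ir_inhibition, offset,
                            noise_sd = noise_sd, seed = seed + 1L)
  evaluate_crt_pair(mono, combo, ir_inhibition)$verdict
}

# all 2^n positive/negative labelings of n samples with >= 1 of each class
all_labelings <- function(n) {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  keep <- rowSums(grid) > 0 & rowSums(grid) < n
  lapply(which(keep), function(i) as.logical(grid[i, ]))
}
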