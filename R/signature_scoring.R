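#' Single-sample GSEA enrichment scores
#'
#' Per sample, genes are ranked by expression (descending) and the score
#' is the running-sum integral of the difference between the weighted
#' in-set empirical CDF and the uniform out-of-set ECDF:
#' in-set steps at rank position `i` are weighted by `rank^alpha` (ranks
#' of the expression values, so scores are invariant under any strictly
#' increasing transform of the expression), out-of-set steps by
#' `1 / (N - n_set)`, and the score is the sum of the ECDF difference
#' over all positions. `alpha = 0.25` is the conventional weighting.
#'
#' Ranks and orderings are computed once per sample and shared across
#' gene sets, so scoring many sets (e.g. a random-signature null) costs
#' one pass per set.
#'
#' @param expression Numeric matrix, genes x samples, with rownames.
#' @param genesets A character vector (one set) or named list of gene
#'   sets; each must intersect the matrix in >= 2 genes and leave >= 2
#'   genes outside.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize If TRUE, additionally min-max rescale each set's
#'   scores across samples to `[0, 1]` (returned as attribute
#'   `"normalized"`; AUC-based evaluation is invariant to this).
#' @return Matrix of scores, gene sets x samples.
#' @export
ssgsea_score <- function(expression, genesets, alpha = 0.25, normalize = FALSE) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression))) stop("expression matrix needs rownames", call. = FALSE)
  if (!is.list(genesets)) genesets <- list(geneset = genesets)
  if (is.null(names(genesets))) names(genesets) <- paste0("set", seq_along(genesets))
  n <- nrow(expression)
  idx_sets <- lapply(genesets, function(g) {
    idx <- which(rownames(expression) %in% g)
    if (length(idx) < 2 || n - length(idx) < 2) {
      stop("each gene set must have >= 2 genes inside and outside the matrix",
           call. = FALSE)
    }
    idx
  })
  scores <- matrix(NA_real_, length(genesets), ncol(expression),
                   dimnames = list(names(genesets), colnames(expression)))
  inset <- logical(n)
  for (j in seq_len(ncol(expression))) {
    x <- expression[, j]
    r <- rank(x, ties.method = "average")
    ord <- order(x, decreasing = TRUE)
    w_all <- r[ord]^alpha
    for (s in seq_along(idx_sets)) {
      inset[] <- FALSE
      inset[idx_sets[[s]]] <- TRUE
      ind <- inset[ord]
      w_in <- w_all * ind
      p_in <- cumsum(w_in) / sum(w_in)
      p_out <- cumsum(!ind) / (n - sum(ind))
      scores[s, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- apply(scores, 1, range)
    attr(scores, "normalized") <- (scores - rng[1, ]) /
      pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
  }
  scores
}

#' Label samples sensitive/resistant from IC50 quantiles
#'
#' Samples with the bottom `floor(q * n)` IC50 values are labeled drug
#' sensitive and the top `floor(q * n)` resistant; the rest stay
#' unlabeled. Boundary ties are broken by stable input order, so the
#' labeling is deterministic.
#'
#' @param ic50 Named numeric vector of per-sample IC50s (uM).
#' @param q Quantile fraction in `(0, 0.5)` (default 0.10).
#' @return data.frame `sample`, `ic50`, `label` (factor
#'   `sensitive`/`unlabeled`/`resistant`).
#' @export
#' @examples
#' # 880 cell lines at q = 0.10 -> 88 sensitive and 88 resistant
#' floor(0.10 * 880)
label_by_ic50 <- function(ic50, q = 0.10) {
  stopifnot(q > 0, q < 0.5)
  n <- length(ic50)
  if (n < 10) warning("fewer than 10 samples; quantile labels are coarse")
  if (length(unique(ic50)) == 1) {
    stop("all IC50 values identical; no sensitivity ordering exists", call. = FALSE)
  }
  if (is.null(names(ic50))) names(ic50) <- sprintf("S%03d", seq_len(n))
  k <- floor(q * n)
  ord <- order(ic50) # stable: ties keep input order
  label <- rep("unlabeled", n)
  label[ord[seq_len(k)]] <- "sensitive"
  label[ord[n + 1 - seq_len(k)]] <- "resistant"
  data.frame(sample = names(ic50), ic50 = unname(ic50),
             label = factor(label, levels = c("sensitive", "unlabeled", "resistant")),
             stringsAsFactors = FALSE)
}

#' ROC curve and AUC by the midrank (Mann-Whitney) statistic
#'
#' AUC is computed as `U / (n1 * n0)` from midranks, which equals the
#' probability that a random positive outscores a random negative with
#' ties counted one half. Unlabeled samples are excluded. The returned
#' curve runs from (0, 0) to (1, 1) over descending score thresholds.
#'
#' @param scores Numeric score per sample.
#' @param labels Factor/character per sample, or a [label_by_ic50()]
#'   data.frame (its `label` column is used).
#' @param positive Label counted as positive (default `"sensitive"`).
#' @param negative Label counted as negative (default `"resistant"`);
#'   any other label is dropped.
#' @return List of class `roc_result`: `auc`, `points` (data.frame
#'   `fpr`, `tpr`), `positive`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.7, 0.6, 0.2), c("pos", "neg", "pos", "neg"),
#'         positive = "pos", negative = "neg")$auc # 0.75
roc_auc <- function(scores, labels, positive = "sensitive",
                    negative = "resistant") {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  keep <- labels %in% c(positive, negative)
  scores <- scores[keep]
  labels <- labels[keep]
  y <- labels == positive
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    stop("need at least one positive and one negative sample", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # curve over descending unique thresholds
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  dup <- rev(duplicated(rev(scores[ord]))) # keep last index of each tie block
  tpr <- cumsum(ys)[!dup] / n1
  fpr <- cumsum(!ys)[!dup] / n0
  structure(list(
    auc = auc,
    points = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)),
    positive = positive, n_pos = n1, n_neg = n0
  ), class = "roc_result")
}

#' Point-biserial correlation of scores and subtypes with drug response
#'
#' Pearson correlation of each pathway score (and, optionally, each
#' subtype membership indicator) with the binary response over labeled
#' samples, coded 1 = sensitive, 0 = resistant. Zero-variance rows give a
#' missing correlation with a reason, not zero.
#'
#' @param scores Matrix from [ssgsea_score()] (sets x samples).
#' @param labels [label_by_ic50()] data.frame aligned to the score
#'   columns, or a label vector.
#' @param subtype Optional per-sample subtype vector; adds one row per
#'   subtype level correlating membership with response.
#' @return data.frame `feature`, `kind` (`pathway`/`subtype`), `r`, `n`,
#'   `note`.
#' @export
score_response_correlation <- function(scores, labels, subtype = NULL) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- as.character(labels)
  stopifnot(ncol(scores) == length(labels))
  keep <- labels %in% c("sensitive", "resistant")
  if (sum(keep) < 3) stop("need at least three labeled samples", call. = FALSE)
  y <- as.numeric(labels[keep] == "sensitive")
  one_row <- function(feature, kind, x) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      data.frame(feature = feature, kind = kind, r = NA_real_, n = length(y),
                 note = "zero variance", stringsAsFactors = FALSE)
    } else {
      data.frame(feature = feature, kind = kind, r = stats::cor(x, y),
                 n = length(y), note = "", stringsAsFactors = FALSE)
    }
  }
  rows <- lapply(rownames(scores), function(p) {
    one_row(p, "pathway", as.numeric(scores[p, keep]))
  })
  if (!is.null(subtype)) {
    stopifnot(length(subtype) == length(labels))
    for (st in unique(as.character(subtype))) {
      rows <- c(rows, list(one_row(st, "subtype",
                                   as.numeric(subtype[keep] == st))))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Random-signature null distribution of prediction AUC
#'
#' Draws `n_iter` random gene signatures of a fixed size, scores every
#' sample by ssGSEA and evaluates the ROC AUC against the given labels.
#' When labels are independent of expression the null AUC distribution is
#' centered at 0.5, the reference against which real signature AUCs are
#' judged.
#'
#' @param expression Genes x samples matrix.
#' @param labels Labels as in [roc_auc()].
#' @param n_genes Signature size (default 105, the combined five-pathway
#'   signature size).
#' @param n_iter Number of random signatures (default 200).
#' @param seed Integer seed.
#' @param alpha ssGSEA weight exponent.
#' @return List: `aucs` (length `n_iter`), `mean`, `sd`, `quantiles`
#'   (2.5/25/50/75/97.5\%), `n_genes`, `n_iter`.
#' @export
random_signature_null <- function(expression, labels, n_genes = 105,
                                  n_iter = 200, seed = 1L, alpha = 0.25) {
  stopifnot(n_iter >= 1)
  universe <- rownames(expression)
  if (n_genes > length(universe)) {
    stop("n_genes exceeds the gene universe", call. = FALSE)
  }
  set.seed(seed)
  sets <- lapply(seq_len(n_iter), function(i) sample(universe, n_genes))
  names(sets) <- sprintf("rand%04d", seq_len(n_iter))
  scores <- ssgsea_score(expression, sets, alpha = alpha)
  aucs <- apply(scores, 1, function(s) roc_auc(s, labels)$auc)
  list(
    aucs = unname(aucs), mean = mean(aucs), sd = stats::sd(aucs),
    quantiles = stats::quantile(aucs, c(0.025, 0.25, 0.5, 0.75, 0.975)),
    n_genes = n_genes, n_iter = n_iter
  )
}
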