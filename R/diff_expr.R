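#' Median-of-ratios normalization of a count matrix
#'
#' Size factor per sample = median, over genes with nonzero counts in
#' every sample, of the ratio of the gene's count to its geometric mean
#' across samples. Falls back to total-count scaling (with a warning)
#' when no gene is nonzero everywhere. The normalized matrix is
#' `log2(count / size_factor + 1)`.
#'
#' @param counts Nonnegative integer matrix, genes x samples.
#' @return List: `size_factors` (named, geometric mean 1 under
#'   median-of-ratios), `log2_normalized` (matrix of same shape).
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least two samples", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  all_nonzero <- rowSums(counts == 0) == 0
  if (!any(all_nonzero)) {
    warning("no gene with nonzero counts in all samples; ",
            "falling back to total-count scaling")
    sf <- colSums(counts) / mean(colSums(counts))
  } else {
    sub <- counts[all_nonzero, , drop = FALSE]
    gm <- exp(rowMeans(log(sub)))
    sf <- apply(sub / gm, 2, stats::median)
  }
  list(
    size_factors = stats::setNames(sf, colnames(counts)),
    log2_normalized = log2(sweep(counts, 2, sf, "/") + 1)
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment (monotone, capped at 1) after validating the
#' inputs are proper p-values.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same length/order).
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # 0.03 0.03 0.03
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Per-gene two-group differential test on normalized expression
#'
#' Two self-contained tests share one effect estimate (the difference of
#' group means on the normalized log2 scale, group A minus group B):
#'
#' * `"moderated"` (method A): a moderated location test. Gene-wise
#'   pooled variances are shrunk toward the across-gene median with
#'   `d0` prior degrees of freedom
#'   (`s2_mod = (d0 * median(s2) + df * s2) / (d0 + df)`); the moderated
#'   t statistic is referred to a t distribution on `df + d0` degrees of
#'   freedom.
#' * `"ranksum"` (method B): the two-sample Wilcoxon rank-sum test
#'   (exact where sample sizes permit, normal approximation otherwise).
#'
#' @param normalized Log2-normalized matrix from [normalize_counts()].
#' @param groups Two-level factor/character of length `ncol(normalized)`;
#'   the first level is group A.
#' @param method `"moderated"` or `"ranksum"`.
#' @param d0 Prior degrees of freedom for variance shrinkage (default 4).
#' @return data.frame `gene`, `log2fc`, `p`, `padj` (BH), `method`.
#' @export
de_test <- function(normalized, groups, method = c("moderated", "ranksum"),
                    d0 = 4) {
  method <- match.arg(method)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels", call. = FALSE)
  if (length(groups) != ncol(normalized)) {
    stop("groups length must match the number of samples", call. = FALSE)
  }
  a <- groups == levels(groups)[1]
  b <- groups == levels(groups)[2]
  if (sum(a) < 2 || sum(b) < 2) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  xa <- normalized[, a, drop = FALSE]
  xb <- normalized[, b, drop = FALSE]
  n1 <- sum(a); n2 <- sum(b)
  lfc <- rowMeans(xa) - rowMeans(xb)
  if (method == "moderated") {
    df <- n1 + n2 - 2
    s2 <- (apply(xa, 1, stats::var) * (n1 - 1) +
           apply(xb, 1, stats::var) * (n2 - 1)) / df
    s2_0 <- stats::median(s2)
    s2_mod <- (d0 * s2_0 + df * s2) / (d0 + df)
    tstat <- lfc / sqrt(s2_mod * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tstat), df = df + d0)
  } else {
    p <- apply(normalized, 1, function(x) {
      stats::wilcox.test(x[a], x[b])$p.value
    })
  }
  genes <- rownames(normalized)
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(nrow(normalized)))
  data.frame(gene = genes, log2fc = unname(lfc), p = unname(p),
             padj = bh_adjust(unname(p)), method = method,
             stringsAsFactors = FALSE)
}

#' Two-method overlap filter for signature genes
#'
#' Significantly differentially expressed genes are those passing
#' `|log2fc| > lfc`, `p < p_cut` and `padj < padj_cut` in BOTH methods,
#' i.e. the overlap of the two survivor sets. Direction (up in group A /
#' up in group B) is assigned by the sign of the shared fold-change
#' estimate; genes whose sign disagrees between methods are dropped.
#' Output is sorted by decreasing `|log2fc|`.
#'
#' @param res_a,res_b [de_test()] results over the same gene universe.
#' @param lfc,p_cut,padj_cut Thresholds (defaults 1, 0.05, 0.05).
#' @return data.frame `gene`, `log2fc`, `direction` (`"up_in_A"` /
#'   `"up_in_B"`), with the thresholds recorded in
#'   `attr(, "provenance")`.
#' @export
overlap_filter <- function(res_a, res_b, lfc = 1, p_cut = 0.05,
                           padj_cut = 0.05) {
  if (!setequal(res_a$gene, res_b$gene)) {
    stop("the two results must cover the same gene universe", call. = FALSE)
  }
  res_b <- res_b[match(res_a$gene, res_b$gene), , drop = FALSE]
  pass <- function(r) abs(r$log2fc) > lfc & r$p < p_cut & r$padj < padj_cut
  keep <- pass(res_a) & pass(res_b) & sign(res_a$log2fc) == sign(res_b$log2fc)
  out <- data.frame(
    gene = res_a$gene[keep], log2fc = res_a$log2fc[keep],
    direction = ifelse(res_a$log2fc[keep] > 0, "up_in_A", "up_in_B"),
    stringsAsFactors = FALSE
  )
  out <- out[order(-abs(out$log2fc)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- list(lfc = lfc, p = p_cut, padj = padj_cut)
  out
}

#' Intersect signature genes with pathway gene sets
#'
#' Builds per-pathway drug-mechanism signatures (signature genes falling
#' in each pathway set) and their combined union, the gene cohort used
#' for sensitivity scoring.
#'
#' @param sig_genes Character vector of signature genes, or the
#'   data.frame from [overlap_filter()].
#' @param pathway_sets Named list of pathway gene vectors (e.g. parsed
#'   from GMT).
#' @return List of class `gene_signature`: `per_pathway` (named list),
#'   `combined` (union), `counts` (per-pathway sizes plus `combined`).
#' @export
assemble_pathway_signature <- function(sig_genes, pathway_sets) {
  if (is.data.frame(sig_genes)) sig_genes <- sig_genes$gene
  if (length(pathway_sets) == 0 || any(lengths(pathway_sets) == 0)) {
    stop("pathway sets must be nonempty", call. = FALSE)
  }
  per <- lapply(pathway_sets, function(set) intersect(sig_genes, set))
  combined <- Reduce(union, per, character(0))
  if (length(combined) == 0) {
    warning("signature genes intersect no pathway set; combined signature is empty")
  }
  structure(list(
    per_pathway = per, combined = combined,
    counts = c(lengths(per), combined = length(combined))
  ), class = "gene_signature")
}
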