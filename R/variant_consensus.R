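variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

#' Merge per-caller somatic call sets with the >= 2-caller rule
#'
#' Only mutations detected by at least `min_callers` independent callers
#' are kept as true positives. Variants are keyed by
#' (chrom, pos, ref, alt); per-caller sets are deduplicated on the key
#' first. Annotations for a consensus variant are taken from the caller
#' reporting the greatest tumor depth (ties broken by caller name order).
#'
#' @param callsets List of >= 2 per-caller data.frames (columns `chrom`,
#'   `pos`, `ref`, `alt` plus annotations).
#' @param min_callers Minimum supporting callers (default 2).
#' @return Consensus data.frame with an added `n_callers` column.
#' @export
merge_callers <- function(callsets, min_callers = 2) {
  if (!is.list(callsets) || length(callsets) < 2) {
    stop("need call sets from at least two callers", call. = FALSE)
  }
  stopifnot(min_callers >= 1)
  if (is.null(names(callsets))) names(callsets) <- paste0("caller", seq_along(callsets))
  dedup <- lapply(callsets, function(cs) cs[!duplicated(variant_key(cs)), , drop = FALSE])
  all_rows <- do.call(rbind, lapply(names(dedup), function(nm) {
    cs <- dedup[[nm]]
    if (nrow(cs) == 0) return(NULL)
    cs$.caller <- nm
    cs$.key <- variant_key(cs)
    cs
  }))
  if (is.null(all_rows) || nrow(all_rows) == 0) {
    out <- callsets[[1]][0, , drop = FALSE]
    out$n_callers <- integer(0)
    return(out)
  }
  support <- table(all_rows$.key)
  keep_keys <- names(support)[support >= min_callers]
  kept <- all_rows[all_rows$.key %in% keep_keys, , drop = FALSE]
  if (nrow(kept) == 0) {
    out <- callsets[[1]][0, , drop = FALSE]
    out$n_callers <- integer(0)
    return(out)
  }
  # provenance: record with max t_depth wins; stable caller-name order breaks ties
  kept <- kept[order(kept$.key, -kept$t_depth, kept$.caller), , drop = FALSE]
  out <- kept[!duplicated(kept$.key), , drop = FALSE]
  out$n_callers <- as.integer(support[out$.key])
  out$.key <- NULL
  out$.caller <- NULL
  rownames(out) <- NULL
  out
}

#' Somatic variant filter configuration
#'
#' Defaults follow the high-confidence filter cascade: population minor
#' allele frequency below 0.0004, tumor total depth over 20,
#' alteration-supporting reads over 3, no alternate-supporting reads in
#' the matched normal, and variant allele fraction over 5\%. All
#' comparisons are strict. The normal-read clause is interpreted as
#' alternate-supporting reads in the normal < 1 (`normal_clause =
#' "n_alt"`); the literal reading (reference-supporting reads < 1) is kept
#' available as `normal_clause = "ref_reads"`.
#'
#' @param max_pop_af Population allele frequency bound (exclusive).
#' @param min_t_depth Tumor total depth bound (exclusive).
#' @param min_t_alt Tumor alternate-read bound (exclusive).
#' @param max_n_alt Normal alternate-read bound (exclusive upper).
#' @param min_vaf Tumor variant allele fraction bound (exclusive).
#' @param min_callers Minimum supporting callers.
#' @param normal_clause `"n_alt"` or `"ref_reads"` (see above).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(max_pop_af = 0.0004, min_t_depth = 20,
                          min_t_alt = 3, max_n_alt = 1, min_vaf = 0.05,
                          min_callers = 2, normal_clause = c("n_alt", "ref_reads")) {
  normal_clause <- match.arg(normal_clause)
  cfg <- list(max_pop_af = max_pop_af, min_t_depth = min_t_depth,
              min_t_alt = min_t_alt, max_n_alt = max_n_alt, min_vaf = min_vaf,
              min_callers = min_callers, normal_clause = normal_clause)
  if (any(unlist(cfg[1:6]) < 0)) stop("thresholds must be nonnegative", call. = FALSE)
  structure(cfg, class = "filter_config")
}

#' Apply the somatic variant filter cascade
#'
#' Retains variants with `pop_af < max_pop_af`, `t_depth > min_t_depth`,
#' `t_alt > min_t_alt`, `n_alt < max_n_alt` and `vaf > min_vaf`
#' (conjunction of independent predicates, hence idempotent and
#' order-free). Variants with any required annotation missing are
#' rejected with reason `missing_annotation`. When a low-mappability mask
#' is supplied (BED intervals, 0-based half-open), variants falling inside
#' a masked interval are removed with reason `low_mappability`.
#'
#' @param consensus Consensus data.frame from [merge_callers()].
#' @param config A [filter_config()].
#' @param mask Optional BED mask data.frame (`chrom`, `start`, `end`).
#' @return Filtered data.frame; rejected variants with their first failing
#'   reason are attached as `attr(, "rejected")`.
#' @export
apply_filters <- function(consensus, config = filter_config(), mask = NULL) {
  stopifnot(inherits(config, "filter_config"))
  need <- c("pop_af", "t_depth", "t_alt", "n_alt", "vaf")
  missing_col <- setdiff(need, names(consensus))
  if (length(missing_col)) {
    stop("consensus table lacks annotation columns: ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  if (nrow(consensus) == 0) {
    attr(consensus, "rejected") <- cbind(consensus, reason = character(0))
    return(consensus)
  }
  reason <- rep(NA_character_, nrow(consensus))
  incomplete <- !stats::complete.cases(consensus[need])
  reason[incomplete] <- "missing_annotation"
  normal_fail <- if (config$normal_clause == "n_alt") {
    !(consensus$n_alt < config$max_n_alt)
  } else {
    !((consensus$t_depth - consensus$t_alt) < 1)
  }
  checks <- list(
    pop_af = !(consensus$pop_af < config$max_pop_af),
    depth = !(consensus$t_depth > config$min_t_depth),
    alt_reads = !(consensus$t_alt > config$min_t_alt),
    normal_alt = normal_fail,
    vaf = !(consensus$vaf > config$min_vaf)
  )
  for (nm in names(checks)) {
    hit <- is.na(reason) & checks[[nm]] & !incomplete
    reason[hit] <- nm
  }
  if (!is.null(mask) && nrow(mask) > 0) {
    masked <- mapply(bed_overlaps, consensus$chrom, consensus$pos,
                     MoreArgs = list(bed = mask))
    reason[is.na(reason) & masked] <- "low_mappability"
  }
  keep <- is.na(reason)
  out <- consensus[keep, , drop = FALSE]
  rej <- consensus[!keep, , drop = FALSE]
  rej$reason <- reason[!keep]
  rownames(out) <- NULL
  rownames(rej) <- NULL
  attr(out, "rejected") <- rej
  out
}

#' Does a 1-based position fall in any BED interval?
#'
#' BED intervals are 0-based half-open `[start, end)`; a 1-based variant
#' position `pos` overlaps iff `start < pos <= end`.
#'
#' @param bed data.frame `chrom`, `start`, `end`.
#' @param chrom,pos Variant coordinate (1-based).
#' @return Logical.
#' @export
bed_overlaps <- function(bed, chrom, pos) {
  any(bed$chrom == chrom & bed$start < pos & pos <= bed$end)
}

#' Per-sample mutation burden and consequence-class summary
#'
#' @param filtered Filtered consensus data.frame with `sample` (and
#'   optionally `consequence`) columns.
#' @param sample_ids All cohort sample identifiers (samples with no
#'   surviving variants count as zero).
#' @return List: `per_sample` (data.frame `sample`, `n`), `total`,
#'   `mean_per_sample` (total / n_samples, rounded to 1 decimal for
#'   reporting), `by_class` (named counts, summing to `total`).
#' @export
#' @examples
#' # 2662 mutations over 88 paired tumors -> 30.3 per sample
#' round(2662 / 88, 1)
burden_summary <- function(filtered, sample_ids) {
  if (length(sample_ids) == 0) stop("sample list must be non-empty", call. = FALSE)
  if (nrow(filtered) > 0 && is.null(filtered$sample)) {
    stop("every variant must carry a sample assignment", call. = FALSE)
  }
  counts <- table(factor(filtered$sample, levels = sample_ids))
  if (nrow(filtered) > 0 && any(!filtered$sample %in% sample_ids)) {
    stop("variant assigned to a sample outside `sample_ids`", call. = FALSE)
  }
  total <- nrow(filtered)
  by_class <- if (!is.null(filtered$consequence)) {
    tab <- table(filtered$consequence)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  list(
    per_sample = data.frame(sample = names(counts), n = as.integer(counts),
                            stringsAsFactors = FALSE),
    total = total,
    mean_per_sample = round_half_up(total / length(sample_ids), 1),
    by_class = by_class
  )
}

#' Per-gene mutation frequency across a cohort
#'
#' Fraction of cohort patients carrying at least one variant in each gene,
#' as a percentage (e.g. a gene mutated in 1 of 106 patients has
#' frequency 0.94\%).
#'
#' @param variants Variant data.frame with `gene` and `sample` columns.
#' @param n_cohort Cohort size (denominator).
#' @param digits Decimal digits (default 2).
#' @return data.frame `gene`, `n_samples`, `frequency_pct`, sorted by
#'   descending frequency.
#' @export
gene_frequencies <- function(variants, n_cohort, digits = 2) {
  stopifnot(n_cohort >= 1)
  if (nrow(variants) == 0) {
    return(data.frame(gene = character(), n_samples = integer(),
                      frequency_pct = numeric()))
  }
  per_gene <- tapply(variants$sample, variants$gene,
                     function(s) length(unique(s)))
  out <- data.frame(gene = names(per_gene), n_samples = as.integer(per_gene),
                    frequency_pct = percent_of(as.integer(per_gene), n_cohort,
                                               digits),
                    stringsAsFactors = FALSE)
  out[order(-out$frequency_pct, out$gene), , drop = FALSE]
}

# --- 96-context trinucleotide catalog -------------------------------------

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp3 <- function(ctx) {
  vapply(strsplit(ctx, ""), function(b) paste(rev(unname(COMPLEMENT[b])), collapse = ""), "")
}

#' Canonical 96 trinucleotide substitution classes
#'
#' Pyrimidine-centered convention: six substitution types (C>A, C>G, C>T,
#' T>A, T>C, T>G) by 16 flanking-base combinations, in the conventional
#' lexicographic order (`A[C>A]A`, `A[C>A]C`, ...).
#'
#' @return Character vector of 96 class labels.
#' @export
context_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(l, r) paste0(l, "[", s, "]", r))))
  }))
}

#' Build a 96-context mutational catalog from SNVs
#'
#' Classifies each single-nucleotide variant by substitution type and
#' flanking reference bases; purine-centered substitutions are
#' reverse-complemented into the pyrimidine convention. Indels and
#' multi-nucleotide variants are ignored; SNVs whose context cannot be
#' resolved (absent from the lookup, or middle base disagreeing with the
#' reference allele) are rejected and counted.
#'
#' @param snvs Variant data.frame (`chrom`, `pos`, `ref`, `alt`).
#' @param context_lookup Either a data.frame (`chrom`, `pos`, `context`)
#'   giving the reference trinucleotide at each site, or a function
#'   `(chrom, pos) -> context`.
#' @return Named integer 96-vector in [context_classes()] order; the
#'   number of unresolvable SNVs is attached as `attr(, "n_rejected")`.
#' @export
trinucleotide_contexts <- function(snvs, context_lookup) {
  classes <- context_classes()
  catalog <- stats::setNames(integer(96), classes)
  is_snv <- nchar(snvs$ref) == 1 & nchar(snvs$alt) == 1 &
    snvs$ref %in% names(COMPLEMENT) & snvs$alt %in% names(COMPLEMENT) &
    snvs$ref != snvs$alt
  snvs <- snvs[is_snv, , drop = FALSE]
  n_rejected <- 0L
  if (nrow(snvs) > 0) {
    ctx <- if (is.function(context_lookup)) {
      mapply(context_lookup, snvs$chrom, snvs$pos)
    } else {
      context_lookup$context[match(paste(snvs$chrom, snvs$pos),
                                   paste(context_lookup$chrom, context_lookup$pos))]
    }
    for (i in seq_len(nrow(snvs))) {
      tri <- ctx[i]
      ref <- snvs$ref[i]
      alt <- snvs$alt[i]
      if (is.na(tri) || nchar(tri) != 3 || substr(tri, 2, 2) != ref) {
        n_rejected <- n_rejected + 1L
        next
      }
      if (ref %in% c("A", "G")) { # collapse to pyrimidine strand
        tri <- revcomp3(tri)
        ref <- unname(COMPLEMENT[ref])
        alt <- unname(COMPLEMENT[alt])
      }
      label <- paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]", substr(tri, 3, 3))
      catalog[label] <- catalog[label] + 1L
    }
  }
  attr(catalog, "n_rejected") <- n_rejected
  catalog
}

#' Refit a mutational catalog against reference signatures
#'
#' Nonnegative least squares of the (optionally exome-to-genome
#' rescaled) catalog fractions onto reference signature columns. Weights
#' are rescaled to exposures summing to at most 1; the reconstruction is
#' scored by cosine similarity. An exact nonnegative mixture of reference
#' columns is recovered with cosine similarity 1.
#'
#' @param catalog Named 96-vector of context counts (total > 0).
#' @param reference 96 x k matrix; each column a reference signature
#'   summing to 1 (rows in [context_classes()] order).
#' @param normalization `"none"` or `"exome2genome"`; the latter
#'   multiplies each context count by the genome/exome trinucleotide
#'   frequency ratio before fitting.
#' @param ratio Length-96 genome/exome ratio vector (required for
#'   `"exome2genome"`; all-ones reproduces `"none"`).
#' @return List of class `signature_fit`: `weights` (named, nonnegative,
#'   summing to <= 1), `cosine`, `fitted` (reconstructed fractions).
#' @export
refit_signatures <- function(catalog, reference,
                             normalization = c("none", "exome2genome"),
                             ratio = NULL) {
  normalization <- match.arg(normalization)
  if (sum(catalog) <= 0) stop("catalog is empty; nothing to refit", call. = FALSE)
  reference <- as.matrix(reference)
  stopifnot(nrow(reference) == length(catalog))
  colsum <- colSums(reference)
  if (any(abs(colsum - 1) > 1e-6)) {
    stop("reference signature columns must each sum to 1", call. = FALSE)
  }
  x <- as.numeric(catalog)
  if (normalization == "exome2genome") {
    if (is.null(ratio) || length(ratio) != length(x)) {
      stop("exome2genome normalization needs a length-96 ratio vector", call. = FALSE)
    }
    x <- x * ratio
  }
  x <- x / sum(x)
  w <- pracma::lsqnonneg(reference, x)$x
  fitted <- as.numeric(reference %*% w)
  cosine <- sum(x * fitted) / sqrt(sum(x^2) * sum(fitted^2))
  if (sum(w) > 1) w <- w / sum(w)
  structure(list(
    weights = stats::setNames(w, colnames(reference)),
    cosine = cosine, fitted = fitted
  ), class = "signature_fit")
}

#' Synthetic reference signature matrix
#'
#' A synthetic stand-in for a reference mutational-signature catalog:
#' `k` sparse probability columns over the 96 trinucleotide classes,
#' each concentrated on a random subset of contexts (gamma draws zeroed
#' outside the subset, normalized to 1). Deterministic given the seed.
#'
#' @param k Number of signatures (default 5).
#' @param seed Integer seed (default 42).
#' @param sparsity Fraction of contexts active per signature.
#' @return 96 x k matrix, rows named by [context_classes()], columns
#'   `SigS1...SigSk`.
#' @export
synthetic_reference_signatures <- function(k = 5, seed = 42, sparsity = 0.25) {
  set.seed(seed)
  classes <- context_classes()
  m <- sapply(seq_len(k), function(j) {
    w <- stats::rgamma(96, shape = 0.5)
    off <- sample.int(96, round(96 * (1 - sparsity)))
    w[off] <- 0
    if (sum(w) == 0) w[sample.int(96, 5)] <- 1
    w / sum(w)
  })
  dimnames(m) <- list(classes, paste0("SigS", seq_len(k)))
  m
}
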