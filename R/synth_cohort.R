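#' Default NPC subtype fractions
#'
#' Subtype mix of the reference cohort: 57/106 epithelial carcinoma (EC),
#' 26/106 mixed sarcomatoid-epithelial (MSEC), 20/106 sarcomatoid (SC) and
#' 3/106 squamous cell carcinoma (SCC).
#'
#' @return Named numeric vector of fractions summing to 1.
#' @export
npc_subtype_fractions <- function() {
  c(EC = 57, MSEC = 26, SC = 20, SCC = 3) / 106
}

#' Default six-point drug dose grid
#'
#' Six concentrations spanning 0.08--20 uM at 3-fold dilutions, the design
#' used for all organoid drug screens. The top dose is exactly 20 uM; lower
#' doses are 20/3^k, so the bottom dose (0.0823 uM) matches the nominal
#' 0.08 uM range limit used for IC50 censoring.
#'
#' @return Numeric vector of 6 strictly increasing doses (uM).
#' @export
dose_grid_default <- function() signif(20 / 3^(5:0), 4)

#' Generate a synthetic patient cohort with fixed subtype proportions
#'
#' Subtype counts are the largest-remainder rounding of `n_patients *
#' subtype_fractions`, so they sum exactly to `n_patients` and match the
#' requested fractions to within rounding. Organoid establishment
#' (`has_pdo`) is Bernoulli with the cohort establishment rate.
#'
#' @param n_patients Number of patients (>= 1).
#' @param subtype_fractions Named fractions summing to 1 (default
#'   [npc_subtype_fractions()]).
#' @param pdo_rate Probability a patient yields an organoid line
#'   (default 40/43).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return data.frame with columns `patient_id`, `subtype` (factor),
#'   `has_pdo`.
#' @export
#' @examples
#' tab <- gen_cohort(106, seed = 1)
#' table(tab$subtype) # EC 57, MSEC 26, SC 20, SCC 3
gen_cohort <- function(n_patients, subtype_fractions = npc_subtype_fractions(),
                       pdo_rate = 40 / 43, seed = 1L) {
  stopifnot(n_patients >= 1)
  if (is.null(names(subtype_fractions)) || any(names(subtype_fractions) == "")) {
    stop("subtype_fractions must be named", call. = FALSE)
  }
  if (abs(sum(subtype_fractions) - 1) > 1e-9) {
    stop("subtype_fractions must sum to 1 (got ", sum(subtype_fractions), ")", call. = FALSE)
  }
  check_fraction(pdo_rate, "pdo_rate")
  counts <- largest_remainder(n_patients * subtype_fractions)
  set.seed(seed)
  subtype <- sample(rep(names(counts), counts))
  data.frame(
    patient_id = sprintf("P%04d", seq_len(n_patients)),
    subtype = factor(subtype, levels = names(subtype_fractions)),
    has_pdo = stats::runif(n_patients) < pdo_rate,
    stringsAsFactors = FALSE
  )
}

# largest-remainder (Hare) rounding: floor everything, hand the leftover
# units to the largest fractional parts; ties broken by input order
largest_remainder <- function(x) {
  f <- floor(x)
  r <- sum(x) - sum(f)
  extra <- utils::head(order(x - f, decreasing = TRUE), round(r))
  f[extra] <- f[extra] + 1
  stats::setNames(as.integer(f), names(x))
}

#' Subtype proportions of a cohort, as percentages
#'
#' @param cohort data.frame from [gen_cohort()].
#' @param digits Decimal digits (default 2, matching cohort reports such as
#'   53.77\% EC).
#' @return Named numeric vector of percentages.
#' @export
subtype_proportions <- function(cohort, digits = 2) {
  tab <- table(cohort$subtype)
  stats::setNames(percent_of(as.numeric(tab), nrow(cohort), digits), names(tab))
}

#' Four-parameter log-logistic viability curve
#'
#' Expected percent viability at dose `d`:
#' `bottom + (top - bottom) / (1 + (d / ic50)^hill)`.
#'
#' @param dose Dose vector (uM, > 0).
#' @param ic50 Half-maximal concentration (uM).
#' @param hill Hill slope (positive for viability decreasing with dose).
#' @param top,bottom Upper/lower viability asymptotes (\%).
#' @return Expected viability (\% of control).
#' @export
four_pl <- function(dose, ic50, hill = 1, top = 100, bottom = 0) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Simulate a viability plate for one sample/treatment arm
#'
#' Viability follows a four-parameter log-logistic curve in the dose;
#' replicate noise is additive Gaussian on the percent scale, truncated at
#' 0 (negative luminescence-derived viabilities do not occur).
#'
#' @param truth List with `ic50`, `hill`, `top`, `bottom` (the simulated
#'   ground truth; defaults `hill = 1`, `top = 100`, `bottom = 0`).
#' @param doses Strictly increasing positive doses (default
#'   [dose_grid_default()]).
#' @param n_reps Replicates per dose (default 3, the usual biological
#'   replicate count).
#' @param noise_sd Replicate noise SD in viability percentage points.
#' @param seed Integer seed.
#' @param sample,drug,ir_gy Identifiers carried into the tidy plate table.
#' @return data.frame (`sample`, `drug`, `dose_uM`, `ir_gy`, `replicate`,
#'   `viability_pct`) with the ground truth attached as `attr(, "truth")`.
#' @export
gen_dose_response <- function(truth, doses = dose_grid_default(), n_reps = 3,
                              noise_sd = 5, seed = 1L, sample = "S1",
                              drug = "drug", ir_gy = 0) {
  truth <- complete_truth(truth)
  if (length(doses) == 0) stop("dose list must be non-empty", call. = FALSE)
  if (any(doses <= 0) || is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be positive and strictly increasing", call. = FALSE)
  }
  stopifnot(noise_sd >= 0, n_reps >= 1)
  expected <- four_pl(doses, truth$ic50, truth$hill, truth$top, truth$bottom)
  set.seed(seed)
  out <- data.frame(
    sample = sample, drug = drug,
    dose_uM = rep(doses, each = n_reps), ir_gy = ir_gy,
    replicate = rep(seq_len(n_reps), times = length(doses)),
    viability_pct = pmax(0, rep(expected, each = n_reps) +
      stats::rnorm(length(doses) * n_reps, 0, noise_sd)),
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- c(truth, list(noise_sd = noise_sd, seed = seed))
  out
}

complete_truth <- function(truth) {
  stopifnot(is.list(truth), !is.null(truth$ic50), truth$ic50 > 0)
  truth$hill <- if (is.null(truth$hill)) 1 else truth$hill
  truth$top <- if (is.null(truth$top)) 100 else truth$top
  truth$bottom <- if (is.null(truth$bottom)) 0 else truth$bottom
  stopifnot(truth$bottom <= truth$top)
  truth
}

#' Simulate the combination (drug + IR) arm of a chemoradiotherapy screen
#'
#' The expected combination inhibition at each dose is the Bliss-additive
#' prediction from the mono drug curve and the fixed IR inhibition, plus a
#' `synergy_offset` (positive = more killing than additive), clipped to
#' `[0, 1]`. With `synergy_offset = 0` and no noise the output satisfies
#' Bliss additivity exactly.
#'
#' @param mono_truth Drug-alone ground truth (as in [gen_dose_response()]).
#' @param ir_inhibition Inhibition fraction of IR alone at the screen dose
#'   (4 Gy), in `[-1, 1]`.
#' @param synergy_offset Added inhibition fraction beyond additivity, in
#'   `[-1, 1]`.
#' @inheritParams gen_dose_response
#' @return Combination-arm plate data.frame as in [gen_dose_response()]
#'   (with `ir_gy = 4`); `attr(, "truth")` records the offset and the
#'   additive inhibition per dose.
#' @export
gen_combo_screen <- function(mono_truth, ir_inhibition, synergy_offset = 0,
                             doses = dose_grid_default(), n_reps = 3,
                             noise_sd = 5, seed = 1L, sample = "S1",
                             drug = "drug") {
  check_fraction(ir_inhibition, "ir_inhibition", -1, 1)
  check_fraction(synergy_offset, "synergy_offset", -1, 1)
  mono_truth <- complete_truth(mono_truth)
  if (length(doses) == 0) stop("dose list must be non-empty", call. = FALSE)
  e2 <- clip(1 - four_pl(doses, mono_truth$ic50, mono_truth$hill,
                         mono_truth$top, mono_truth$bottom) / 100, 0, 1)
  e1 <- clip(ir_inhibition, 0, 1)
  e_add <- bliss_additive(rep(e1, length(e2)), e2)
  e_combo <- clip(e_add + synergy_offset, 0, 1)
  expected <- 100 * (1 - e_combo)
  set.seed(seed)
  out <- data.frame(
    sample = sample, drug = drug,
    dose_uM = rep(doses, each = n_reps), ir_gy = 4,
    replicate = rep(seq_len(n_reps), times = length(doses)),
    viability_pct = pmax(0, rep(expected, each = n_reps) +
      stats::rnorm(length(doses) * n_reps, 0, noise_sd)),
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- list(
    mono = mono_truth, ir_inhibition = ir_inhibition,
    synergy_offset = synergy_offset, additive_inhibition = e_add,
    combo_inhibition = e_combo, noise_sd = noise_sd, seed = seed
  )
  out
}

#' Simulate per-caller somatic call sets with known truth
#'
#' Emulates the output of three independent somatic SNV callers for the
#' consensus stage. Every true variant is emitted by at least two callers;
#' every false positive is private to a single caller, so the precision of
#' the >= 2-caller consensus rule is exactly 1 by construction and recall
#' equals the fraction of true variants surviving annotation filters.
#'
#' Annotations are drawn truth-dependently: true somatic variants get deep
#' coverage, clean normals and zero population frequency; false positives
#' get shallow/low-VAF support and occasionally a nonzero population
#' frequency, so the downstream filter cascade has signal to work with.
#'
#' @param n_true Number of true somatic variants.
#' @param fp_per_caller Integer vector (one per caller) of caller-private
#'   false positives.
#' @param sample_ids Sample labels the variants are distributed over.
#' @param depth_model List of annotation distribution parameters; see
#'   defaults in the source (`mean_depth`, `vaf_shape`, `fp_pop_af_rate`,
#'   ...).
#' @param callers Caller names (default `callerA/B/C`).
#' @param seed Integer seed.
#' @return List: `callsets` (named list of per-caller data.frames in the
#'   VCF-like TSV layout), `truth` (data.frame with `key`, `is_true`),
#'   `context_lookup` (data.frame `chrom`, `pos`, `context` giving the
#'   reference trinucleotide at each site).
#' @export
gen_caller_callsets <- function(n_true, fp_per_caller = c(5, 5, 5),
                                sample_ids = "S1",
                                depth_model = list(), seed = 1L,
                                callers = c("callerA", "callerB", "callerC")) {
  stopifnot(n_true >= 0, all(fp_per_caller >= 0),
            length(fp_per_caller) == length(callers), length(callers) >= 2)
  dm <- utils::modifyList(list(
    mean_depth = 80, min_depth = 30, vaf_a = 8, vaf_b = 20,
    fp_mean_depth = 18, fp_vaf_a = 1.5, fp_vaf_b = 40, fp_pop_af_rate = 0.3
  ), depth_model)
  set.seed(seed)
  n_fp <- sum(fp_per_caller)
  n_all <- n_true + n_fp
  bases <- c("A", "C", "G", "T")
  make_sites <- function(n) {
    if (n == 0) {
      return(data.frame(chrom = character(), pos = integer(), ref = character(),
                        alt = character(), stringsAsFactors = FALSE))
    }
    chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
    pos <- sample.int(5e7, n) # sparse genome: collisions vanishingly rare
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
               stringsAsFactors = FALSE)
  }
  sites <- make_sites(n_all)
  sites <- sites[!duplicated(paste(sites$chrom, sites$pos)), , drop = FALSE]
  while (nrow(sites) < n_all) {
    sites <- rbind(sites, make_sites(n_all - nrow(sites)))
    sites <- sites[!duplicated(paste(sites$chrom, sites$pos)), , drop = FALSE]
  }
  sites$key <- with(sites, paste(chrom, pos, ref, alt, sep = ":"))
  sites$is_true <- seq_len(n_all) <= n_true
  sites$sample <- sample(sample_ids, n_all, replace = TRUE)
  # consequence classes follow the observed exome-wide class mix
  cls <- c(missense = 2306, nonsense = 191, splice_site = 47,
           frameshift_del = 51, inframe_del = 31, frameshift_ins = 23,
           inframe_ins = 8, other = 5)
  sites$consequence <- sample(names(cls), n_all, replace = TRUE, prob = cls)
  sites$gene <- sprintf("GENE%04d", sample.int(2500, n_all, replace = TRUE))
  # reference trinucleotide context at each site (middle base = ref)
  flank <- function(n) sample(bases, n, replace = TRUE)
  sites$context <- paste0(flank(n_all), sites$ref, flank(n_all))

  annotate <- function(idx, true) {
    n <- length(idx)
    if (true) {
      t_depth <- dm$min_depth + stats::rpois(n, dm$mean_depth - dm$min_depth)
      vaf_true <- stats::rbeta(n, dm$vaf_a, dm$vaf_b)
      t_alt <- pmax(4L, stats::rbinom(n, t_depth, vaf_true))
      n_alt <- integer(n)
      pop_af <- numeric(n)
    } else {
      t_depth <- pmax(5L, stats::rpois(n, dm$fp_mean_depth))
      vaf_true <- stats::rbeta(n, dm$fp_vaf_a, dm$fp_vaf_b)
      t_alt <- stats::rbinom(n, t_depth, pmax(vaf_true, 0.02))
      n_alt <- stats::rbinom(n, 30, 0.03)
      pop_af <- ifelse(stats::runif(n) < dm$fp_pop_af_rate,
                       stats::runif(n, 5e-4, 1e-2), 0)
    }
    cbind(sites[idx, c("chrom", "pos", "ref", "alt", "sample", "consequence",
                       "gene", "context")],
          data.frame(t_depth = t_depth, t_alt = t_alt, n_alt = n_alt,
                     pop_af = pop_af, vaf = t_alt / t_depth))
  }

  callsets <- stats::setNames(vector("list", length(callers)), callers)
  for (cl in callers) {
    callsets[[cl]] <- data.frame(
      chrom = character(), pos = integer(), ref = character(), alt = character(),
      sample = character(), consequence = character(), gene = character(),
      context = character(), t_depth = integer(), t_alt = integer(),
      n_alt = integer(), pop_af = numeric(), vaf = numeric(),
      stringsAsFactors = FALSE
    )
  }
  if (n_true > 0) {
    ann_true <- annotate(seq_len(n_true), TRUE)
    for (i in seq_len(n_true)) {
      k <- sample(2:length(callers), 1)
      who <- sample(callers, k)
      for (cl in who) {
        rec <- ann_true[i, , drop = FALSE]
        # per-caller depth jitter so merge provenance (max t_depth) is exercised
        rec$t_depth <- rec$t_depth + sample(-3:3, 1)
        rec$t_alt <- pmin(rec$t_alt, rec$t_depth)
        rec$vaf <- rec$t_alt / rec$t_depth
        callsets[[cl]] <- rbind(callsets[[cl]], rec)
      }
    }
  }
  if (n_fp > 0) {
    fp_idx <- n_true + seq_len(n_fp)
    owner <- rep(callers, fp_per_caller)
    ann_fp <- annotate(fp_idx, FALSE)
    for (j in seq_len(n_fp)) {
      callsets[[owner[j]]] <- rbind(callsets[[owner[j]]], ann_fp[j, , drop = FALSE])
    }
  }
  for (cl in callers) {
    callsets[[cl]]$caller <- cl
    rownames(callsets[[cl]]) <- NULL
  }
  list(
    callsets = callsets,
    truth = data.frame(key = sites$key, is_true = sites$is_true,
                       sample = sites$sample, stringsAsFactors = FALSE),
    context_lookup = sites[c("chrom", "pos", "context")],
    seed = seed
  )
}

#' Simulate a bulk expression count matrix with subtype-structured signal
#'
#' Negative-binomial counts for two sample groups (EC-like vs SC-like)
#' with designated signature gene blocks shifted by `group_log2fc` in
#' their group, gene-wise dispersions drawn log-uniformly, and library
#' sizes spanning at least 2-fold. A continuous IC50 phenotype is a noisy
#' monotone function of each sample's true signature activity, emulating
#' subtype-linked drug resistance.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param signature_sets Named list with elements `up_in_A` and `up_in_B`:
#'   gene names (subsets of `g0001...`) shifted up in group A / group B.
#'   Defaults to two disjoint 60-gene blocks.
#' @param group_log2fc Log2 shift applied to signature genes in their group.
#' @param dispersion Either a single NB dispersion or a range `c(lo, hi)`
#'   sampled log-uniformly per gene (default `c(0.05, 0.4)`).
#' @param ic50_link Monotone map from signature activity to IC50 (uM);
#'   default `function(a) 1.5 * 2^a`, so high group-A activity means
#'   resistance.
#' @param ic50_noise_sd SD of log2 multiplicative noise on the phenotype.
#' @param seed Integer seed.
#' @return List: `counts` (genes x samples integer matrix), `phenotype`
#'   (data.frame `sample`, `group`, `activity`, `ic50`), `signature_sets`,
#'   `truth` (per-gene true log2 fold changes and dispersions, seed).
#' @export
gen_expression <- function(n_genes = 2000, n_samples = 14,
                           signature_sets = NULL, group_log2fc = 3,
                           dispersion = c(0.05, 0.4),
                           ic50_link = function(a) 1.5 * 2^a,
                           ic50_noise_sd = 0.25, seed = 1L) {
  stopifnot(n_genes >= 10, n_samples >= 4, is.finite(group_log2fc))
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (is.null(signature_sets)) {
    signature_sets <- list(up_in_A = genes[1:60], up_in_B = genes[61:120])
  }
  stopifnot(all(unlist(signature_sets) %in% genes))
  samples <- sprintf("PDO%02d", seq_len(n_samples))
  group <- rep(c("A", "B"), length.out = n_samples)
  base_mu <- exp(stats::runif(n_genes, log(20), log(2000)))
  disp <- if (length(dispersion) == 2) {
    exp(stats::runif(n_genes, log(dispersion[1]), log(dispersion[2])))
  } else rep(dispersion, n_genes)
  lfc <- numeric(n_genes) # true log2fc, group A vs B
  lfc[genes %in% signature_sets$up_in_A] <- group_log2fc
  lfc[genes %in% signature_sets$up_in_B] <- -group_log2fc
  # library sizes: geometric ladder spanning > 2-fold, shuffled
  libf <- sample(2^seq(-0.6, 0.6, length.out = n_samples))
  mu <- outer(base_mu, libf) * 2^(outer(lfc, ifelse(group == "A", 0.5, -0.5)))
  counts <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu,
                                  size = rep(1 / disp, n_samples)),
                   n_genes, n_samples, dimnames = list(genes, samples))
  # per-sample signature activity: group effect plus biological scatter
  activity <- ifelse(group == "A", 0.5, -0.5) * group_log2fc +
    stats::rnorm(n_samples, 0, 0.25)
  ic50 <- ic50_link(activity) * 2^stats::rnorm(n_samples, 0, ic50_noise_sd)
  list(
    counts = counts,
    phenotype = data.frame(sample = samples, group = group,
                           activity = activity, ic50 = ic50,
                           stringsAsFactors = FALSE),
    signature_sets = signature_sets,
    truth = list(log2fc = stats::setNames(lfc, genes),
                 dispersion = stats::setNames(disp, genes),
                 library_factor = stats::setNames(libf, samples),
                 group_log2fc = group_log2fc, seed = seed)
  )
}
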