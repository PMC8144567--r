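#' Pipeline configuration with study defaults
#'
#' One serializable object holding every tunable threshold of the
#' pipeline, defaulting to the study's printed values where one exists:
#' the 106-patient subtype mix, the six-dose 0.08--20 uM screen with 3
#' replicates, 4 Gy IR with Bliss additivity, the IC50 fold-change cutoff
#' of 3, the somatic filter cascade (pop AF < 0.0004, depth > 20, alt
#' reads > 3, normal alt < 1, VAF > 5\%, >= 2 callers), DE thresholds
#' (|log2FC| > 1, p < 0.05, padj < 0.05, two-method overlap), the
#' bottom/top-10\% IC50 labeling quantile, and ssGSEA alpha 0.25.
#'
#' @param seed Global seed, fanned out per stage via [stage_seed()].
#' @param ... Overrides for any default field.
#' @return List of class `npcpgx_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_patients = 106,
    subtype_fractions = as.list(npc_subtype_fractions()),
    pdo_rate = 40 / 43,
    doses = dose_grid_default(),
    n_reps = 3,
    noise_sd = 5,
    dose_range = c(0.08, 20),
    ir_gy = 4,
    ir_inhibition = 0.25,
    synergy_tol = 2,
    synergy_min_points = 3,
    fold_cutoff = 3,
    synergy_offsets = c(0.25, 0.2, 0),
    filter = list(max_pop_af = 0.0004, min_t_depth = 20, min_t_alt = 3,
                  max_n_alt = 1, min_vaf = 0.05, min_callers = 2,
                  normal_clause = "n_alt"),
    de = list(lfc = 1, p = 0.05, padj = 0.05),
    label_q = 0.10,
    ssgsea_alpha = 0.25,
    demo = list(n_dr_samples = 6, n_wes_samples = 8, snv_per_sample = 30,
                fp_per_caller = 40, n_genes = 1200, n_organoids = 14,
                group_log2fc = 3, n_validation = 100, null_iter = 50)
  )
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  utils::modifyList(structure(cfg, class = "npcpgx_config"), override)
}

#' Serialize / deserialize a pipeline configuration
#'
#' JSON round-trip: `config_from_json(config_to_json(cfg, path))` equals
#' the original configuration.
#'
#' @param config An `npcpgx_config`.
#' @param path File path.
#' @return `config_from_json` returns the `npcpgx_config`.
#' @export
config_to_json <- function(config, path) {
  stopifnot(inherits(config, "npcpgx_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname config_to_json
#' @export
config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$seed <- as.integer(raw$seed)
  raw$subtype_fractions <- as.list(raw$subtype_fractions)
  raw$filter <- as.list(raw$filter)
  raw$de <- as.list(raw$de)
  raw$demo <- as.list(raw$demo)
  structure(raw, class = "npcpgx_config")
}

#' Run the end-to-end synthetic demonstration pipeline
#'
#' Executes every stage on synthetic data at demonstration scale:
#' cohort generation, drug-screen simulation and 4PL IC50 extraction,
#' chemoradiotherapy synergy evaluation at the configured synergy
#' offsets, multi-caller variant consensus with filtering, burden and
#' 96-context signature refitting, two-method differential expression
#' with the overlap filter and pathway signature assembly, ssGSEA
#' scoring of an independent validation cohort with quantile response
#' labels, ROC/AUC evaluation and a random-signature null. Deterministic
#' given `config$seed`.
#'
#' @param config An [pipeline_config()] object.
#' @param outdir Optional directory; when given, the report is written to
#'   `report.json` (plus the config to `config.json`) inside it.
#' @return The run report (named list of per-stage summaries).
#' @export
run_demo <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "npcpgx_config"))
  seed <- config$seed
  d <- config$demo

  ## 1. cohort -------------------------------------------------------------
  cohort <- gen_cohort(config$n_patients,
                       unlist(config$subtype_fractions),
                       pdo_rate = config$pdo_rate,
                       seed = stage_seed(seed, "cohort"))
  cohort_report <- list(
    n = nrow(cohort),
    subtype_pct = as.list(subtype_proportions(cohort)),
    pdo_rate_pct = percent_of(sum(cohort$has_pdo), nrow(cohort), 0)
  )

  ## 2. drug screen + IC50 extraction --------------------------------------
  set.seed(stage_seed(seed, "dr_truth"))
  dr_truth <- data.frame(
    sample = sprintf("PDO%02d", seq_len(d$n_dr_samples)),
    ic50 = exp(stats::runif(d$n_dr_samples, log(0.2), log(10))),
    hill = stats::runif(d$n_dr_samples, 0.8, 2)
  )
  fits <- do.call(rbind, lapply(seq_len(d$n_dr_samples), function(i) {
    plate <- gen_dose_response(
      list(ic50 = dr_truth$ic50[i], hill = dr_truth$hill[i]),
      doses = config$doses, n_reps = config$n_reps,
      noise_sd = config$noise_sd,
      seed = stage_seed(seed, paste0("plate", i)),
      sample = dr_truth$sample[i], drug = "docetaxel"
    )
    fit_plate(plate, config$dose_range)
  }))
  rel_err <- abs(fits$ic50_raw - dr_truth$ic50) / dr_truth$ic50
  dr_report <- list(
    n_fits = nrow(fits),
    n_converged = sum(fits$converged),
    median_rel_ic50_error = stats::median(rel_err, na.rm = TRUE)
  )

  ## 3. chemoradiotherapy synergy ------------------------------------------
  syn_rows <- lapply(seq_along(config$synergy_offsets), function(i) {
    off <- config$synergy_offsets[i]
    truth <- list(ic50 = 2, hill = 1.2)
    mono <- gen_dose_response(truth, doses = config$doses,
                              n_reps = config$n_reps, noise_sd = config$noise_sd,
                              seed = stage_seed(seed, paste0("mono", i)),
                              drug = paste0("drug", i))
    combo <- gen_combo_screen(truth, config$ir_inhibition, off,
                              doses = config$doses, n_reps = config$n_reps,
                              noise_sd = config$noise_sd,
                              seed = stage_seed(seed, paste0("combo", i)),
                              drug = paste0("drug", i))
    ev <- evaluate_crt_pair(mono, combo, config$ir_inhibition,
                            tol = config$synergy_tol,
                            min_points = config$synergy_min_points,
                            fold_cutoff = config$fold_cutoff)
    data.frame(drug = paste0("drug", i), offset = off, verdict = ev$verdict,
               fold_change = ev$fold$fold_change,
               good_combination = ev$fold$good_combination,
               stringsAsFactors = FALSE)
  })
  synergy_tab <- do.call(rbind, syn_rows)
  synergy_report <- list(
    calls = synergy_tab,
    synergistic_rate = mean(synergy_tab$verdict == "synergistic")
  )

  ## 4. somatic variant consensus ------------------------------------------
  wes_samples <- sprintf("T%02d", seq_len(d$n_wes_samples))
  sim <- gen_caller_callsets(
    n_true = d$snv_per_sample * d$n_wes_samples,
    fp_per_caller = rep(d$fp_per_caller, 3),
    sample_ids = wes_samples,
    seed = stage_seed(seed, "wes")
  )
  consensus <- merge_callers(sim$callsets, config$filter$min_callers)
  filtered <- apply_filters(consensus, do.call(filter_config, config$filter))
  burden <- burden_summary(filtered, wes_samples)
  catalog <- trinucleotide_contexts(filtered, sim$context_lookup)
  reference <- synthetic_reference_signatures()
  sig_fit <- if (sum(catalog) > 0) refit_signatures(catalog, reference) else NULL
  variant_report <- list(
    n_consensus = nrow(consensus),
    n_filtered = nrow(filtered),
    total = burden$total,
    mean_per_sample = burden$mean_per_sample,
    by_class = as.list(burden$by_class),
    signature_weights = if (!is.null(sig_fit)) as.list(round(sig_fit$weights, 4)),
    signature_cosine = if (!is.null(sig_fit)) sig_fit$cosine
  )

  ## 5. differential expression + signature assembly -----------------------
  expr_sim <- gen_expression(n_genes = d$n_genes, n_samples = d$n_organoids,
                             group_log2fc = d$group_log2fc,
                             seed = stage_seed(seed, "expr"))
  norm <- normalize_counts(expr_sim$counts)
  res_a <- de_test(norm$log2_normalized, expr_sim$phenotype$group, "moderated")
  res_b <- de_test(norm$log2_normalized, expr_sim$phenotype$group, "ranksum")
  sig <- overlap_filter(res_a, res_b, lfc = config$de$lfc,
                        p_cut = config$de$p, padj_cut = config$de$padj)
  # five mechanism "pathways": chunks of the true signature blocks padded
  # with background genes, mimicking curated pathway sets
  truth_genes <- unlist(expr_sim$signature_sets, use.names = FALSE)
  chunks <- split(truth_genes, rep(1:5, length.out = length(truth_genes)))
  set.seed(stage_seed(seed, "pathways"))
  background <- setdiff(rownames(expr_sim$counts), truth_genes)
  pathway_sets <- stats::setNames(lapply(chunks, function(g) {
    c(g, sample(background, 20))
  }), c("apoptosis", "microtubule", "mitotic_cell_cycle", "androgen_response",
        "tnfa_nfkb"))
  assembled <- assemble_pathway_signature(sig, pathway_sets)
  de_report <- list(
    n_overlap_genes = nrow(sig),
    pathway_counts = as.list(assembled$counts)
  )

  ## 6. response scoring + ROC ---------------------------------------------
  val <- gen_expression(n_genes = d$n_genes, n_samples = d$n_validation,
                        group_log2fc = d$group_log2fc,
                        seed = stage_seed(seed, "validation"))
  labels <- label_by_ic50(stats::setNames(val$phenotype$ic50,
                                          val$phenotype$sample),
                          q = config$label_q)
  # sensitivity-oriented signature: genes up in the drug-sensitive group
  sens_genes <- intersect(sig$gene[sig$direction == "up_in_B"],
                          assembled$combined)
  score_report <- if (length(sens_genes) >= 2) {
    scores <- ssgsea_score(val$counts, list(sensitive_up = sens_genes),
                           alpha = config$ssgsea_alpha)
    roc <- roc_auc(scores["sensitive_up", ], labels)
    null <- random_signature_null(val$counts, labels,
                                  n_genes = max(2, length(sens_genes)),
                                  n_iter = d$null_iter,
                                  seed = stage_seed(seed, "null"),
                                  alpha = config$ssgsea_alpha)
    list(n_signature_genes = length(sens_genes), auc = roc$auc,
         null_mean_auc = null$mean, null_sd_auc = null$sd)
  } else {
    list(n_signature_genes = length(sens_genes), auc = NA_real_,
         null_mean_auc = NA_real_, null_sd_auc = NA_real_)
  }

  report <- list(
    seed = seed,
    cohort = cohort_report,
    dose_response = dr_report,
    synergy = synergy_report,
    variants = variant_report,
    diff_expr = de_report,
    scoring = score_report,
    config = unclass(config)
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_json_report(report, file.path(outdir, "report.json"))
    config_to_json(config, file.path(outdir, "config.json"))
  }
  report
}
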