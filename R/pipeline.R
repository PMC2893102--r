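## End-to-end orchestration: simulate or load inputs, then
## segment -> map -> prep -> associate -> screen -> survival, with a
## JSON-serializable report of every headline quantity.

#' Pipeline configuration with the analysis defaults
#'
#' Houses every tunable threshold of the analysis: the gain/loss call ratio
#' pair (0.93/1.07; stringent preset 0.7/1.4), the six dose-response bin
#' edges {0.5, 0.93, 1.07, 2, 4}, the transcript filters (log2 > 3 in >= 3
#' samples, IQR >= 0.1), the mapping window (250 kb, 5 SNPs), the FDR level
#' (1%), the Bonferroni alpha (0.01), the case/control Z cutoff (6), the
#' minimum follow-up (4 months), the ROC landmark (24 months) and the
#' permutation/bootstrap counts.
#'
#' @param ... overrides of any default listed above.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    cna_lower = 0.93, cna_upper = 1.07,
    lambda_sparsity = 0, lambda_fusion = NULL,
    window_bp = 250000, min_snps = 5,
    min_log2 = 3, min_samples = 3, min_iqr = 0.1,
    fdr_q = 0.01, alpha_bonferroni = 0.01, cluster_k = 5,
    z_cutoff = 6, surv_z_cutoff = 1.96, min_followup = 4,
    landmark_months = 24, n_perm = 1000, n_boot = 2000,
    pc_components = 2, seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_arg("unknown configuration field(s): %s",
             paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$cna_lower > 0, cfg$cna_lower < 1, cfg$cna_upper > 1,
            cfg$fdr_q > 0, cfg$fdr_q < 1, cfg$min_followup >= 0,
            cfg$landmark_months > 0, cfg$n_perm >= 100, cfg$n_boot >= 10)
  structure(cfg, class = "pipeline_config")
}

#' Simulate a complete two-cohort study
#'
#' Builds the discovery cohort (segmental copy number plus dosage-driven
#' expression for `n_samples` tumors) and an independent testing cohort
#' (`n_cases` primary tumors with survival follow-up and `n_controls`
#' normals). The differentially expressed and survival-driving transcripts
#' are drawn from the dosage-responsive set, so copy-number-associated
#' transcripts carry the downstream case/control and survival signal.
#'
#' @param seed master integer seed.
#' @param n_chrom,n_snps,n_transcripts genome size.
#' @param n_samples discovery cohort size.
#' @param n_cases,n_controls testing cohort sizes.
#' @param segment_rate,cn_noise_sd copy-number simulation settings.
#' @param dosage_fraction,beta_mean,expr_noise_sd expression settings.
#' @param n_de,de_shift case/control signal: number of differentially
#'   expressed transcripts (drawn from the responsive set) and their shift.
#' @param n_risk,hr_per_unit,censor_rate survival signal settings. By default
#'   the whole differentially expressed set is weakly prognostic
#'   (`hr_per_unit` close to 1 per transcript): its members share a latent
#'   per-sample factor (see [simulate_clinical()]), so the set behaves like a
#'   co-regulated signature whose aggregate, not any single member, carries
#'   the survival signal.
#' @return list with `layout`, `cn_ratios`, `expression` (discovery),
#'   `testing_expression`, `clinical`, and `truth`.
#' @export
simulate_study <- function(seed = 1, n_chrom = 3, n_snps = 3000,
                           n_transcripts = 2000, n_samples = 20,
                           n_cases = 148, n_controls = 45,
                           segment_rate = 0.2, cn_noise_sd = 0.25,
                           dosage_fraction = 0.3, beta_mean = 1,
                           expr_noise_sd = 0.3, n_de = 100, de_shift = 1.5,
                           n_risk = 100, hr_per_unit = 1.05,
                           censor_rate = 0.02) {
  layout <- simulate_layout(n_chrom, n_snps, n_transcripts, seed)
  cn <- simulate_copy_number(layout, n_samples, segment_rate = segment_rate,
                             noise_sd = cn_noise_sd, seed = seed)
  ## dosage drives expression through the noise-free transcript copy number
  truth_profile <- cn_profile(layout$snps, log2(cn$truth$snp_ratio),
                              segmented = log2(cn$truth$snp_ratio))
  tcn_truth <- infer_transcript_cn(layout, truth_profile)
  ex <- simulate_expression(layout, cn$truth, tcn_truth,
                            dosage_fraction = dosage_fraction,
                            beta_mean = beta_mean, noise_sd = expr_noise_sd,
                            seed = seed)
  responsive <- ex$truth$dosage$transcript_id[ex$truth$dosage$responsive]
  set.seed(derive_seed(seed, 8L))
  de <- if (length(responsive)) sample(responsive, min(n_de, length(responsive)))
        else character(0)
  risk <- if (length(de)) sample(de, min(n_risk, length(de))) else character(0)
  clin <- simulate_clinical(n_cases, n_controls,
                            transcript_ids = layout$transcripts$transcript_id,
                            risk_transcripts = risk, hr_per_unit = hr_per_unit,
                            censor_rate = censor_rate, seed = seed,
                            de_transcripts = de, de_shift = de_shift)
  truth <- ex$truth
  truth$casecontrol <- clin$truth$casecontrol
  truth$survival <- clin$truth$survival
  list(layout = layout, cn_ratios = cn$ratios, expression = ex$expression,
       testing_expression = clin$expression, clinical = clin$clinical,
       truth = truth)
}

#' Run the full integrative analysis
#'
#' Executes segmentation, gain/loss calling, transcript copy-number mapping,
#' expression filtering and renormalization, per-transcript dosage testing
#' with FDR selection, case/control and survival screening with permutation
#' enrichment, and PC-based Cox survival models compared by time-dependent
#' ROC at the configured landmark. Fully reproducible given the data and the
#' config seed.
#'
#' @param data list as returned by [simulate_study()] (fields: layout,
#'   cn_ratios, expression, testing_expression, clinical).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, intermediate tables and the
#'   JSON report are written there.
#' @return the report, a nested list; intermediate objects are attached as
#'   the `"objects"` attribute.
#' @export
run_pipeline <- function(data, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  layout <- data$layout
  ids_expr <- rownames(data$expression)
  if (!setequal(ids_expr, layout$transcripts$transcript_id))
    stop_arg("transcript ids of expression matrix and annotation disagree")
  if (!identical(rownames(data$cn_ratios), layout$snps$snp_id))
    stop_arg("SNP ids of copy-number matrix and annotation disagree")

  ## 1. segmentation and CNA burden
  profile <- cn_profile(layout$snps, to_log2_ratio(data$cn_ratios))
  profile <- segment_fused_lasso(profile, config$lambda_sparsity,
                                 config$lambda_fusion)
  calls <- call_cna(profile, config$cna_lower, config$cna_upper)
  gaf <- genome_altered_fraction(calls)

  ## 2. transcript copy number
  tcn <- infer_transcript_cn(layout, profile, config$window_bp,
                             config$min_snps)
  msum <- mapping_summary(tcn)

  ## 3. expression prep
  filt <- filter_transcripts(data$expression, layout$transcripts,
                             config$min_log2, config$min_samples,
                             config$min_iqr)
  renorm <- suppressWarnings(renormalize(filt$expr))

  ## 4. association
  assoc <- associate_all(renorm, tcn)
  selected <- fdr_select(assoc, config$fdr_q)
  signal_prop <- estimate_signal_proportion(assoc$p[!is.na(assoc$p)])
  dr <- dose_response(renorm, tcn)
  scan <- genome_scan_report(assoc, layout, config$alpha_bonferroni,
                             config$cluster_k)

  ## 5. screening and enrichment in the testing cohort
  cc <- casecontrol_screen(data$testing_expression, data$clinical$case,
                           config$z_cutoff)
  cases <- data$clinical[data$clinical$case == 1L, , drop = FALSE]
  scr <- survival_screen(data$testing_expression[, cases$sample_id,
                                                 drop = FALSE],
                         cases, config$min_followup, config$surv_z_cutoff)
  cc_z <- stats::setNames(cc$cc_z, cc$transcript_id)
  surv_z <- stats::setNames(scr$surv_z, scr$transcript_id)
  cand <- intersect(selected, names(cc_z))
  enr_cc <- enr_surv <- NULL
  if (length(cand) >= 1L && length(cand) < length(cc_z)) {
    enr_cc <- permutation_enrichment(cand, cc_z, config$n_perm,
                                     "count_exceed", config$z_cutoff,
                                     seed = derive_seed(config$seed, 9L))
    enr_surv <- permutation_enrichment(cand, surv_z, config$n_perm,
                                       "count_exceed", config$surv_z_cutoff,
                                       seed = derive_seed(config$seed, 10L))
  }
  set_cc <- cand[abs(cc_z[cand]) > config$z_cutoff]
  set_surv <- cand[!is.na(surv_z[cand]) & abs(surv_z[cand]) > config$surv_z_cutoff]

  ## 6. survival models
  coh <- cases[!is.na(cases$followup_months) &
                 cases$followup_months >= config$min_followup, , drop = FALSE]
  clin2 <- data.frame(sample_id = coh$sample_id, time = coh$followup_months,
                      event = coh$oscc_death, stage = coh$stage,
                      age = coh$age, sex = coh$sex, stringsAsFactors = FALSE)
  surv_section <- survival_model_section(data$testing_expression, clin2,
                                         set_cc, set_surv, config)

  report <- list(
    seed = config$seed,
    copy_number = list(
      altered_fraction = list(min = min(gaf), max = max(gaf),
                              mean = mean(gaf), sd = stats::sd(gaf)),
      thresholds = c(lower = config$cna_lower, upper = config$cna_upper)),
    mapping = list(counts = as.list(msum$counts), n_total = msum$n_total,
                   n_mapped = msum$n_mapped,
                   pct_ge_min_snps = msum$pct_ge_min_snps),
    filtering = list(n_input = nrow(data$expression),
                     n_retained = nrow(filt$expr),
                     pct_retained = percent1(nrow(filt$expr),
                                             nrow(data$expression)),
                     removed_by_rule = as.list(table(filt$removed$rule))),
    association = list(m = scan$m, n_fdr_selected = length(selected),
                       signal_proportion = signal_prop,
                       bonferroni_threshold_p = scan$threshold_p,
                       bonferroni_neglog10 = scan$neglog10_cutoff,
                       n_clustered_regions = nrow(scan$regions)),
    dose_response = dr,
    screen = list(n_candidate = length(cand),
                  n_casecontrol_flagged = length(set_cc),
                  n_survival_flagged = length(set_surv),
                  enrichment_p_casecontrol =
                    if (is.null(enr_cc)) NA else enr_cc$empirical_p,
                  enrichment_p_survival =
                    if (is.null(enr_surv)) NA else enr_surv$empirical_p),
    survival = surv_section$report)

  objects <- list(profile = profile, calls = calls, gaf = gaf, tcn = tcn,
                  filtered = filt, renormalized = renorm, association = assoc,
                  selected = selected, scan = scan, casecontrol = cc,
                  survival_screen = scr, enrichment_cc = enr_cc,
                  enrichment_surv = enr_surv, cohort = clin2,
                  models = surv_section$objects)
  attr(report, "objects") <- objects

  if (!is.null(out_dir)) write_pipeline_outputs(report, objects, out_dir)
  report
}

## Five Cox models (stage alone, the two PC pairs, the two combinations),
## jackknife risk scores and landmark ROC comparison vs stage alone.
survival_model_section <- function(testing_expression, clin2, set_cc,
                                   set_surv, config) {
  npc <- config$pc_components
  notes <- character(0)
  models <- list()
  aucs <- list()
  sets <- list(pc_cc = set_cc, pc_surv = set_surv)
  pcs <- list()
  d <- clin2
  for (nm in names(sets)) {
    if (length(sets[[nm]]) < npc) {
      notes <- c(notes, sprintf("set %s has fewer than %d transcripts; its models were skipped",
                                nm, npc))
      next
    }
    pc <- pc_scores(testing_expression[, d$sample_id, drop = FALSE],
                    sets[[nm]], npc)
    pcs[[nm]] <- pc
    d[[paste0(nm, "_1")]] <- pc$scores[, 1]
    d[[paste0(nm, "_2")]] <- pc$scores[, 2]
  }
  specs <- list(stage = "stage")
  if (!is.null(pcs$pc_cc)) {
    specs$pc_cc <- c("pc_cc_1", "pc_cc_2")
    specs$stage_pc_cc <- c("stage", "pc_cc_1", "pc_cc_2")
  }
  if (!is.null(pcs$pc_surv)) {
    specs$pc_surv <- c("pc_surv_1", "pc_surv_2")
    specs$stage_pc_surv <- c("stage", "pc_surv_1", "pc_surv_2")
  }
  scores <- list(stage = stats::setNames(d$stage, d$sample_id))
  for (nm in names(specs)) {
    fit <- fit_cox(d, specs[[nm]])
    models[[nm]] <- fit$table
    if (nm != "stage")
      scores[[nm]] <- jackknife_risk_scores(d, specs[[nm]])
  }
  comparisons <- list()
  for (nm in names(scores)) {
    aucs[[nm]] <- time_dependent_roc(scores[[nm]], d$time, d$event,
                                     config$landmark_months)$auc
  }
  for (nm in intersect(c("stage_pc_cc", "stage_pc_surv"), names(scores))) {
    cmp <- compare_auc(scores[[nm]], scores$stage, d$time, d$event,
                       config$landmark_months, config$n_boot,
                       seed = derive_seed(config$seed, 11L + match(nm, names(scores))))
    comparisons[[paste0(nm, "_vs_stage")]] <-
      list(auc_model = cmp$auc_a, auc_stage = cmp$auc_b, diff = cmp$diff,
           p = cmp$p)
  }
  list(report = list(n_subjects = nrow(d), n_events = sum(d$event),
                     models = models, landmark_months = config$landmark_months,
                     auc = aucs, comparisons = comparisons, notes = notes),
       objects = list(data = d, scores = scores, pcs = pcs))
}

write_pipeline_outputs <- function(report, objects, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(objects$profile$segmented,
                   file.path(out_dir, "segmented_log2.tsv"), "snp_id")
  write_matrix_tsv(objects$calls$calls, file.path(out_dir, "cna_calls.tsv"),
                   "snp_id")
  tcn_tab <- data.frame(objects$tcn$info[, c("transcript_id", "rule", "n_snps")],
                        objects$tcn$cn, check.names = FALSE)
  utils::write.table(tcn_tab, file.path(out_dir, "transcript_cn.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(objects$filtered$removed,
                     file.path(out_dir, "removed_transcripts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(objects$renormalized,
                   file.path(out_dir, "expression_renormalized.tsv"),
                   "transcript_id")
  utils::write.table(objects$association,
                     file.path(out_dir, "association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  screen_tab <- merge(objects$casecontrol, objects$survival_screen,
                      by = "transcript_id", all = TRUE)
  utils::write.table(screen_tab, file.path(out_dir, "screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' Validate pipeline input files
#'
#' Checks column schemas, duplicate identifiers, coordinate sanity,
#' chromosome naming and clinical value domains without mutating anything.
#'
#' @param paths named list: `layout_dir`, `cn_ratio`, `expression`,
#'   `testing_expression`, `clinical` (any subset).
#' @return data frame of diagnostics (file, issue); zero rows when clean.
#' @export
validate_inputs <- function(paths) {
  diags <- list()
  note <- function(file, issue)
    diags[[length(diags) + 1L]] <<- data.frame(file = file, issue = issue,
                                               stringsAsFactors = FALSE)
  if (!is.null(paths$layout_dir)) {
    lay <- tryCatch(read_layout(paths$layout_dir), error = function(e) e)
    if (inherits(lay, "error")) note(paths$layout_dir, conditionMessage(lay))
    else {
      if (anyDuplicated(lay$snps$snp_id))
        note(paths$layout_dir, "duplicated snp_id")
      dup <- lay$transcripts$transcript_id[duplicated(lay$transcripts$transcript_id)]
      if (length(dup))
        note(paths$layout_dir,
             sprintf("duplicated transcript_id: %s", dup[1]))
    }
  }
  for (nm in c("cn_ratio", "expression", "testing_expression")) {
    if (is.null(paths[[nm]])) next
    m <- tryCatch(read_matrix_tsv(paths[[nm]]), error = function(e) e)
    if (inherits(m, "error")) { note(paths[[nm]], conditionMessage(m)); next }
    if (anyDuplicated(rownames(m))) note(paths[[nm]], "duplicated row ids")
    if (!is.numeric(m)) note(paths[[nm]], "non-numeric values")
    else if (nm == "cn_ratio" && any(m <= 0, na.rm = TRUE))
      note(paths[[nm]], "non-positive copy-number ratio")
  }
  if (!is.null(paths$clinical)) {
    cl <- tryCatch(read_clinical(paths$clinical), error = function(e) e)
    if (inherits(cl, "error")) note(paths$clinical, conditionMessage(cl))
    else {
      need <- c("sample_id", "case", "age", "sex", "stage",
                "followup_months", "dead", "oscc_death")
      miss <- setdiff(need, names(cl))
      if (length(miss))
        note(paths$clinical, sprintf("missing column(s): %s",
                                     paste(miss, collapse = ", ")))
      if ("sex" %in% names(cl) && !all(cl$sex %in% c(0, 1, NA)))
        note(paths$clinical, "sex outside {0, 1} coding")
      if ("case" %in% names(cl) && !all(cl$case %in% c(0, 1)))
        note(paths$clinical, "case outside {0, 1} coding")
      if ("stage" %in% names(cl) && !all(is.na(cl$stage) | cl$stage %in% 1:4))
        note(paths$clinical, "stage outside 1-4")
      if ("followup_months" %in% names(cl) &&
          any(cl$followup_months < 0, na.rm = TRUE))
        note(paths$clinical, "negative follow-up time")
    }
  }
  if (length(diags)) do.call(rbind, diags)
  else data.frame(file = character(0), issue = character(0))
}
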