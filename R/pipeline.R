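# End-to-end orchestration: discovery -> FFPE filter -> direction filter ->
# concordance selection -> nested-CV DLDA training -> cohort scoring ->
# combination -> clinical evaluation, with full provenance.

#' Pipeline configuration
#'
#' Collects every stage parameter plus the master seed.  With
#' `simulate = TRUE` (default) the pipeline generates its own cell panels and
#' cohorts via the synthetic-data module; otherwise `paths` must point at the
#' input files (see [run_pipeline()]).
#'
#' @param drugs Character vector of drug names (one panel and predictor
#'   each); the first two are combined into the combination predictor.
#' @param tail_fraction Extreme-responder tail fraction per side.
#' @param rank_alpha,max_genes Candidate retention threshold and cap for
#'   [rank_chemosensitivity_genes()].
#' @param coxen_alpha,n_permutations Concordance significance threshold and
#'   permutation count.
#' @param candidate_ks Feature counts explored by the inner CV loop.
#' @param cutoff_rule Cutoff used for survival stratification: `"npv_max"`
#'   (clinical-utility rule) or `"youden"`.
#' @param min_predicted_negatives Constraint for [npv_max_cutoff()].
#' @param censor_horizon Survival censoring horizon in months.
#' @param n_boot Bootstrap resamples for the AUC confidence interval.
#' @param simulate Generate inputs with the synthetic-data module?
#' @param sim Optional [sim_config()] overriding the one built from `seed`.
#' @param paths For `simulate = FALSE`: a list with `panels` (per drug a list
#'   `expr` TSV / `activity` CSV with columns cell_line_id, activity),
#'   `development`, `tuning`, `validation` (each a list `expr` TSV /
#'   `clinical` CSV) and `robust_genes` (text file, one gene ID per line).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(drugs = c("carboplatin", "paclitaxel"),
                            tail_fraction = 0.30, rank_alpha = 0.05,
                            max_genes = 500, coxen_alpha = 0.05,
                            n_permutations = 1000,
                            candidate_ks = c(5, 10, 20, 50),
                            cutoff_rule = c("npv_max", "youden"),
                            min_predicted_negatives = 3,
                            censor_horizon = 60, n_boot = 500,
                            simulate = TRUE, sim = NULL, paths = NULL,
                            seed = 1) {
  cutoff_rule <- match.arg(cutoff_rule)
  if (!simulate && is.null(paths))
    stop2("paths are required when simulate = FALSE")
  cfg <- list(drugs = drugs, tail_fraction = tail_fraction,
              rank_alpha = rank_alpha, max_genes = max_genes,
              coxen_alpha = coxen_alpha, n_permutations = n_permutations,
              candidate_ks = candidate_ks, cutoff_rule = cutoff_rule,
              min_predicted_negatives = min_predicted_negatives,
              censor_horizon = censor_horizon, n_boot = n_boot,
              simulate = simulate, sim = sim, paths = paths,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

read_drug_activity <- function(path, drug) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_line_id", "activity") %in% names(df)))
  structure(list(drug_name = drug, cell_line_ids = df$cell_line_id,
                 activity = stats::setNames(df$activity, df$cell_line_id),
                 source_metric = "gi50_neg_log"),
            class = "drug_activity")
}

simulate_pipeline_inputs <- function(config) {
  sim <- if (!is.null(config$sim)) config$sim else sim_config(seed = config$seed)
  panels <- lapply(config$drugs, function(d) simulate_cell_panel(sim, drug = d))
  names(panels) <- config$drugs
  truth <- do.call(merge_truths, lapply(panels, `[[`, "truth"))
  dev <- simulate_patient_cohort(sim, truth, cohort_id = "development")
  tune <- simulate_patient_cohort(sim, truth, cohort_id = "tuning")
  test <- simulate_patient_cohort(sim, truth, cohort_id = "validation")
  ffpe <- simulate_ffpe_pair(test$expr, sim)
  list(panels = panels,
       development = dev, tuning = tune,
       validation = list(expr = ffpe$expr, clinical = test$clinical),
       robust_ids = ffpe$truth$robust_genes,
       truths = lapply(panels, `[[`, "truth"))
}

read_pipeline_inputs <- function(config) {
  p <- config$paths
  panels <- lapply(config$drugs, function(d) {
    list(expr = read_expression_matrix(p$panels[[d]]$expr),
         activity = read_drug_activity(p$panels[[d]]$activity, d))
  })
  names(panels) <- config$drugs
  cohort <- function(e) list(expr = read_expression_matrix(e$expr),
                             clinical = read_clinical_table(e$clinical))
  list(panels = panels,
       development = cohort(p$development),
       tuning = cohort(p$tuning),
       validation = cohort(p$validation),
       robust_ids = readLines(p$robust_genes),
       truths = NULL)
}

evaluate_cohort <- function(scores, clinical, cutoffs, config, boot_seed) {
  resp <- as_response(clinical)
  al <- align_scores_response(scores, clinical)
  wt <- wilcoxon_rank_sum(al$score[al$response == "responder"],
                          al$score[al$response == "non_responder"])
  auc <- roc_auc(scores, clinical, n_boot = config$n_boot, seed = boot_seed)
  conf <- lapply(cutoffs, function(ct) confusion_metrics(scores, clinical, ct))
  # Survival stratification uses the balanced (Youden) cutoff: the NPV-max
  # rule deliberately leaves a small predicted-negative group, which is the
  # right trade-off for clinical screening but not for a two-arm KM contrast.
  thr <- cutoffs$youden$threshold
  grp <- stats::setNames(ifelse(al$score >= thr, "pred_responder",
                                "pred_non_responder"), al$sample_id)
  surv <- tryCatch(km_logrank(clinical, grp, config$censor_horizon),
                   error = function(e) structure(list(message = conditionMessage(e)),
                                                 class = "skipped_analysis"))
  covars <- intersect(c("age", "stage", "debulking", "race"), names(clinical))
  logit <- tryCatch(
    suppressWarnings(
      logistic_adjusted(clinical, scores,
                        clinical[, c("sample_id", covars), drop = FALSE])),
    error = function(e) structure(list(message = conditionMessage(e)),
                                  class = "skipped_analysis"))
  list(n = length(al$score), wilcoxon_p = wt$p_value, auc = auc$auc,
       auc_ci = c(auc$ci_low, auc$ci_high), confusion = conf,
       survival = surv, logistic = logit)
}

#' Run the full prediction pipeline
#'
#' Executes, per drug: extreme-line labeling, candidate gene ranking, FFPE
#' robustness and direction-consistency filtering against the development
#' cohort, concordance selection by permutation-tested COXEN coefficient,
#' nested-CV DLDA training on the labeled lines, and scoring of the tuning
#' and validation cohorts; then forms the combination score, derives Youden
#' and NPV-maximizing cutoffs on the tuning cohort, and evaluates every
#' predictor on both cohorts (rank-sum test, AUC with bootstrap CI,
#' confusion metrics at each cutoff, survival stratification, adjusted
#' logistic regression).  Deterministic given the config.
#'
#' @param config A [pipeline_config()].
#' @return A `"coxen_report"`: `config`, per-drug results (`biomarkers`,
#'   `provenance`, `model`, `cutoffs`, `evaluation$tuning`,
#'   `evaluation$validation`), `combination`, and `recovery` (biomarker
#'   precision against planted truth, simulation mode only).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- if (config$simulate) simulate_pipeline_inputs(config)
            else read_pipeline_inputs(config)
  dev <- inputs$development
  res <- list(config = config, drugs = list())
  scores_tune <- list(); scores_val <- list()
  for (drug in config$drugs) {
    panel <- inputs$panels[[drug]]
    labels <- select_extreme_lines(panel$activity, config$tail_fraction)
    cand <- rank_chemosensitivity_genes(panel$expr, labels,
                                        alpha = config$rank_alpha,
                                        max_genes = config$max_genes)
    cand <- filter_ffpe_robust(cand, inputs$robust_ids)
    cand <- filter_direction_consistent(cand, dev$expr, dev$clinical)
    perm <- coxen_permutation_test(panel$expr, dev$expr, cand$gene_id,
                                   n_permutations = config$n_permutations,
                                   seed = derive_seed(config$seed,
                                                      paste0("coxen-", drug)))
    bset <- select_coxen_genes(perm, config$coxen_alpha, cand,
                               drug_name = drug)
    lab_ids <- labels$sample_id
    model <- double_cross_validate(
      panel$expr[bset$gene_ids, lab_ids, drop = FALSE], labels,
      candidate_ks = pmin(config$candidate_ks, length(bset$gene_ids)),
      drug_name = drug)
    st <- score_cohort(model, inputs$tuning$expr)
    sv <- score_cohort(model, inputs$validation$expr)
    cutoffs <- list(youden = youden_cutoff(st, inputs$tuning$clinical),
                    npv_max = npv_max_cutoff(st, inputs$tuning$clinical,
                                             config$min_predicted_negatives))
    res$drugs[[drug]] <- list(
      biomarkers = bset, provenance = provenance(bset), model = model,
      coxen = perm, cutoffs = cutoffs,
      evaluation = list(
        tuning = evaluate_cohort(st, inputs$tuning$clinical, cutoffs, config,
                                 derive_seed(config$seed, paste0("boot-t-", drug))),
        validation = evaluate_cohort(sv, inputs$validation$clinical, cutoffs,
                                     config,
                                     derive_seed(config$seed, paste0("boot-v-", drug)))))
    scores_tune[[drug]] <- st; scores_val[[drug]] <- sv
  }
  if (length(config$drugs) >= 2) {
    d12 <- config$drugs[1:2]
    ct <- combine_scores(scores_tune[[d12[1]]], scores_tune[[d12[2]]])
    cv <- combine_scores(scores_val[[d12[1]]], scores_val[[d12[2]]])
    cutoffs <- list(youden = youden_cutoff(ct, inputs$tuning$clinical),
                    npv_max = npv_max_cutoff(ct, inputs$tuning$clinical,
                                             config$min_predicted_negatives))
    res$combination <- list(
      drugs = d12, cutoffs = cutoffs,
      evaluation = list(
        tuning = evaluate_cohort(ct, inputs$tuning$clinical, cutoffs, config,
                                 derive_seed(config$seed, "boot-t-comb")),
        validation = evaluate_cohort(cv, inputs$validation$clinical, cutoffs,
                                     config,
                                     derive_seed(config$seed, "boot-v-comb"))))
  }
  if (!is.null(inputs$truths)) {
    prec <- vapply(config$drugs, function(d) {
      sel <- res$drugs[[d]]$biomarkers$gene_ids
      mean(sel %in% inputs$truths[[d]]$informative_genes)
    }, numeric(1))
    res$recovery <- list(biomarker_precision = prec,
                         overall_precision = {
                           sel <- unlist(lapply(res$drugs, function(x)
                             x$biomarkers$gene_ids))
                           truth_all <- unique(unlist(lapply(inputs$truths,
                             `[[`, "informative_genes")))
                           mean(sel %in% truth_all)
                         })
  }
  class(res) <- "coxen_report"
  res
}

#' @export
print.coxen_report <- function(x, ...) {
  cat(sprintf("COXEN pipeline report (seed %d)\n", x$config$seed))
  for (d in names(x$drugs)) {
    r <- x$drugs[[d]]
    ev <- r$evaluation$validation
    cat(sprintf(
      "  %-12s %3d biomarkers, k=%d, CV acc %.2f | validation AUC %.3f [%.3f-%.3f], Wilcoxon p %.3g\n",
      d, length(r$biomarkers$gene_ids), r$model$k, r$model$cv_accuracy,
      ev$auc, ev$auc_ci[1], ev$auc_ci[2], ev$wilcoxon_p))
  }
  if (!is.null(x$combination)) {
    ev <- x$combination$evaluation$validation
    cat(sprintf(
      "  %-12s validation AUC %.3f [%.3f-%.3f], Wilcoxon p %.3g\n",
      "combination", ev$auc, ev$auc_ci[1], ev$auc_ci[2], ev$wilcoxon_p))
    if (!inherits(ev$survival, "skipped_analysis")) {
      med <- ifelse(is.na(ev$survival$medians), "not reached",
                    sprintf("%.1f", ev$survival$medians))
      cat(sprintf("    median OS (predicted groups): %s months, log-rank p %.3g\n",
                  paste(med, collapse = " vs "), ev$survival$p_value))
    }
  }
  if (!is.null(x$recovery))
    cat(sprintf("  biomarker precision vs planted truth: %s\n",
                paste(sprintf("%s %.2f", names(x$recovery$biomarker_precision),
                              x$recovery$biomarker_precision), collapse = ", ")))
  invisible(x)
}

#' @export
summary.coxen_report <- function(object, ...) {
  rows <- list()
  add <- function(pred, cohort, ev) {
    conf <- ev$confusion[[object$config$cutoff_rule]]
    rows[[length(rows) + 1]] <<- data.frame(
      predictor = pred, cohort = cohort, n = ev$n, auc = ev$auc,
      wilcoxon_p = ev$wilcoxon_p, sensitivity = conf$sensitivity,
      specificity = conf$specificity, ppv = conf$ppv, npv = conf$npv,
      odds_ratio = conf$odds_ratio, stringsAsFactors = FALSE)
  }
  for (d in names(object$drugs))
    for (ch in names(object$drugs[[d]]$evaluation))
      add(d, ch, object$drugs[[d]]$evaluation[[ch]])
  if (!is.null(object$combination))
    for (ch in names(object$combination$evaluation))
      add("combination", ch, object$combination$evaluation[[ch]])
  do.call(rbind, rows)
}
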