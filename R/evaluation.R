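# Clinical-utility evaluation of score vectors: rank-sum stratification,
# ROC/AUC with bootstrap CI, Youden and NPV-maximizing cutoffs, confusion
# metrics with Wald/Woolf intervals, Kaplan-Meier / log-rank survival, and
# covariate-adjusted logistic regression.

#' Wilcoxon rank-sum comparison of responder vs non-responder scores
#'
#' Two-sided; exact enumeration when both groups have n <= 8 and there are no
#' ties, normal approximation with tie correction otherwise.
#'
#' @param scores_responders,scores_nonresponders Numeric score vectors.
#' @return List with `statistic` (Mann-Whitney W for the responder group) and
#'   `p_value`.
#' @export
wilcoxon_rank_sum <- function(scores_responders, scores_nonresponders) {
  x <- scores_responders; y <- scores_nonresponders
  if (!length(x) || !length(y)) stop2("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  no_ties <- !any(duplicated(c(x, y)))
  use_exact <- no_ties && length(x) <= 8 && length(y) <= 8
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

# Mann-Whitney AUC with ties counted 1/2, via midranks.
auc_stat <- function(score, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  r <- rank(score)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC area under the curve with bootstrap confidence interval
#'
#' AUC is the Mann-Whitney concordance probability (ties counted one half).
#' The CI is a seeded stratified percentile bootstrap over patients
#' (responders and non-responders resampled within class).
#'
#' @param scores A `"score_vector"` or named numeric vector.
#' @param response Clinical table or named response vector.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return List with `auc`, `ci_low`, `ci_high`, `n`.
#' @export
roc_auc <- function(scores, response, n_boot = 2000, seed = 1) {
  al <- align_scores_response(scores, response)
  is_pos <- al$response == "responder"
  if (!any(is_pos) || all(is_pos)) stop2("both classes must be present")
  auc <- auc_stat(al$score, is_pos)
  ip <- which(is_pos); ineg <- which(!is_pos)
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ip, length(ip), replace = TRUE),
               sample(ineg, length(ineg), replace = TRUE))
      auc_stat(al$score[idx], is_pos[idx])
    }, numeric(1))
  })
  ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  list(auc = auc, ci_low = ci[1], ci_high = ci[2], n = length(al$score))
}

# Candidate thresholds: midpoints between consecutive sorted unique scores,
# plus -Inf (everyone predicted responder) and +Inf (no one).
candidate_thresholds <- function(score) {
  u <- sort(unique(score))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  c(-Inf, mids, Inf)
}

# Confusion counts at one threshold; predicted responder <=> score >= thr.
counts_at <- function(score, is_pos, thr) {
  pred <- score >= thr
  c(tp = sum(pred & is_pos), fn = sum(!pred & is_pos),
    fp = sum(pred & !is_pos), tn = sum(!pred & !is_pos))
}

cutoff_spec <- function(threshold, rule, cts) {
  sens <- if (cts["tp"] + cts["fn"] > 0) cts[["tp"]] / (cts[["tp"]] + cts[["fn"]]) else NA_real_
  spec <- if (cts["tn"] + cts["fp"] > 0) cts[["tn"]] / (cts[["tn"]] + cts[["fp"]]) else NA_real_
  npv <- if (cts["tn"] + cts["fn"] > 0) cts[["tn"]] / (cts[["tn"]] + cts[["fn"]]) else NA_real_
  structure(list(threshold = threshold, rule = rule, sensitivity = sens,
                 specificity = spec, youden_j = sens + spec - 1, npv = npv),
            class = "cutoff_spec")
}

#' Youden-optimal cutoff
#'
#' Scans the candidate thresholds (midpoints between consecutive sorted
#' unique scores, plus the two degenerate extremes) and returns the one
#' maximizing the Youden index J = sensitivity + specificity - 1.  Predicted
#' responder means score >= threshold.  Ties are broken by higher
#' sensitivity, then by the lower threshold.
#'
#' @param scores A `"score_vector"` or named numeric vector (z scale).
#' @param response Clinical table or named response vector.
#' @return A `"cutoff_spec"` list: `threshold`, `rule`, achieved
#'   `sensitivity`, `specificity`, `youden_j`, `npv`.
#' @export
youden_cutoff <- function(scores, response) {
  al <- align_scores_response(scores, response)
  is_pos <- al$response == "responder"
  if (!any(is_pos) || all(is_pos)) stop2("both classes must be present")
  thr <- candidate_thresholds(al$score)
  best <- NULL
  for (t in thr) {
    cand <- cutoff_spec(t, "youden", counts_at(al$score, is_pos, t))
    if (is.null(best) ||
        cand$youden_j > best$youden_j + 1e-12 ||
        (abs(cand$youden_j - best$youden_j) <= 1e-12 &&
         cand$sensitivity > best$sensitivity + 1e-12))
      best <- cand
  }
  best
}

#' NPV-maximizing cutoff
#'
#' Over the same candidate grid as [youden_cutoff()], maximizes the negative
#' predictive value among thresholds leaving at least
#' `min_predicted_negatives` predicted non-responders (guarding against
#' vacuous NPV = 1 at a one-patient tail).  Ties are broken by higher
#' sensitivity, then by the lower threshold.
#'
#' @inheritParams youden_cutoff
#' @param min_predicted_negatives Minimum count of predicted non-responders.
#' @return A `"cutoff_spec"`.
#' @export
npv_max_cutoff <- function(scores, response, min_predicted_negatives = 3) {
  al <- align_scores_response(scores, response)
  is_pos <- al$response == "responder"
  if (!any(is_pos) || all(is_pos)) stop2("both classes must be present")
  thr <- candidate_thresholds(al$score)
  best <- NULL
  for (t in thr) {
    cts <- counts_at(al$score, is_pos, t)
    if (cts[["tn"]] + cts[["fn"]] < min_predicted_negatives) next
    cand <- cutoff_spec(t, "npv_max", cts)
    if (is.null(best) ||
        cand$npv > best$npv + 1e-12 ||
        (abs(cand$npv - best$npv) <= 1e-12 &&
         cand$sensitivity > best$sensitivity + 1e-12))
      best <- cand
  }
  if (is.null(best))
    stop2("no threshold leaves >= ", min_predicted_negatives,
          " predicted non-responders")
  best
}

wald_ci <- function(p, n) {
  if (is.na(p) || n == 0) return(c(NA_real_, NA_real_))
  half <- stats::qnorm(0.975) * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

#' Confusion metrics from the four cell counts
#'
#' Sensitivity, specificity, PPV and NPV with 95% Wald intervals truncated to
#' \[0, 1\], and the odds ratio with a 95% Woolf log interval.  If any cell is
#' zero, a Haldane 0.5 continuity correction is applied to all four cells for
#' the odds-ratio computation (flagged in the result).  Metrics with an empty
#' margin are reported as NA rather than raising an error.
#'
#' @param tp,fn,fp,tn Cell counts (rows: truth; columns: prediction).
#' @return A `"confusion_metrics"` list: the counts, each proportion with its
#'   CI, `odds_ratio` with `or_ci_low`/`or_ci_high`, and `haldane` flag.
#' @export
confusion_from_counts <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  prop <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- prop(tp, tp + fn); spec <- prop(tn, tn + fp)
  ppv <- prop(tp, tp + fp); npv <- prop(tn, tn + fn)
  haldane <- any(c(tp, fn, fp, tn) == 0)
  h <- if (haldane) 0.5 else 0
  or <- ((tp + h) * (tn + h)) / ((fp + h) * (fn + h))
  se_log <- sqrt(1 / (tp + h) + 1 / (fn + h) + 1 / (fp + h) + 1 / (tn + h))
  or_ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  out <- list(tp = tp, fn = fn, fp = fp, tn = tn,
              sensitivity = sens, sensitivity_ci = wald_ci(sens, tp + fn),
              specificity = spec, specificity_ci = wald_ci(spec, tn + fp),
              ppv = ppv, ppv_ci = wald_ci(ppv, tp + fp),
              npv = npv, npv_ci = wald_ci(npv, tn + fn),
              odds_ratio = or, or_ci_low = or_ci[1], or_ci_high = or_ci[2],
              haldane = haldane)
  class(out) <- "confusion_metrics"
  out
}

#' Confusion metrics of a score vector at a cutoff
#'
#' Dichotomizes scores at the cutoff (predicted responder means score >=
#' threshold, ties predicted responder) and delegates to
#' [confusion_from_counts()].
#'
#' @param scores A `"score_vector"` or named numeric vector.
#' @param response Clinical table or named response vector.
#' @param cutoff A `"cutoff_spec"` or a bare numeric threshold (may be
#'   +/-Inf).
#' @return A `"confusion_metrics"` list.
#' @export
confusion_metrics <- function(scores, response, cutoff) {
  thr <- if (inherits(cutoff, "cutoff_spec")) cutoff$threshold else cutoff
  stopifnot(is.numeric(thr), length(thr) == 1)
  al <- align_scores_response(scores, response)
  cts <- counts_at(al$score, al$response == "responder", thr)
  confusion_from_counts(cts[["tp"]], cts[["fn"]], cts[["fp"]], cts[["tn"]])
}

#' @export
print.confusion_metrics <- function(x, ...) {
  fmt <- function(p, ci) if (is.na(p)) "undefined" else
    sprintf("%.3f (%.3f-%.3f)", p, ci[1], ci[2])
  cat(sprintf("counts: tp=%d fn=%d fp=%d tn=%d%s\n", x$tp, x$fn, x$fp, x$tn,
              if (x$haldane) "  [Haldane-corrected OR]" else ""))
  cat(" sensitivity:", fmt(x$sensitivity, x$sensitivity_ci), "\n",
      "specificity:", fmt(x$specificity, x$specificity_ci), "\n",
      "PPV:        ", fmt(x$ppv, x$ppv_ci), "\n",
      "NPV:        ", fmt(x$npv, x$npv_ci), "\n")
  cat(sprintf(" odds ratio: %.2f (%.3f-%.3f)\n", x$odds_ratio, x$or_ci_low,
              x$or_ci_high))
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test for predicted groups
#'
#' Overall-survival events beyond the censor horizon (default 60 months, i.e.
#' five years) are converted to censorings at the horizon to keep a few
#' outlying survivors from dominating; the product-limit estimator is
#' computed per group and groups are compared with the unweighted
#' (Mantel-Haenszel) log-rank test.
#'
#' @param clinical Clinical table with `sample_id`, `os_months`, `event`.
#' @param predicted_groups Named vector (by sample) of two group labels, e.g.
#'   predicted responder / non-responder.
#' @param censor_horizon_months Administrative censoring horizon.
#' @return A `"survival_result"` list: `curves` (data.frame `group`, `time`,
#'   `survival`, `n_risk`, `n_event`), `medians` (named, NA when the curve
#'   never falls to 0.5), `chisq`, `p_value`, `censor_horizon`.
#' @export
km_logrank <- function(clinical, predicted_groups,
                       censor_horizon_months = 60) {
  stopifnot(is.data.frame(clinical),
            all(c("sample_id", "os_months", "event") %in% names(clinical)))
  grp <- predicted_groups
  if (is.null(names(grp))) stop2("predicted_groups must be named by sample ID")
  common <- intersect(clinical$sample_id, names(grp))
  cl <- clinical[match(common, clinical$sample_id), ]
  g <- factor(as.character(grp[common]))
  if (nlevels(g) != 2) stop2("exactly two groups are required")
  if (min(table(g)) == 0) stop2("a group has zero subjects")
  time <- pmin(cl$os_months, censor_horizon_months)
  status <- as.integer(cl$event == "death" & cl$os_months <= censor_horizon_months)
  if (any(tapply(status, g, sum) == 0))
    stop2("each group needs >= 1 event after horizon censoring")
  fit <- survival::survfit(survival::Surv(time, status) ~ g)
  sm <- summary(fit)
  curves <- data.frame(group = sub("^g=", "", as.character(sm$strata)),
                       time = sm$time, survival = sm$surv,
                       n_risk = sm$n.risk, n_event = sm$n.event,
                       stringsAsFactors = FALSE)
  tab <- summary(fit)$table
  medians <- stats::setNames(tab[, "median"], sub("^g=", "", rownames(tab)))
  sd <- survival::survdiff(survival::Surv(time, status) ~ g)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  structure(list(curves = curves, medians = medians,
                 chisq = unname(sd$chisq), p_value = p,
                 censor_horizon = censor_horizon_months),
            class = "survival_result")
}

#' Covariate-adjusted logistic regression on the score
#'
#' Maximum-likelihood logistic regression (IRLS, convergence tolerance 1e-8,
#' at most 100 iterations) of responder status on the continuous score plus
#' clinical covariates, categorical covariates reference-coded.  Perfect
#' separation is detected and raised as an error.
#'
#' @param response Clinical table or named response vector.
#' @param score A `"score_vector"` or named numeric vector.
#' @param covariates Optional data.frame of covariates with a `sample_id`
#'   column (e.g. age, stage, debulking, race).
#' @return A data.frame (`term`, `estimate`, `se`, `z`, `p_value`).
#' @export
logistic_adjusted <- function(response, score, covariates = NULL) {
  al <- align_scores_response(score, response)
  df <- data.frame(.response = as.integer(al$response == "responder"),
                   score = al$score)
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), "sample_id" %in% names(covariates))
    cv <- covariates[match(al$sample_id, covariates$sample_id),
                     setdiff(names(covariates), "sample_id"), drop = FALSE]
    cv[] <- lapply(cv, function(x) if (is.character(x)) factor(x) else x)
    df <- cbind(df, cv)
  }
  fit <- stats::glm(.response ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop2("logistic regression did not converge")
  mu <- stats::fitted(fit)
  if (all(mu > 1 - 1e-6 | mu < 1e-6))
    stop2("perfect separation detected; coefficients are unbounded")
  co <- summary(fit)$coefficients
  data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
             z = co[, 3], p_value = co[, 4], row.names = NULL,
             stringsAsFactors = FALSE)
}
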