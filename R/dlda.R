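# Diagonal linear discriminant predictor of drug sensitivity, with nested
# (double) leave-one-out cross-validation for feature-count selection and an
# unbiased accuracy estimate.
#
# Discriminant for sample x:
#   d(x) = sum_g (mu_s,g - mu_r,g) * (x_g - (mu_s,g + mu_r,g)/2) / s2_g
#          + log(pi_s / pi_r)
# Higher d(x) = predicted sensitive.  Priors default to equal: extreme-tail
# class sizes reflect the tail fractions, not prevalence.

dlda_params <- function(X, idx_s, idx_r) {
  ns <- length(idx_s); nr <- length(idx_r)
  Xs <- X[, idx_s, drop = FALSE]; Xr <- X[, idx_r, drop = FALSE]
  ms <- rowMeans(Xs); mr <- rowMeans(Xr)
  ss <- rowSums((Xs - ms)^2); sr <- rowSums((Xr - mr)^2)
  v <- (ss + sr) / (ns + nr - 2)
  list(mean_sensitive = ms, mean_resistant = mr, pooled_var = v,
       n_s = ns, n_r = nr)
}

dlda_score <- function(ms, mr, v, priors, X) {
  w <- (ms - mr) / v
  b <- -sum(w * (ms + mr) / 2) + log(priors[1] / priors[2])
  drop(crossprod(w, X)) + b
}

#' Fit a diagonal linear discriminant sensitivity predictor
#'
#' Diagonal LDA on labeled cell lines: per-gene class means and pooled
#' variances with an independence (diagonal) covariance, suited to
#' many-genes/few-samples training.  Genes with zero pooled variance are
#' dropped with a warning.
#'
#' @param expr Genes x samples training matrix.
#' @param labels Sensitivity labels ([select_extreme_lines()] output or named
#'   vector).
#' @param gene_ids Genes to use (default all rows of `expr`).
#' @param priors Class priors `c(sensitive, resistant)`; `"equal"` (default)
#'   or `"empirical"` or a numeric pair summing to 1.
#' @param drug_name Optional drug label.
#' @return An object of class `"dlda"` with components `gene_ids`,
#'   `mean_sensitive`, `mean_resistant`, `pooled_var`, `priors`, `k`,
#'   `cv_accuracy` (NA unless fitted via [double_cross_validate()]).
#' @seealso [predict.dlda()], [double_cross_validate()], [score_cohort()]
#' @export
fit_dlda <- function(expr, labels, gene_ids = rownames(expr),
                     priors = c(0.5, 0.5), drug_name = NULL) {
  check_expression_matrix(expr)
  lab <- as_sensitivity_labels(labels)
  lab <- lab[names(lab) %in% colnames(expr)]
  idx_s <- names(lab)[lab == "sensitive"]
  idx_r <- names(lab)[lab == "resistant"]
  if (length(idx_s) < 2 || length(idx_r) < 2)
    stop2("need >= 2 samples per class")
  missing <- setdiff(gene_ids, rownames(expr))
  if (length(missing)) stop2("gene(s) not in expr: ", missing[1], " ...")
  if (identical(priors, "equal")) priors <- c(0.5, 0.5)
  if (identical(priors, "empirical"))
    priors <- c(length(idx_s), length(idx_r)) / (length(idx_s) + length(idx_r))
  stopifnot(is.numeric(priors), length(priors) == 2,
            abs(sum(priors) - 1) < 1e-8, all(priors > 0))
  X <- expr[gene_ids, , drop = FALSE]
  p <- dlda_params(X, idx_s, idx_r)
  ok <- p$pooled_var > 0
  if (any(!ok)) {
    warning(sum(!ok), " zero-pooled-variance gene(s) dropped", call. = FALSE)
    if (!any(ok)) stop2("all genes have zero pooled variance")
  }
  structure(list(drug_name = drug_name, gene_ids = gene_ids[ok],
                 mean_sensitive = p$mean_sensitive[ok],
                 mean_resistant = p$mean_resistant[ok],
                 pooled_var = p$pooled_var[ok],
                 priors = stats::setNames(priors, c("sensitive", "resistant")),
                 k = sum(ok), cv_accuracy = NA_real_,
                 n_train = c(sensitive = length(idx_s),
                             resistant = length(idx_r))),
            class = "dlda")
}

#' Predict from a diagonal LDA model
#'
#' @param object A `"dlda"` model.
#' @param newdata Genes x samples matrix containing the model genes.
#' @param type `"score"` for the raw discriminant (higher = predicted
#'   sensitive) or `"class"` for the implied label (ties to sensitive).
#' @param ... Unused.
#' @return Named numeric score vector or a factor of labels.
#' @export
predict.dlda <- function(object, newdata,
                         type = c("score", "class"), ...) {
  type <- match.arg(type)
  check_expression_matrix(newdata, "newdata")
  missing <- setdiff(object$gene_ids, rownames(newdata))
  if (length(missing)) stop2("newdata lacks model gene(s): ", missing[1], " ...")
  sc <- dlda_score(object$mean_sensitive, object$mean_resistant,
                   object$pooled_var, object$priors,
                   newdata[object$gene_ids, , drop = FALSE])
  sc <- stats::setNames(as.numeric(sc), colnames(newdata))
  if (type == "score") return(sc)
  factor(ifelse(sc >= 0, "sensitive", "resistant"),
         levels = c("sensitive", "resistant"))
}

#' @export
coef.dlda <- function(object, ...) {
  stats::setNames((object$mean_sensitive - object$mean_resistant) /
                    object$pooled_var, object$gene_ids)
}

#' @export
print.dlda <- function(x, ...) {
  cat("Diagonal LDA sensitivity predictor",
      if (!is.null(x$drug_name)) paste0("(", x$drug_name, ")"), "\n")
  cat("  genes:", length(x$gene_ids), " priors:",
      paste(sprintf("%s=%.2f", names(x$priors), x$priors), collapse = ", "),
      "\n")
  if (!is.na(x$cv_accuracy))
    cat(sprintf("  nested-CV accuracy: %.3f (k = %d)\n", x$cv_accuracy, x$k))
  invisible(x)
}

# Inner leave-one-out loop: for each candidate feature count k, LOO accuracy
# with per-fold re-ranking of genes by |Welch t|.  Returns accuracy per k.
inner_loo_accuracy <- function(X, lab, ks, priors) {
  n <- ncol(X)
  samples <- colnames(X)
  acc <- matrix(NA, n, length(ks))
  for (i in seq_len(n)) {
    tr <- samples[-i]
    lab_tr <- lab[tr]
    idx_s <- tr[lab_tr == "sensitive"]; idx_r <- tr[lab_tr == "resistant"]
    if (length(idx_s) < 2 || length(idx_r) < 2)
      stop2("a cross-validation fold lost a class; need more lines per class")
    w <- welch_t(X[, tr, drop = FALSE], idx_s, idx_r)
    ord <- order(-abs(w$statistic))
    p <- dlda_params(X[, tr, drop = FALSE], idx_s, idx_r)
    truth_s <- lab[samples[i]] == "sensitive"
    for (j in seq_along(ks)) {
      top <- ord[seq_len(min(ks[j], nrow(X)))]
      v <- p$pooled_var[top]
      ok <- v > 0
      if (!any(ok)) { acc[i, j] <- 0.5; next }
      sc <- dlda_score(p$mean_sensitive[top][ok], p$mean_resistant[top][ok],
                       v[ok], priors, X[top, i, drop = FALSE][ok, , drop = FALSE])
      acc[i, j] <- as.numeric((sc >= 0) == truth_s)
    }
  }
  colMeans(acc)
}

#' Double (nested) cross-validated DLDA
#'
#' Outer leave-one-out loop estimates unbiased prediction accuracy; within
#' each outer training fold an inner leave-one-out loop re-ranks genes by
#' |Welch t| and selects the candidate feature count maximizing inner
#' accuracy (smallest k on ties).  Gene ranking happens inside every fold, so
#' no selection information leaks into the accuracy estimate.  The returned
#' model is refit on all samples with the feature count chosen by the inner
#' loop on the full data.
#'
#' @param expr Genes x samples training matrix.
#' @param labels Sensitivity labels.
#' @param candidate_ks Candidate feature counts (default `c(5, 10, 20, 50,
#'   100)`, truncated to the number of available genes).
#' @param priors Passed to [fit_dlda()].
#' @param drug_name Optional drug label.
#' @return A `"dlda"` model with `k` (chosen feature count) and `cv_accuracy`
#'   (outer leave-one-out estimate) filled in, plus an `"outer_ks"` attribute
#'   recording the per-fold choices.
#' @export
double_cross_validate <- function(expr, labels,
                                  candidate_ks = c(5, 10, 20, 50, 100),
                                  priors = c(0.5, 0.5), drug_name = NULL) {
  check_expression_matrix(expr)
  lab <- as_sensitivity_labels(labels)
  lab <- lab[names(lab) %in% colnames(expr)]
  if (!length(candidate_ks)) stop2("candidate_ks must be non-empty")
  ks <- sort(unique(pmin(as.integer(candidate_ks), nrow(expr))))
  X <- expr[, names(lab), drop = FALSE]
  if (identical(priors, "equal")) priors <- c(0.5, 0.5)
  n <- ncol(X)
  samples <- colnames(X)
  correct <- logical(n)
  outer_ks <- integer(n)
  for (i in seq_len(n)) {
    tr <- samples[-i]
    lab_tr <- lab[tr]
    idx_s <- tr[lab_tr == "sensitive"]; idx_r <- tr[lab_tr == "resistant"]
    if (length(idx_s) < 2 || length(idx_r) < 2)
      stop2("an outer fold lost a class; need more lines per class")
    acc <- inner_loo_accuracy(X[, tr, drop = FALSE], lab_tr, ks, priors)
    k_i <- ks[which.max(acc)]            # which.max takes the smallest on ties
    outer_ks[i] <- k_i
    w <- welch_t(X[, tr, drop = FALSE], idx_s, idx_r)
    top <- order(-abs(w$statistic))[seq_len(k_i)]
    p <- dlda_params(X[, tr, drop = FALSE], idx_s, idx_r)
    v <- p$pooled_var[top]; ok <- v > 0
    sc <- dlda_score(p$mean_sensitive[top][ok], p$mean_resistant[top][ok],
                     v[ok], priors, X[top, i, drop = FALSE][ok, , drop = FALSE])
    correct[i] <- (sc >= 0) == (lab[samples[i]] == "sensitive")
  }
  acc_full <- inner_loo_accuracy(X, lab, ks, priors)
  k_star <- ks[which.max(acc_full)]
  w <- welch_t(X, names(lab)[lab == "sensitive"],
               names(lab)[lab == "resistant"])
  top_ids <- rownames(X)[order(-abs(w$statistic))[seq_len(k_star)]]
  model <- fit_dlda(X, lab, gene_ids = top_ids, priors = priors,
                    drug_name = drug_name)
  model$k <- k_star
  model$cv_accuracy <- mean(correct)
  attr(model, "outer_ks") <- outer_ks
  model
}

#' Score a patient cohort with a fitted predictor
#'
#' Applies the discriminant to each sample; model genes missing from the
#' cohort matrix are dropped from the discriminant sum (at least half must be
#' present).  The z score is the within-cohort standardization of the raw
#' score; if the cohort is degenerate (zero score variance) z is set to 0
#' with a warning.
#'
#' @param model A `"dlda"` model.
#' @param expr Cohort genes x samples matrix.
#' @return A `"score_vector"` data.frame (`sample_id`, `raw`, `z`).
#' @export
score_cohort <- function(model, expr) {
  stopifnot(inherits(model, "dlda"))
  check_expression_matrix(expr)
  present <- model$gene_ids %in% rownames(expr)
  if (mean(present) < 0.5)
    stop2("fewer than half of the model genes are present in the cohort (",
          sum(present), "/", length(present), ")")
  if (any(!present))
    warning(sum(!present), " model gene(s) absent from the cohort were ",
            "dropped from the discriminant", call. = FALSE)
  ids <- model$gene_ids[present]
  raw <- dlda_score(model$mean_sensitive[present],
                    model$mean_resistant[present],
                    model$pooled_var[present], model$priors,
                    expr[ids, , drop = FALSE])
  raw <- as.numeric(raw)
  s <- stats::sd(raw)
  if (length(raw) >= 2 && s > 0) {
    z <- (raw - mean(raw)) / s
  } else {
    if (length(raw) >= 2)
      warning("degenerate cohort: all raw scores equal; z set to 0",
              call. = FALSE)
    z <- rep(0, length(raw))
  }
  out <- data.frame(sample_id = colnames(expr), raw = raw, z = z,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Combine two single-drug scores into a combination score
#'
#' Under drug independence the combination score is the equal-weight sum of
#' the cohort-standardized single-drug scores, scaled to unit variance and
#' re-standardized within the cohort.  Symmetric in its arguments.
#'
#' @param score_a,score_b `"score_vector"`s over identical sample sets.
#' @return A `"score_vector"` (`raw` holds the pre-restandardization
#'   combination `(z_a + z_b)/sqrt(2)`).
#' @export
combine_scores <- function(score_a, score_b) {
  stopifnot(inherits(score_a, "data.frame"), inherits(score_b, "data.frame"))
  if (!setequal(score_a$sample_id, score_b$sample_id))
    stop2("score vectors cover different sample sets")
  b <- score_b[match(score_a$sample_id, score_b$sample_id), ]
  comb <- (score_a$z + b$z) / sqrt(2)
  s <- stats::sd(comb)
  z <- if (length(comb) >= 2 && s > 0) (comb - mean(comb)) / s else rep(0, length(comb))
  out <- data.frame(sample_id = score_a$sample_id, raw = comb, z = z,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_vector", "data.frame")
  out
}
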