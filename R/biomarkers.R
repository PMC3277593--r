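# Biomarker discovery from extreme-responding cell lines, and the
# FFPE-robustness and cross-cohort direction-consistency filters.

new_gene_score_table <- function(df, provenance) {
  attr(df, "provenance") <- provenance
  class(df) <- c("gene_score_table", "data.frame")
  df
}

#' Filter provenance of a candidate gene table
#'
#' @param x A gene score table or biomarker set.
#' @return A data.frame with one row per applied filter (`filter`, `n_before`,
#'   `n_after`).
#' @export
provenance <- function(x) {
  p <- attr(x, "provenance")
  if (is.null(p)) p <- list()
  do.call(rbind, lapply(p, function(e)
    data.frame(filter = e$filter, n_before = e$n_before, n_after = e$n_after,
               stringsAsFactors = FALSE)))
}

append_provenance <- function(x, filter, n_before, n_after) {
  p <- attr(x, "provenance")
  if (is.null(p)) p <- list()
  p[[length(p) + 1]] <- list(filter = filter, n_before = n_before,
                             n_after = n_after)
  attr(x, "provenance") <- p
  x
}

#' Label extreme sensitive/resistant cell lines
#'
#' Labels the most sensitive `ceiling(upper_fraction * n)` lines "sensitive"
#' and the least sensitive `ceiling(lower_fraction * n)` "resistant" on a
#' higher-is-more-sensitive activity scale; middle lines are excluded.  Lines
#' tied with the boundary value are all included in the tail.  Per-tail
#' fractions must lie in the 10-35% range used for extreme-responder biomarker
#' discovery.
#'
#' @param activity A `"drug_activity"` object or named numeric vector of
#'   activities.
#' @param tail_fraction Fraction used for both tails (default 0.30).
#' @param upper_fraction,lower_fraction Optional per-tail overrides.
#' @return A data.frame (`sample_id`, `label`) with labels in
#'   \{"sensitive", "resistant"\}.
#' @export
select_extreme_lines <- function(activity, tail_fraction = 0.30,
                                 upper_fraction = tail_fraction,
                                 lower_fraction = tail_fraction) {
  if (inherits(activity, "drug_activity")) {
    act <- activity$activity
    names(act) <- activity$cell_line_ids
  } else {
    act <- activity
    if (is.null(names(act))) stop2("activity must be named by cell line ID")
  }
  if (anyDuplicated(names(act))) stop2("duplicate cell line IDs")
  if (any(!is.finite(act))) stop2("activity values must be finite")
  # Discovery convention is 10-35% per tail; explicit per-tail overrides may
  # deviate modestly so published asymmetric class sizes stay representable.
  if (tail_fraction < 0.10 || tail_fraction > 0.35)
    stop2("tail_fraction must lie in [0.10, 0.35]")
  for (f in c(upper_fraction, lower_fraction))
    if (f < 0.05 || f > 0.45)
      stop2("per-tail fractions must lie in [0.05, 0.45]")
  n <- length(act)
  n_up <- ceiling(upper_fraction * n)
  n_lo <- ceiling(lower_fraction * n)
  if (n_up < 2 || n_lo < 2)
    stop2("need at least 2 lines per tail; increase the tail fraction or n")
  srt <- sort(act, decreasing = TRUE)
  sens <- names(act)[act >= srt[n_up]]           # ties at boundary included
  res <- names(act)[act <= sort(act)[n_lo]]
  if (length(intersect(sens, res)))
    stop2("tails overlap (2 * ceiling(tail_fraction * n) > n or heavy ties); ",
          "reduce the tail fractions")
  data.frame(sample_id = c(sens, res),
             label = c(rep("sensitive", length(sens)),
                       rep("resistant", length(res))),
             stringsAsFactors = FALSE)
}

# Vectorized Welch two-sample t across rows of X (genes x samples).
welch_t <- function(X, idx_s, idx_r) {
  ns <- length(idx_s); nr <- length(idx_r)
  Xs <- X[, idx_s, drop = FALSE]; Xr <- X[, idx_r, drop = FALSE]
  ms <- rowMeans(Xs); mr <- rowMeans(Xr)
  vs <- rowSums((Xs - ms)^2) / (ns - 1)
  vr <- rowSums((Xr - mr)^2) / (nr - 1)
  se2 <- vs / ns + vr / nr
  stat <- (ms - mr) / sqrt(se2)
  df <- se2^2 / ((vs / ns)^2 / (ns - 1) + (vr / nr)^2 / (nr - 1))
  zero <- se2 == 0
  stat[zero & (ms == mr)] <- 0
  stat[zero & (ms != mr)] <- sign((ms - mr)[zero & (ms != mr)]) * Inf
  df[zero] <- ns + nr - 2
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  p[is.na(p)] <- 1
  stat[is.na(stat)] <- 0
  list(statistic = stat, df = df, p_value = p,
       direction = ifelse(ms >= mr, 1, -1))
}

#' Rank chemosensitivity candidate genes
#'
#' Welch two-sample t statistic per gene between the sensitive and resistant
#' extreme cell lines; genes with `p < alpha` are retained, ordered by
#' decreasing |t| and truncated to `max_genes`.
#'
#' @param expr Genes x samples expression matrix containing the labeled
#'   lines.
#' @param labels Output of [select_extreme_lines()] (or a named label
#'   vector).
#' @param alpha Retention threshold on the two-sided p-value.
#' @param max_genes Cap on the number of genes returned.
#' @return A `"gene_score_table"` data.frame (`gene_id`, `statistic`,
#'   `p_value`, `direction`) carrying filter provenance.
#' @export
rank_chemosensitivity_genes <- function(expr, labels, alpha = 0.05,
                                        max_genes = 500) {
  check_expression_matrix(expr)
  lab <- as_sensitivity_labels(labels)
  lab <- lab[names(lab) %in% colnames(expr)]
  idx_s <- names(lab)[lab == "sensitive"]
  idx_r <- names(lab)[lab == "resistant"]
  if (length(idx_s) < 2 || length(idx_r) < 2)
    stop2("each class needs >= 2 samples in expr (variance undefined)")
  w <- welch_t(expr, idx_s, idx_r)
  df <- data.frame(gene_id = rownames(expr), statistic = w$statistic,
                   p_value = w$p_value, direction = w$direction,
                   stringsAsFactors = FALSE, row.names = NULL)
  n0 <- nrow(df)
  df <- df[df$p_value < alpha, , drop = FALSE]
  df <- df[order(-abs(df$statistic)), , drop = FALSE]
  if (is.finite(max_genes) && nrow(df) > max_genes)
    df <- df[seq_len(max_genes), , drop = FALSE]
  rownames(df) <- NULL
  out <- new_gene_score_table(df, list())
  append_provenance(out, "welch_t_rank", n0, nrow(df))
}

#' Restrict candidates to FFPE-robust genes
#'
#' @param genes A `"gene_score_table"`.
#' @param robust_ids Character vector of FFPE-robust gene IDs.
#' @return The table restricted to robust genes, order preserved, provenance
#'   appended.
#' @export
filter_ffpe_robust <- function(genes, robust_ids) {
  stopifnot(inherits(genes, "gene_score_table"))
  n0 <- nrow(genes)
  keep <- genes$gene_id %in% robust_ids
  if (!any(keep))
    stop2("no candidate gene is FFPE-robust (", n0, " candidates vs ",
          length(robust_ids), " robust IDs, empty intersection)")
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- new_gene_score_table(out, attr(genes, "provenance"))
  append_provenance(out, "ffpe_robust", n0, nrow(out))
}

#' Keep genes whose effect direction replicates in patients
#'
#' Per candidate gene, the sign of (mean responder - mean non-responder)
#' expression in the patient cohort must equal the cell-line direction;
#' inconsistent genes are excluded.  Genes absent from the patient matrix are
#' dropped with a warning.
#'
#' @param genes A `"gene_score_table"`.
#' @param patient_expr Patient genes x samples matrix.
#' @param patient_response Clinical table (or named response vector) for the
#'   patient cohort.
#' @return Filtered `"gene_score_table"`, order preserved.
#' @export
filter_direction_consistent <- function(genes, patient_expr,
                                        patient_response) {
  stopifnot(inherits(genes, "gene_score_table"))
  check_expression_matrix(patient_expr, "patient_expr")
  resp <- as_response(patient_response)
  resp <- resp[names(resp) %in% colnames(patient_expr)]
  idx_r <- names(resp)[resp == "responder"]
  idx_n <- names(resp)[resp == "non_responder"]
  if (!length(idx_r) || !length(idx_n))
    stop2("patient cohort must contain both responders and non-responders")
  n0 <- nrow(genes)
  present <- genes$gene_id %in% rownames(patient_expr)
  if (any(!present))
    warning(sum(!present), " candidate gene(s) absent from the patient ",
            "matrix were dropped", call. = FALSE)
  g <- genes[present, , drop = FALSE]
  mr <- rowMeans(patient_expr[g$gene_id, idx_r, drop = FALSE])
  mn <- rowMeans(patient_expr[g$gene_id, idx_n, drop = FALSE])
  pat_dir <- ifelse(mr >= mn, 1, -1)
  out <- g[pat_dir == g$direction, , drop = FALSE]
  rownames(out) <- NULL
  out <- new_gene_score_table(out, attr(genes, "provenance"))
  append_provenance(out, "direction_consistent", n0, nrow(out))
}
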