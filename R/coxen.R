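# The COXEN "correlation of correlations" concordance coefficient: per gene,
# the correlation between its correlation vector (against all other candidate
# genes) computed in the cell-line set and the same vector computed in the
# patient set.  Significance by gene-identity permutation.

#' Pairwise gene-gene correlation matrix
#'
#' Pearson correlation for every pair of the requested genes across samples.
#'
#' @param expr Genes x samples matrix (>= 3 samples).
#' @param gene_ids Genes to include (all must be present).
#' @return Symmetric correlation matrix with gene IDs as dimnames.
#' @export
correlation_matrix <- function(expr, gene_ids = rownames(expr)) {
  check_expression_matrix(expr)
  if (ncol(expr) < 3) stop2("need >= 3 samples to estimate correlations")
  missing <- setdiff(gene_ids, rownames(expr))
  if (length(missing))
    stop2("gene(s) not in expr: ", paste(utils::head(missing, 5), collapse = ", "))
  X <- expr[gene_ids, , drop = FALSE]
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0))
    stop2("zero-variance gene(s): ",
          paste(utils::head(gene_ids[sds == 0], 5), collapse = ", "))
  stats::cor(t(X))
}

check_cor_pair <- function(corrA, corrB) {
  if (!identical(rownames(corrA), rownames(corrB)))
    stop2("corrA and corrB must cover identical gene_ids in identical order")
  if (nrow(corrA) < 3)
    stop2("need >= 3 genes for a defined concordance coefficient")
}

# Per-gene correlation between row g of A and row g of B, self-entry removed.
coxen_coef_vec <- function(corrA, corrB) {
  G <- nrow(corrA)
  vapply(seq_len(G), function(g)
    stats::cor(corrA[g, -g], corrB[g, -g]), numeric(1))
}

#' COXEN concordance coefficients
#'
#' For each gene, the Pearson correlation between its row of the cell-line
#' correlation matrix and its row of the patient correlation matrix (self
#' entries removed).  A coefficient near 1 means the gene's co-expression
#' neighbourhood is conserved between the two sets.
#'
#' @param corrA,corrB Correlation matrices from [correlation_matrix()] on the
#'   identical, identically ordered gene set.
#' @return A `"coxen_coefficients"` data.frame (`gene_id`, `coefficient`).
#' @export
coxen_coefficients <- function(corrA, corrB) {
  check_cor_pair(corrA, corrB)
  out <- data.frame(gene_id = rownames(corrA),
                    coefficient = coxen_coef_vec(corrA, corrB),
                    stringsAsFactors = FALSE)
  class(out) <- c("coxen_coefficients", "data.frame")
  out
}

#' Permutation significance for COXEN coefficients
#'
#' The null is built by randomly permuting the gene identities of the patient
#' set's correlation matrix (rows and columns together) and recomputing each
#' gene's coefficient; this breaks the cell-line/patient gene matching while
#' preserving both correlation structures.  Two-sided:
#' `p = (1 + #\{|null| >= |observed|\}) / (n_permutations + 1)`.
#'
#' @param exprA,exprB Cell-line and patient expression matrices.
#' @param gene_ids Candidate genes present in both matrices.
#' @param n_permutations Number of permutations (>= 99).
#' @param seed RNG seed; identical seeds give identical p-values.
#' @return A `"coxen_coefficients"` data.frame (`gene_id`, `coefficient`,
#'   `p_value`) with `n_permutations` and `seed` attributes.
#' @export
coxen_permutation_test <- function(exprA, exprB, gene_ids,
                                   n_permutations = 1000, seed = 1) {
  if (n_permutations < 99) stop2("n_permutations must be >= 99")
  corrA <- correlation_matrix(exprA, gene_ids)
  corrB <- correlation_matrix(exprB, gene_ids)
  obs <- coxen_coef_vec(corrA, corrB)
  G <- length(gene_ids)
  exceed <- integer(G)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_permutations)) {
      perm <- sample.int(G)
      corrBp <- corrB[perm, perm]
      null_b <- coxen_coef_vec(corrA, corrBp)
      exceed <- exceed + (abs(null_b) >= abs(obs))
    }
  })
  out <- data.frame(gene_id = gene_ids, coefficient = obs,
                    p_value = (1 + exceed) / (n_permutations + 1),
                    stringsAsFactors = FALSE)
  attr(out, "n_permutations") <- as.integer(n_permutations)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("coxen_coefficients", "data.frame")
  out
}

#' Select concordant biomarkers
#'
#' Retains candidate genes whose COXEN permutation p-value is below `alpha`,
#' ordered by the candidates' |t| statistic, and records the filter in the
#' provenance chain.
#'
#' @param coeffs Output of [coxen_permutation_test()].
#' @param alpha Significance threshold in (0, 1].
#' @param candidates The `"gene_score_table"` the genes came from.
#' @param drug_name Drug label stored on the result.
#' @return A `"biomarker_set"`: list with `drug_name`, `gene_ids` (ordered by
#'   |t|), `scores` (the retained rows) and provenance.
#' @export
select_coxen_genes <- function(coeffs, alpha = 0.05, candidates,
                               drug_name = "drug") {
  stopifnot(inherits(coeffs, "coxen_coefficients"),
            inherits(candidates, "gene_score_table"))
  if (alpha <= 0 || alpha > 1) stop2("alpha must be in (0, 1]")
  if (!"p_value" %in% names(coeffs))
    stop2("coeffs must carry permutation p-values")
  keep_ids <- coeffs$gene_id[coeffs$p_value < alpha | alpha >= 1]
  out <- candidates[candidates$gene_id %in% keep_ids, , drop = FALSE]
  if (!nrow(out))
    stop2("no gene passes the COXEN concordance filter at alpha = ", alpha,
          "; consider a larger alpha or more candidates")
  out <- out[order(-abs(out$statistic)), , drop = FALSE]
  rownames(out) <- NULL
  prov <- attr(candidates, "provenance")
  set <- structure(list(drug_name = drug_name, gene_ids = out$gene_id,
                        scores = out),
                   class = "biomarker_set")
  attr(set, "provenance") <- prov
  set <- append_provenance(set, "coxen_concordance", nrow(candidates),
                           nrow(out))
  set
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat("Biomarker set for", x$drug_name, "-", length(x$gene_ids), "genes\n")
  p <- provenance(x)
  if (!is.null(p)) {
    cat("Filter chain:\n")
    print(p, row.names = FALSE)
  }
  invisible(x)
}
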