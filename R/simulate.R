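# Synthetic data generator: cell-line panels, patient cohorts, and paired
# frozen/FFPE profiles with the statistical structure the COXEN analysis
# assumes, plus planted ground truth for recovery tests.
#
# Co-expression sharing is implemented via latent factors: every gene carries
# a loading vector; concordant genes reuse the SAME loadings in cell panel and
# patient cohorts (so their gene-gene correlation structure transfers), while
# non-concordant genes get independent loadings per data set.

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator.  Defaults emulate
#' the study conditions this package targets: a 60-line cell panel profiled
#' genome-wide, patient cohorts of 100 with a 58% complete-response rate, a
#' planted standardized effect of 1.5 between sensitive and resistant
#' classes, 55% of genes surviving FFPE degradation, and exponential survival
#' with a non-responder/responder hazard ratio of 1.72 (median 55.4 months in
#' responders).
#'
#' @param n_genes Number of genes.
#' @param n_cell_lines Number of cell lines in the panel.
#' @param n_patients Default cohort size for [simulate_patient_cohort()].
#' @param n_informative Number of drug-associated genes (drawn from the
#'   concordant set first, so the signal is transferable).
#' @param n_concordant Number of genes whose co-expression structure is shared
#'   between the cell panel and patient cohorts.
#' @param effect_size Standardized mean difference (in units of `noise_sd`)
#'   between sensitive and resistant classes on informative genes.  In the
#'   cell panel the expression-activity slope is calibrated so that the
#'   difference between ~30% extreme tails matches this value.
#' @param response_rate Fraction of cohort patients that are responders (CR).
#' @param ffpe_robust_fraction Fraction of genes surviving FFPE degradation.
#' @param noise_sd Residual (non-factor) standard deviation.
#' @param n_factors Number of shared latent co-expression factors.
#' @param factor_sd Standard deviation of the latent-factor component of each
#'   gene; controls the strength of the plantable co-expression signal.
#' @param hazard_ratio Planted non-responder vs responder hazard ratio.
#' @param median_survival_responder Median overall survival of responders, in
#'   months (exponential model).
#' @param censor_range Range (months) of the uniform independent censoring
#'   time.
#' @param ffpe_noise_sd Measurement noise added to FFPE-robust genes; defaults
#'   to `0.25 * noise_sd`.
#' @param seed Master RNG seed; all generator randomness derives from it.
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_genes = 500, n_cell_lines = 60, n_patients = 100,
                       n_informative = 40, n_concordant = 100,
                       effect_size = 1.5, response_rate = 0.58,
                       ffpe_robust_fraction = 0.55, noise_sd = 1,
                       n_factors = 4, factor_sd = 1,
                       hazard_ratio = 1.72, median_survival_responder = 55.4,
                       censor_range = c(36, 120),
                       ffpe_noise_sd = 0.25 * noise_sd, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cell_lines = as.integer(n_cell_lines),
              n_patients = as.integer(n_patients),
              n_informative = as.integer(n_informative),
              n_concordant = as.integer(n_concordant),
              effect_size = effect_size, response_rate = response_rate,
              ffpe_robust_fraction = ffpe_robust_fraction,
              noise_sd = noise_sd, n_factors = as.integer(n_factors),
              factor_sd = factor_sd, hazard_ratio = hazard_ratio,
              median_survival_responder = median_survival_responder,
              censor_range = censor_range, ffpe_noise_sd = ffpe_noise_sd,
              seed = as.integer(seed))
  if (cfg$n_genes < 1 || cfg$n_cell_lines < 4 || cfg$n_patients < 4)
    stop2("n_genes, n_cell_lines and n_patients must be positive (panel >= 4)")
  if (cfg$n_informative > cfg$n_genes)
    stop2("configuration error: n_informative > n_genes")
  if (cfg$n_concordant > cfg$n_genes)
    stop2("configuration error: n_concordant > n_genes")
  if (cfg$response_rate <= 0 || cfg$response_rate >= 1)
    stop2("response_rate must be in (0, 1)")
  if (cfg$ffpe_robust_fraction < 0 || cfg$ffpe_robust_fraction > 1)
    stop2("ffpe_robust_fraction must be in [0, 1]")
  if (cfg$noise_sd <= 0 || cfg$factor_sd < 0)
    stop2("noise_sd must be > 0 and factor_sd >= 0")
  if (cfg$hazard_ratio <= 0) stop2("hazard_ratio must be positive")
  class(cfg) <- "sim_config"
  cfg
}

gene_ids_for <- function(n) sprintf("g%05d", seq_len(n))

# Unit-norm latent-factor loadings, one row per gene.
draw_loadings <- function(n, k) {
  L <- matrix(stats::rnorm(n * k), n, k)
  L / sqrt(rowSums(L^2))
}

# Structure shared by every data set generated under one config: which genes
# are concordant and their latent loadings.  Seeded from config$seed alone, so
# panels for different drugs under the same config share it.
shared_structure <- function(config) {
  withr::with_seed(derive_seed(config$seed, "shared-structure"), {
    ids <- gene_ids_for(config$n_genes)
    concordant <- sort(sample(ids, config$n_concordant))
    L <- draw_loadings(config$n_concordant, config$n_factors)
    rownames(L) <- concordant
    list(gene_ids = ids, concordant = concordant, loadings = L)
  })
}

#' Simulate a cell-line panel with drug activity
#'
#' Generates a genes x cell-lines expression matrix, a continuous drug
#' activity profile (higher = more sensitive, a negative-log-GI50-like
#' convention), and the planted ground truth.  Informative genes track
#' standardized activity with slope `effect_size/2 * noise_sd` in the planted
#' direction; concordant genes share latent-factor loadings that patient
#' cohorts generated under the same config reuse; all other variation is
#' noise.
#'
#' @param config A [sim_config()] object.
#' @param drug Drug name; panels for different drugs under the same config
#'   share the concordant co-expression structure but draw independent
#'   activities and informative gene sets.
#' @return A list with elements `expr` (matrix), `activity` (a
#'   `"drug_activity"` list: `drug_name`, `cell_line_ids`, `activity`,
#'   `source_metric`) and `truth` (a `"synthetic_truth"` list).
#' @export
simulate_cell_panel <- function(config, drug = "carboplatin") {
  stopifnot(inherits(config, "sim_config"))
  shared <- shared_structure(config)
  G <- config$n_genes; n <- config$n_cell_lines
  ids <- shared$gene_ids
  withr::with_seed(derive_seed(config$seed, paste0("panel-", drug)), {
    pool <- c(sample(shared$concordant),
              sample(setdiff(ids, shared$concordant)))
    informative <- sort(pool[seq_len(config$n_informative)])
    directions <- stats::setNames(sample(c(-1, 1), config$n_informative,
                                         replace = TRUE), informative)
    activity <- stats::setNames(stats::rnorm(n), sprintf("CL%03d", seq_len(n)))
    z_act <- as.vector(scale(activity))

    FF <- matrix(stats::rnorm(n * config$n_factors), n, config$n_factors)
    L <- matrix(0, G, config$n_factors, dimnames = list(ids, NULL))
    L[shared$concordant, ] <- shared$loadings
    free <- setdiff(ids, shared$concordant)
    L[free, ] <- draw_loadings(length(free), config$n_factors)

    X <- config$factor_sd * (L %*% t(FF)) +
      config$noise_sd * matrix(stats::rnorm(G * n), G, n)
    X[informative, ] <- X[informative, ] +
      (directions * (config$effect_size / 2) * config$noise_sd) %o% z_act
    dimnames(X) <- list(ids, names(activity))

    truth <- structure(list(
      informative_genes = informative, directions = directions,
      concordant_genes = shared$concordant, robust_genes = NULL,
      hazard_ratio = config$hazard_ratio, loadings = shared$loadings,
      drug_name = drug), class = "synthetic_truth")
    act <- structure(list(drug_name = drug, cell_line_ids = names(activity),
                          activity = activity,
                          source_metric = "gi50_neg_log"),
                     class = "drug_activity")
    list(expr = expression_matrix(X, platform = "synthetic-cell-panel"),
         activity = act, truth = truth)
  })
}

#' Merge ground truths from several drug panels
#'
#' Unions the informative gene sets (first truth wins on direction conflicts)
#' so one patient cohort can carry the response effects of every drug in a
#' combination.  Concordant structure must be identical (same config).
#'
#' @param ... Two or more `"synthetic_truth"` objects from
#'   [simulate_cell_panel()] under the same config.
#' @return A merged `"synthetic_truth"`.
#' @export
merge_truths <- function(...) {
  truths <- list(...)
  stopifnot(length(truths) >= 1,
            all(vapply(truths, inherits, logical(1), "synthetic_truth")))
  out <- truths[[1]]
  for (tr in truths[-1]) {
    if (!identical(tr$concordant_genes, out$concordant_genes))
      stop2("truths to merge must share the concordant structure")
    new <- setdiff(tr$informative_genes, out$informative_genes)
    out$informative_genes <- sort(c(out$informative_genes, new))
    out$directions <- c(out$directions, tr$directions[new])
    out$directions <- out$directions[out$informative_genes]
    out$drug_name <- paste(out$drug_name, tr$drug_name, sep = "+")
  }
  out
}

#' Simulate a patient cohort concordant with a cell panel
#'
#' Concordant genes reuse the cell panel's latent-factor loadings (fresh
#' factor scores), so their gene-gene correlation structure matches the
#' panel's; non-concordant genes get independent structure.  Responders and
#' non-responders differ by `effect_size * noise_sd` on informative-and-
#' concordant genes in the planted direction.  Overall survival is
#' exponential with the planted non-responder/responder hazard ratio and
#' independent uniform censoring; covariates (age, stage, debulking, race)
#' are drawn null, matching typical advanced ovarian-carcinoma cohort
#' demographics.
#'
#' @param config A [sim_config()] object.
#' @param truth A `"synthetic_truth"` from [simulate_cell_panel()] (possibly
#'   [merge_truths()]-combined).
#' @param cohort_id Cohort label; cohorts with different labels under the same
#'   config are independent draws.
#' @param n_patients Cohort size (default `config$n_patients`).
#' @return A list with `expr` (matrix), `clinical` (data.frame: `sample_id`,
#'   `response` code CR/PR/PD, `response_class`, `os_months`, `event`, `age`,
#'   `stage`, `debulking`, `race`) and `truth`.
#' @export
simulate_patient_cohort <- function(config, truth, cohort_id = "cohort",
                                    n_patients = config$n_patients) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(truth) || !inherits(truth, "synthetic_truth"))
    stop2("truth from a prior simulate_cell_panel() call is required")
  shared <- shared_structure(config)
  G <- config$n_genes; n <- as.integer(n_patients)
  ids <- shared$gene_ids
  withr::with_seed(derive_seed(config$seed, paste0("cohort-", cohort_id)), {
    responder <- stats::rbinom(n, 1, config$response_rate) == 1
    sample_ids <- sprintf("%s_P%03d", cohort_id, seq_len(n))

    FF <- matrix(stats::rnorm(n * config$n_factors), n, config$n_factors)
    L <- matrix(0, G, config$n_factors, dimnames = list(ids, NULL))
    L[shared$concordant, ] <- truth$loadings[shared$concordant, ]
    free <- setdiff(ids, shared$concordant)
    L[free, ] <- draw_loadings(length(free), config$n_factors)

    X <- config$factor_sd * (L %*% t(FF)) +
      config$noise_sd * matrix(stats::rnorm(G * n), G, n)
    planted <- intersect(truth$informative_genes, shared$concordant)
    if (length(planted)) {
      shift <- (truth$directions[planted] * config$effect_size *
                  config$noise_sd) %o% (ifelse(responder, 0.5, -0.5))
      X[planted, ] <- X[planted, ] + shift
    }
    dimnames(X) <- list(ids, sample_ids)

    lam_resp <- log(2) / config$median_survival_responder
    lam <- ifelse(responder, lam_resp, lam_resp * config$hazard_ratio)
    t_event <- stats::rexp(n, lam)
    t_cens <- stats::runif(n, config$censor_range[1], config$censor_range[2])
    os <- pmin(t_event, t_cens)
    event <- ifelse(t_event <= t_cens, "death", "censored")

    clinical <- data.frame(
      sample_id = sample_ids,
      response = ifelse(responder, "CR",
                        sample(c("PR", "PD"), n, TRUE, prob = c(0.7, 0.3))),
      response_class = ifelse(responder, "responder", "non_responder"),
      os_months = round(os, 2),
      event = event,
      age = pmin(pmax(round(stats::rnorm(n, 62, 7)), 38), 85),
      stage = sample(c("III", "IV"), n, TRUE, prob = c(0.91, 0.09)),
      debulking = sample(c("optimal", "suboptimal"), n, TRUE,
                         prob = c(0.55, 0.45)),
      race = sample(c("White", "Black"), n, TRUE, prob = c(0.93, 0.07)),
      stringsAsFactors = FALSE)

    list(expr = expression_matrix(X, platform = "synthetic-cohort"),
         clinical = clinical, truth = truth)
  })
}

#' Simulate an FFPE profile paired to a frozen one
#'
#' A planted fraction of genes is "FFPE-robust": their FFPE measurements are
#' the frozen values plus small measurement noise.  The remaining genes lose
#' their signal (10% of the centered frozen value plus noise at the gene's
#' own scale), decorrelating them from the frozen profile.
#'
#' @param expr Frozen genes x samples matrix.
#' @param config A [sim_config()] object (uses `ffpe_robust_fraction`,
#'   `ffpe_noise_sd`, `seed`).
#' @return A list with `expr` (FFPE matrix, same dimensions) and `truth` (a
#'   `"synthetic_truth"` carrying `robust_genes`).
#' @export
simulate_ffpe_pair <- function(expr, config) {
  stopifnot(inherits(config, "sim_config"))
  check_expression_matrix(expr)
  if (nrow(expr) == 0) stop2("expr must be non-empty")
  withr::with_seed(derive_seed(config$seed, "ffpe"), {
    ids <- rownames(expr)
    n_robust <- round(config$ffpe_robust_fraction * nrow(expr))
    robust <- sort(sample(ids, n_robust))
    ffpe <- expr
    if (length(robust))
      ffpe[robust, ] <- expr[robust, ] +
        config$ffpe_noise_sd * matrix(stats::rnorm(length(robust) * ncol(expr)),
                                      length(robust), ncol(expr))
    lost <- setdiff(ids, robust)
    if (length(lost)) {
      m <- rowMeans(expr[lost, , drop = FALSE])
      s <- apply(expr[lost, , drop = FALSE], 1, stats::sd)
      s[s == 0] <- config$noise_sd
      ffpe[lost, ] <- m + 0.1 * (expr[lost, , drop = FALSE] - m) +
        s * matrix(stats::rnorm(length(lost) * ncol(expr)),
                   length(lost), ncol(expr))
    }
    truth <- structure(list(informative_genes = character(0),
                            directions = numeric(0),
                            concordant_genes = character(0),
                            robust_genes = robust,
                            hazard_ratio = config$hazard_ratio,
                            loadings = NULL, drug_name = NA_character_),
                       class = "synthetic_truth")
    list(expr = expression_matrix(ffpe, platform = "synthetic-ffpe"),
         truth = truth)
  })
}
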