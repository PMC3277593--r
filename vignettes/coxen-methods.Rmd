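---
title: "Methods: co-expression extrapolation for chemosensitivity prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression extrapolation for chemosensitivity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Chemotherapy response signatures trained directly on patient cohorts are
confounded by combination regimens, prognosis and treatment heterogeneity.
Drug screens on cancer cell-line panels avoid those confounders — each line
has a clean single-drug activity readout (a GI50-derived measure or percent
kill) next to a genome-wide expression profile — but most in vitro markers
do not behave the same way in tumors. Co-expression extrapolation (COXEN)
bridges the gap by keeping only markers whose *co-expression context* is
conserved between the cell panel and human tumors, on the premise that a
gene embedded in the same regulatory neighbourhood in vitro and in vivo will
carry its drug-response association across.

This package implements that workflow end to end for single drugs and a
two-drug combination, together with a synthetic-data generator that plants
every ingredient of the analysis (drug-associated genes, shared
co-expression structure, response effects, survival differences, FFPE
degradation) so the whole chain can be tested for recovery and for honesty
under the null.

## Pipeline stages

1. **Extreme-responder labeling.** On a higher-is-more-sensitive activity
   scale, the top and bottom `tail_fraction` of lines (default 0.30 per
   tail, the conventional 10–35% range; per-tail overrides are allowed for
   published asymmetric designs) become the sensitive/resistant training
   classes; the middle is excluded. Boundary ties are included, which makes
   the labeling invariant to monotone transforms of activity.
2. **Candidate ranking.** A Welch two-sample *t* per gene between the
   extreme classes; genes with `p < rank_alpha` (default 0.05) are kept,
   ordered by |t|, capped at `max_genes` (default 500). The extreme-group
   *t* orders genes like a point-biserial correlation with activity but has
   a usable p-value, which is why it is the default statistic here.
   No multiplicity correction is applied at this stage: the later filters,
   not this screen, control the false content of the final set.
3. **FFPE-robustness filter.** Candidates are intersected with the list of
   genes whose measurements survive formalin fixation (in simulation, the
   planted robust set; in practice a list derived from paired frozen/FFPE
   profiles). Provenance records counts before/after every filter.
4. **Direction consistency.** A candidate must show the same sign of
   (responder − non-responder) mean expression in an independent development
   cohort as it showed between sensitive and resistant lines. Under a null
   cohort this halves the list; for true markers it is nearly lossless.
5. **Concordance (COXEN) selection.** For the candidate set, compute the
   gene–gene Pearson correlation matrix in the cell panel (A) and in the
   development cohort (B). Gene *g*'s COXEN coefficient is the correlation
   between row *g* of A and row *g* of B with the self-entry removed — a
   second-order, "correlation of correlations" statistic in [−1, 1].
   Significance comes from permuting the **gene identities** of B (rows and
   columns together) and recomputing: this breaks the A↔B gene matching,
   which is exactly the null of interest, while sample permutation would
   instead destroy B's correlation structure altogether. Two-sided
   `p = (1 + #{|null| ≥ |obs|}) / (B + 1)`; genes with `p < coxen_alpha`
   (default 0.05, 1000 permutations) survive.
6. **Predictor training.** Diagonal LDA on the labeled lines:

   `d(x) = Σ_g (μ_s,g − μ_r,g)(x_g − (μ_s,g + μ_r,g)/2)/σ²_g + log(π_s/π_r)`

   with per-gene pooled variances. The diagonal (independence) covariance is
   forced by the geometry — tens of lines against tens to hundreds of genes
   make the pooled full covariance singular. Priors default to **equal**:
   the class sizes are an artifact of the tail fractions, not of
   prevalence, and empirical priors would bias leave-one-out estimates on
   top of that. The feature count *k* is chosen by **double (nested)
   leave-one-out cross-validation**: the outer loop estimates accuracy, the
   inner loop (within each outer training fold) re-ranks genes by |t| and
   picks the `candidate_ks` member with the best inner accuracy, smallest
   *k* on ties. Ranking happens inside every fold — no selection leakage —
   and the test suite verifies both the honesty of the outer estimate on
   null data and the measurable optimism of a deliberately leaky variant.
7. **Scoring and combination.** Cohorts are scored with the discriminant
   and standardized within cohort (z-scores), which is what makes scores
   transferable across platforms and tissue types. The combination score
   under assumed drug independence is `(z_a + z_b)/√2`, re-standardized; the
   equal-weight rule is the simplest symmetric choice consistent with that
   assumption.
8. **Evaluation.** Wilcoxon rank-sum stratification (exact when both groups
   have ≤ 8 tie-free observations, normal approximation with tie correction
   otherwise); AUC as the Mann–Whitney concordance probability with a
   seeded stratified percentile bootstrap CI (default 2000 resamples);
   cutoffs on the z scale by Youden's J or by NPV maximization subject to a
   minimum predicted-negative count (default 3, to rule out vacuous NPV = 1
   on a one-patient tail); confusion metrics with 95% Wald intervals
   truncated to [0, 1] and the odds ratio with a Woolf log interval
   (Haldane 0.5 on all cells, flagged, iff any cell is zero); Kaplan–Meier
   curves with events beyond a 60-month horizon converted to censorings and
   the unweighted Mantel–Haenszel log-rank test; and covariate-adjusted
   logistic regression (IRLS, tolerance 1e-8, max 100 iterations, perfect
   separation raised as an error). Candidate thresholds are midpoints
   between consecutive sorted unique scores plus ±∞; predicted responder
   means score ≥ threshold, ties predicted responder; cutoff ties are broken
   by higher sensitivity, then lower threshold. Survival stratification in
   the pipeline always uses the Youden cutoff — the NPV-max rule
   deliberately leaves a small predicted-negative arm, the right trade-off
   for a clinical screen but not for a two-arm survival contrast.

## The synthetic-data generator

`sim_config()` fixes the study conditions; the generator is not a tuning
dial. Defaults: 500 genes, a 60-line panel, cohorts of 100 patients with a
58% responder rate, 40 drug-associated genes inside a 100-gene concordant
set, standardized effect 1.5, 55% FFPE-robust genes, exponential survival
with responder median 55.4 months and a non-responder hazard ratio of 1.72,
uniform 36–120-month censoring. The responder rate, FFPE fraction, survival
medians and hazard ratio mirror the advanced serous ovarian-carcinoma
setting this design targets; gene counts are scaled down from genome-wide
arrays to keep the full chain testable in seconds while preserving the
signal-to-background ratios that matter (≈ 8% informative genes, alpha-level
false candidates competing with them through every filter).

Mechanics:

* **Co-expression sharing** uses latent factors: every gene gets a
  unit-norm loading vector on `n_factors` (default 4) factors scaled by
  `factor_sd`. Concordant genes reuse the *same* loadings in the panel and
  in every cohort (fresh factor scores per data set); all other genes draw
  independent loadings per data set. Concordance is therefore a property of
  the population correlation structure, not of shared noise, and the mean
  COXEN coefficient over concordant genes rises with `factor_sd` (tested).
* **Drug association**: informative genes (drawn from the concordant set —
  the COXEN premise is that transferable response genes live in the
  conserved program) track standardized activity with slope
  `effect_size/2 · noise_sd`, calibrated so the mean difference between the
  ~30% extreme tails is about `effect_size · noise_sd`. Patient responders
  and non-responders differ by the same `effect_size · noise_sd` on
  informative∩concordant genes, in the planted direction.
* **Two drugs, one biology**: panels for different drugs under the same
  config share the concordant structure (the loadings are seeded from the
  config seed alone) but draw independent activities and informative sets;
  `merge_truths()` unions the informative sets so one cohort carries both
  drugs' response effects, letting the combination predictor see signal the
  way the two-panel/common-cohort study design intends.
* **FFPE pairing**: a planted `ffpe_robust_fraction` of genes keeps the
  frozen values plus small measurement noise (`0.25 · noise_sd`); the rest
  retain only 10% of their centered signal plus noise at the gene's own
  scale, decorrelating them from the frozen profile.
* **Determinism**: every stochastic step derives its own seed from the
  master seed and a stage tag; identical config ⇒ bit-identical output, and
  no call touches the caller's RNG state.

What the generator does **not** emulate: probe-level intensity
distributions, batch and platform effects, correlated censoring, covariates
that actually predict response (age, stage, debulking and race are drawn
null on purpose — the adjusted logistic regression should find only the
score significant), and the proprietary paired frozen/FFPE data behind real
robust-probe lists (robustness is planted, not inferred). Passing tests
therefore demonstrate the *machinery* — calibration under the null,
recovery of planted signal, transfer through concordant structure — not
clinical performance on real cohorts, which the original study could only
establish with its microarray data.

## Numerical choices and degenerate inputs

* Welch *t* with zero pooled variance: equal constant classes give
  statistic 0, p 1; unequal constants give ±∞ (p ≈ 0). DLDA drops
  zero-pooled-variance genes with a warning.
* Scoring a cohort in which every sample is identical yields equal raw
  scores; the z-score is set to 0 with a warning rather than NaN.
* Missing model genes at scoring time are dropped from the discriminant sum
  (no renormalization), erroring only below 50% coverage.
* Correlation matrices require ≥ 3 samples and ≥ 3 genes and refuse
  zero-variance genes by name.
* The permutation p-value is never below `1/(B+1)`.
* Confusion metrics with an empty margin report the affected proportion as
  `NA` instead of raising.
* `ks.test` on discrete p-value sets is used with its asymptotic form; the
  suite's calibration checks operate on 200-seed samples where ties are
  immaterial.
* Nested leave-one-out accuracy on null data sits slightly *below* 0.5
  (≈ 0.46–0.48 at 18 training lines): with one sample held out, its own
  class mean is estimated from fewer lines and is noisier, a well-known
  small-sample pessimism of leave-one-out discriminant estimates. It is a
  property of the estimator, not a leak; the calibration tests bound the
  deviation rather than pretending it is exactly 0.5.

## Problem sizes used by the test suite

Null calibration runs 200 seeded replicates of a 40-gene, 30-line panel
with 40-patient cohorts; signal recovery runs the full pipeline at the
default study conditions (500 genes, 60 lines, three cohorts of 100) over
six seeds; the cutoff rules are checked against exhaustive scans on 1000
random instances of up to 50 patients. These sizes were chosen so the whole
suite exercises every stage, including the stochastic guarantees, in well
under a minute of compute.

## Known limitations

The combination rule ignores between-drug response correlation (the
independence assumption it inherits); the permutation null conditions on
the candidate set after upstream filtering, so genes whose chance activity
association was direction-confirmed in patients can be genuinely
concordant with the true markers' neighbourhood and pass — biomarker
precision on synthetic data plateaus around 0.8–0.95 rather than 1 for
exactly this reason; and cutoffs transferred on the z scale assume the
score distribution standardizes comparably across cohorts, which a strong
cohort-specific batch effect would violate.
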