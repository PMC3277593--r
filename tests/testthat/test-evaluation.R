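# Rank-sum, ROC/AUC, cutoffs, confusion metrics, survival, logistic.

test_that("rank-sum test matches exact enumeration on small groups", {
  got <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(got$p_value, wilcoxon_enum_oracle(c(1, 2), c(3, 4)),
               tolerance = 1e-12)
  expect_equal(got$p_value, 1 / 3, tolerance = 1e-12)
  x <- c(1.2, 3.4, 0.5, 2.2); y <- c(4.1, 5.0, 2.9)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value, wilcoxon_enum_oracle(x, y),
               tolerance = 1e-12)
})

test_that("rank-sum handles degenerate and strongly shifted groups", {
  expect_equal(wilcoxon_rank_sum(rep(2, 4), rep(2, 5))$p_value, 1)
  withr::with_seed(1, { a <- rnorm(20); b <- rnorm(20) + 100 })
  expect_lt(wilcoxon_rank_sum(a, b)$p_value, 1e-4)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("AUC equals the pair-counting oracle, including ties", {
  sc <- c(0.1, 0.4, 0.35, 0.8)
  resp <- setNames(c("non_responder", "non_responder", "responder",
                     "responder"), paste0("P", 1:4))
  names(sc) <- names(resp)
  got <- roc_auc(sc, resp, n_boot = 99, seed = 1)
  expect_equal(got$auc, 0.75)
  for (s in 1:8) {
    withr::with_seed(s, {
      score <- sample(seq(0, 1, 0.1), 12, replace = TRUE)  # forces ties
      pos <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    })
    if (!any(pos) || all(pos)) next
    resp <- setNames(ifelse(pos, "responder", "non_responder"),
                     paste0("P", 1:12))
    names(score) <- names(resp)
    expect_equal(roc_auc(score, resp, n_boot = 99, seed = s)$auc,
                 auc_pair_oracle(score, pos), tolerance = 1e-12)
  }
})

test_that("AUC is 1 for separated scores and its bootstrap CI brackets it", {
  resp <- setNames(rep(c("responder", "non_responder"), each = 10),
                   paste0("P", 1:20))
  sc <- setNames(c(rnorm(10) + 10, rnorm(10)), names(resp))
  got <- roc_auc(sc, resp, n_boot = 200, seed = 2)
  expect_equal(got$auc, 1)
  withr::with_seed(3, sc2 <- setNames(rnorm(20), names(resp)))
  null_auc <- roc_auc(sc2, resp, n_boot = 200, seed = 3)
  expect_true(null_auc$ci_low <= null_auc$auc && null_auc$auc <= null_auc$ci_high)
  expect_error(roc_auc(sc[1:10], resp[1:10], n_boot = 99, seed = 1),
               "both classes")
})

test_that("cross-check: AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(4, {
    sc <- rnorm(40)
    pos <- rbinom(40, 1, plogis(sc))
  })
  if (length(unique(pos)) < 2) skip("degenerate draw")
  resp <- setNames(ifelse(pos == 1, "responder", "non_responder"),
                   paste0("P", 1:40))
  names(sc) <- names(resp)
  ref <- as.numeric(pROC::auc(pROC::roc(pos, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(sc, resp, n_boot = 99, seed = 1)$auc, ref,
               tolerance = 1e-12)
})

test_that("Youden cutoff separates a clean instance at the midpoint", {
  sc <- setNames(c(0.1, 0.2, 0.8, 0.9), paste0("P", 1:4))
  resp <- setNames(c("non_responder", "non_responder", "responder",
                     "responder"), names(sc))
  ct <- youden_cutoff(sc, resp)
  expect_equal(ct$threshold, 0.5)
  expect_equal(ct$youden_j, 1)
  # anti-predictive scores: J still >= 0 thanks to degenerate thresholds
  ct2 <- youden_cutoff(setNames(rev(sc), names(sc)), resp)
  expect_gte(ct2$youden_j, 0)
})

test_that("both cutoff rules match exhaustive scans on random instances", {
  for (s in 1:60) {
    withr::with_seed(s, {
      n <- sample(8:50, 1)
      score <- round(rnorm(n), 2)
      pos <- rbinom(n, 1, 0.5) == 1
    })
    if (!any(pos) || all(pos)) next
    resp <- setNames(ifelse(pos, "responder", "non_responder"),
                     paste0("P", seq_along(score)))
    names(score) <- names(resp)
    got_y <- youden_cutoff(score, resp)
    want_y <- cutoff_scan_oracle(score, pos, "youden")
    expect_equal(got_y$threshold, want_y$thr)
    expect_equal(got_y$youden_j, want_y$obj, tolerance = 1e-12)
    got_n <- npv_max_cutoff(score, resp, min_predicted_negatives = 3)
    want_n <- cutoff_scan_oracle(score, pos, "npv", min_neg = 3)
    expect_equal(got_n$threshold, want_n$thr)
    expect_equal(got_n$npv, want_n$obj, tolerance = 1e-12)
  }
})

test_that("NPV rule honours its constraint and degenerates loudly", {
  sc <- setNames(c(0.1, 0.2, 0.8, 0.9), paste0("P", 1:4))
  resp <- setNames(c("non_responder", "non_responder", "responder",
                     "responder"), names(sc))
  ct <- npv_max_cutoff(sc, resp, min_predicted_negatives = 2)
  expect_equal(ct$npv, 1)
  expect_equal(ct$threshold, 0.5)
  flat <- setNames(rep(1, 4), names(resp))
  expect_error(npv_max_cutoff(flat, resp, min_predicted_negatives = 5),
               "predicted non-responders")
})

test_that("confusion metrics reproduce published proportions and intervals", {
  # carboplatin, FFPE validation cohort: 29/32 sensitive detected, NPV 4/7
  m <- confusion_from_counts(tp = 29, fn = 3, fp = 19, tn = 4)
  expect_equal(round(m$sensitivity, 3), 0.906)
  expect_equal(round(m$sensitivity_ci, 3), c(0.805, 1))
  expect_equal(round(m$npv, 3), 0.571)
  expect_equal(round(m$npv_ci, 3), c(0.205, 0.938))
  expect_equal(round(m$specificity, 3), 0.174)
  expect_equal(round(m$specificity_ci, 3), c(0.019, 0.329))
  # carboplatin, frozen tuning cohort
  m2 <- confusion_from_counts(tp = 80, fn = 5, fp = 24, tn = 10)
  expect_equal(round(m2$sensitivity, 3), 0.941)
  expect_equal(round(m2$sensitivity_ci, 3), c(0.891, 0.991))
  expect_equal(round(m2$ppv, 3), 0.769)
  expect_equal(round(m2$ppv_ci, 3), c(0.688, 0.850))
  expect_equal(round(m2$npv, 3), 0.667)
  expect_equal(round(m2$npv_ci, 3), c(0.428, 0.905))
  # symmetric table
  m3 <- confusion_from_counts(10, 10, 10, 10)
  expect_equal(c(m3$sensitivity, m3$specificity, m3$ppv, m3$npv),
               rep(0.5, 4))
  expect_equal(m3$odds_ratio, 1)
})

test_that("the combination odds ratio and Woolf interval reproduce", {
  m <- confusion_from_counts(tp = 83, fn = 2, fp = 29, tn = 5)
  expect_equal(round(m$odds_ratio, 2), 7.16)
  expect_equal(m$or_ci_low, 1.315, tolerance = 2e-3)
  expect_equal(m$or_ci_high, 38.912, tolerance = 2e-3)
  expect_false(m$haldane)
})

test_that("zero cells trigger the flagged Haldane correction, empty margins NA", {
  m <- confusion_from_counts(tp = 5, fn = 0, fp = 3, tn = 2)
  expect_true(m$haldane)
  expect_equal(m$odds_ratio, (5.5 * 2.5) / (3.5 * 0.5))
  m2 <- confusion_from_counts(tp = 5, fn = 5, fp = 0, tn = 0)
  expect_true(is.na(m2$specificity))     # empty true-negative margin
  expect_equal(m2$npv, 0)
  expect_equal(m2$sensitivity, 0.5)
})

test_that("score dichotomization feeds the counts correctly", {
  sc <- setNames(c(-1, -0.5, 0.2, 0.4, 1, 2), paste0("P", 1:6))
  resp <- setNames(c("non_responder", "non_responder", "responder",
                     "non_responder", "responder", "responder"), names(sc))
  m <- confusion_metrics(sc, resp, cutoff = 0.2)   # ties predicted responder
  expect_equal(c(m$tp, m$fn, m$fp, m$tn), c(3, 0, 1, 2))
})

test_that("KM median and log-rank match first principles", {
  cl <- data.frame(sample_id = paste0("P", 1:5),
                   os_months = 1:5,
                   event = rep("death", 5), stringsAsFactors = FALSE)
  grp <- setNames(c("a", "a", "a", "b", "b"), cl$sample_id)
  # survfit needs an event in each group; median of the pooled empirical
  # survival function of group a tested below via curves
  res <- km_logrank(cl, grp, censor_horizon_months = 60)
  ca <- res$curves[res$curves$group == "a", ]
  expect_equal(ca$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(unname(res$medians["a"]), 2)

  withr::with_seed(5, {
    time <- c(2, 4, 5, 7, 9, 12)
    status <- c(1, 1, 0, 1, 1, 1)
    group <- c("x", "y", "x", "y", "x", "y")
  })
  cl2 <- data.frame(sample_id = paste0("Q", 1:6), os_months = time,
                    event = ifelse(status == 1, "death", "censored"),
                    stringsAsFactors = FALSE)
  res2 <- km_logrank(cl2, setNames(group, cl2$sample_id), 60)
  want <- logrank_oracle(time, status, group)
  expect_equal(res2$chisq, want$chisq, tolerance = 1e-8)
  expect_equal(res2$p_value, want$p, tolerance = 1e-8)
})

test_that("events beyond the horizon are censored at the horizon", {
  cl <- data.frame(sample_id = paste0("P", 1:8),
                   os_months = c(10, 20, 30, 90, 15, 25, 70, 80),
                   event = "death", stringsAsFactors = FALSE)
  grp <- setNames(rep(c("a", "b"), each = 4), cl$sample_id)
  res <- km_logrank(cl, grp, censor_horizon_months = 60)
  expect_true(all(res$curves$time <= 60))
  # group b keeps only 2 events (70 and 80 censored at 60)
  expect_equal(sum(res$curves$n_event[res$curves$group == "b"]), 2)
  expect_error(km_logrank(cl, setNames(rep("a", 8), cl$sample_id), 60),
               "two groups")
})

test_that("KM with no censoring equals the empirical survival function", {
  withr::with_seed(6, tms <- sort(round(rexp(12, 0.05), 1)))
  cl <- data.frame(sample_id = paste0("P", 1:24),
                   os_months = c(tms, sort(round(rexp(12, 0.02), 1))),
                   event = "death", stringsAsFactors = FALSE)
  grp <- setNames(rep(c("a", "b"), each = 12), cl$sample_id)
  res <- km_logrank(cl, grp, censor_horizon_months = Inf)
  ca <- res$curves[res$curves$group == "a", ]
  emp <- vapply(ca$time, function(t) mean(tms > t), numeric(1))
  expect_equal(ca$survival, emp, tolerance = 1e-12)
})

test_that("logistic slope recovers the closed-form 2x2 log odds ratio", {
  df_resp <- rep(c(1, 1, 0, 0), c(10, 5, 5, 10))
  x <- rep(c(1, 0, 1, 0), c(10, 5, 5, 10))
  resp <- setNames(ifelse(df_resp == 1, "responder", "non_responder"),
                   paste0("P", seq_along(x)))
  sc <- setNames(as.numeric(x), names(resp))
  fit <- logistic_adjusted(resp, sc)
  expect_equal(fit$estimate[fit$term == "score"], log(4), tolerance = 1e-6)
})

test_that("a strong planted score dominates null covariates", {
  withr::with_seed(7, {
    n <- 200
    z <- rnorm(n)
    pr <- plogis(2 * z)
    y <- rbinom(n, 1, pr)
    covs <- data.frame(sample_id = paste0("P", 1:n),
                       age = rnorm(n, 62, 7),
                       stage = sample(c("III", "IV"), n, TRUE))
  })
  resp <- setNames(ifelse(y == 1, "responder", "non_responder"),
                   covs$sample_id)
  sc <- setNames(z, covs$sample_id)
  fit <- logistic_adjusted(resp, sc, covs)
  expect_lt(fit$p_value[fit$term == "score"], 1e-6)
  expect_gt(min(fit$p_value[grepl("age|stage", fit$term)]), 0.01)
})

test_that("perfect separation is reported as an error", {
  resp <- setNames(rep(c("responder", "non_responder"), each = 10),
                   paste0("P", 1:20))
  sc <- setNames(c(rnorm(10) + 50, rnorm(10) - 50), names(resp))
  expect_error(suppressWarnings(logistic_adjusted(resp, sc)), "separation")
})
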