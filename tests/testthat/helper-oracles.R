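# Independent oracles and small fixture builders used across the suite.
# Every oracle recomputes its quantity from first principles, without calling
# the implementation path it checks.

# genes x samples matrix of N(0,1) noise with IDs.
rand_expr <- function(n_genes, n_samples, seed, prefix = "S") {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("%s%03d", prefix, seq_len(n_samples))))
    m
  })
}

# Pearson correlation from the explicit sum formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Brute-force per-gene correlation-of-correlations on two matrices.
coxen_oracle <- function(exprA, exprB, ids) {
  cA <- stats::cor(t(exprA[ids, ])); cB <- stats::cor(t(exprB[ids, ]))
  vapply(seq_along(ids), function(g)
    pearson_oracle(cA[g, -g], cB[g, -g]), numeric(1))
}

# Gaussian log likelihood-ratio with diagonal covariance and priors.
gaussian_lr_oracle <- function(x, mu_s, mu_r, v, priors = c(0.5, 0.5)) {
  ls <- sum(stats::dnorm(x, mu_s, sqrt(v), log = TRUE)) + log(priors[1])
  lr <- sum(stats::dnorm(x, mu_r, sqrt(v), log = TRUE)) + log(priors[2])
  ls - lr
}

# AUC as the probability of concordance: count pairs directly.
auc_pair_oracle <- function(score, is_pos) {
  pos <- score[is_pos]; neg <- score[!is_pos]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exhaustive cutoff scan sharing the documented rule: candidate thresholds
# are +/-Inf plus midpoints of consecutive sorted unique scores; predicted
# responder <=> score >= threshold; ties broken by higher sensitivity then
# lower threshold.
cutoff_scan_oracle <- function(score, is_pos, objective = c("youden", "npv"),
                               min_neg = 0) {
  objective <- match.arg(objective)
  u <- sort(unique(score))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (t in thr) {
    pred <- score >= t
    tp <- sum(pred & is_pos); fn <- sum(!pred & is_pos)
    fp <- sum(pred & !is_pos); tn <- sum(!pred & !is_pos)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    if (objective == "youden") {
      obj <- sens + spec - 1
    } else {
      if (tn + fn < min_neg) next
      obj <- tn / (tn + fn)
    }
    if (is.null(best) || obj > best$obj + 1e-12 ||
        (abs(obj - best$obj) <= 1e-12 && sens > best$sens + 1e-12))
      best <- list(thr = t, obj = obj, sens = sens)
  }
  best
}

# Unweighted two-group log-rank statistic from the observed-minus-expected
# table, looping over distinct event times.
logrank_oracle <- function(time, status, group) {
  g1 <- levels(factor(group))[1]
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[status == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(status == 1 & time == t)
    d1 <- sum(status == 1 & time == t & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Exact two-sided rank-sum p by enumerating all group assignments.
wilcoxon_enum_oracle <- function(x, y) {
  pooled <- c(x, y); n <- length(pooled); n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  sums <- apply(utils::combn(n, n1), 2, function(i) sum(r[i]))
  mu <- n1 * (n + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# A small labeled panel with planted signal, for predictor tests.
signal_panel <- function(n_genes = 30, n_per_class = 10, effect = 2,
                         n_signal = 5, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    X <- matrix(rnorm(n_genes * n), n_genes, n,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("CL%03d", seq_len(n))))
    lab <- rep(c("sensitive", "resistant"), each = n_per_class)
    X[seq_len(n_signal), lab == "sensitive"] <-
      X[seq_len(n_signal), lab == "sensitive"] + effect
    list(expr = X, labels = data.frame(sample_id = colnames(X), label = lab,
                                       stringsAsFactors = FALSE))
  })
}
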