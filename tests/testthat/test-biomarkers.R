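# Extreme-line labeling, candidate ranking, and the two filters.

test_that("extreme-line selection is an order statistic with exclusions", {
  act <- setNames(1:10, paste0("c", 1:10))
  lab <- select_extreme_lines(act, tail_fraction = 0.3)
  expect_setequal(lab$sample_id[lab$label == "sensitive"], c("c8", "c9", "c10"))
  expect_setequal(lab$sample_id[lab$label == "resistant"], c("c1", "c2", "c3"))
  expect_equal(nrow(lab), 6)
})

test_that("asymmetric per-tail fractions reproduce published class sizes", {
  act <- setNames(withr::with_seed(1, rnorm(60)), paste0("c", 1:60))
  lab <- select_extreme_lines(act, upper_fraction = 10 / 60,
                              lower_fraction = 22 / 60)
  expect_equal(sum(lab$label == "sensitive"), 10)
  expect_equal(sum(lab$label == "resistant"), 22)
})

test_that("boundary ties are all included in the tail", {
  act <- setNames(c(1, 2, 3, 3, 3, 5, 6, 7, 8, 9), paste0("c", 1:10))
  lab <- select_extreme_lines(act, tail_fraction = 0.3)
  # nominal resistant tail is 3 but the tied value 3 spans ranks 3-5
  expect_gte(sum(lab$label == "resistant"), 3)
  expect_setequal(lab$sample_id[lab$label == "resistant"],
                  c("c1", "c2", "c3", "c4", "c5"))
})

test_that("labeling is invariant to monotone transforms of activity", {
  act <- setNames(withr::with_seed(2, rnorm(30)), paste0("c", 1:30))
  a <- select_extreme_lines(act, 0.3)
  b <- select_extreme_lines(exp(act), 0.3)
  expect_identical(a[order(a$sample_id), ], b[order(b$sample_id), ])
})

test_that("overlapping tails and out-of-range fractions error", {
  act <- setNames(1:6, paste0("c", 1:6))
  expect_error(select_extreme_lines(setNames(1:7, paste0("c", 1:7)), 0.35,
                                    upper_fraction = 0.45,
                                    lower_fraction = 0.45), "overlap")
  expect_error(select_extreme_lines(act, 0.5), "0.35")
})

test_that("gene ranking matches per-gene Welch t computation", {
  pan <- signal_panel(n_genes = 25, n_per_class = 8, effect = 1.5, seed = 4)
  tab <- rank_chemosensitivity_genes(pan$expr, pan$labels, alpha = 1,
                                     max_genes = Inf)
  expect_equal(nrow(tab), 25)            # alpha = 1 keeps every gene
  for (g in c("g001", "g010", "g020")) {
    tt <- t.test(pan$expr[g, pan$labels$label == "sensitive"],
                 pan$expr[g, pan$labels$label == "resistant"])
    row <- tab[tab$gene_id == g, ]
    expect_equal(row$statistic, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-12)
  }
  expect_equal(tab$direction, sign(tab$statistic))
  expect_false(is.unsorted(rev(abs(tab$statistic))))
})

test_that("a strongly planted gene ranks first and constants are excluded", {
  pan <- signal_panel(n_genes = 2, n_per_class = 10, effect = 0, n_signal = 0,
                      seed = 5)
  pan$expr["g001", pan$labels$label == "sensitive"] <-
    pan$expr["g001", pan$labels$label == "sensitive"] + 2
  tab <- rank_chemosensitivity_genes(pan$expr, pan$labels, alpha = 1,
                                     max_genes = Inf)
  expect_equal(tab$gene_id[1], "g001")

  pan$expr["g002", ] <- 1                # identical in both classes
  tab2 <- rank_chemosensitivity_genes(pan$expr, pan$labels, alpha = 0.99,
                                      max_genes = Inf)
  expect_false("g002" %in% tab2$gene_id)
})

test_that("ranking requires two samples per class", {
  pan <- signal_panel(n_per_class = 5, seed = 6)
  lab <- pan$labels[c(1, 6, 7, 8), ]     # one sensitive line only
  expect_error(rank_chemosensitivity_genes(pan$expr, lab), ">= 2")
})

test_that("FFPE filter intersects, preserves order and records provenance", {
  pan <- signal_panel(n_genes = 20, seed = 7)
  tab <- rank_chemosensitivity_genes(pan$expr, pan$labels, alpha = 1,
                                     max_genes = Inf)
  expect_identical(filter_ffpe_robust(tab, tab$gene_id)$gene_id, tab$gene_id)
  robust <- tab$gene_id[c(2, 5, 9)]
  out <- filter_ffpe_robust(tab, robust)
  expect_identical(out$gene_id, tab$gene_id[tab$gene_id %in% robust])
  p <- provenance(out)
  expect_equal(p$n_after[p$filter == "ffpe_robust"], 3)
  expect_true(all(diff(c(p$n_before[1], p$n_after)) <= 0))
  expect_error(filter_ffpe_robust(tab, "nope"), "intersection")
})

test_that("direction filter keeps agreeing genes and drops the rest", {
  pan <- signal_panel(n_genes = 6, n_per_class = 10, effect = 3, n_signal = 2,
                      seed = 8)
  tab <- rank_chemosensitivity_genes(pan$expr, pan$labels, alpha = 1,
                                     max_genes = Inf)
  # patients: g001 replicates the up-in-sensitive direction, g002 reversed
  pexpr <- rand_expr(6, 40, seed = 9, prefix = "P")
  resp <- rep(c("responder", "non_responder"), each = 20)
  names(resp) <- colnames(pexpr)
  pexpr["g001", resp == "responder"] <- pexpr["g001", resp == "responder"] + 3
  pexpr["g002", resp == "responder"] <- pexpr["g002", resp == "responder"] - 3
  out <- filter_direction_consistent(tab, pexpr, resp)
  expect_true("g001" %in% out$gene_id)
  expect_false("g002" %in% out$gene_id)
})

test_that("under a null cohort about half of candidates survive direction", {
  surv <- vapply(1:30, function(s) {
    pan <- signal_panel(n_genes = 40, n_per_class = 10, effect = 2,
                        n_signal = 0, seed = s)
    tab <- rank_chemosensitivity_genes(pan$expr, pan$labels, alpha = 1,
                                       max_genes = Inf)
    pexpr <- rand_expr(40, 30, seed = s + 1000, prefix = "P")
    resp <- setNames(rep(c("responder", "non_responder"), c(15, 15)),
                     colnames(pexpr))
    nrow(filter_direction_consistent(tab, pexpr, resp)) / nrow(tab)
  }, numeric(1))
  expect_gt(mean(surv), 0.42)
  expect_lt(mean(surv), 0.58)
})

test_that("genes absent from the patient matrix are dropped with a warning", {
  pan <- signal_panel(n_genes = 10, seed = 11)
  tab <- rank_chemosensitivity_genes(pan$expr, pan$labels, alpha = 1,
                                     max_genes = Inf)
  pexpr <- rand_expr(8, 20, seed = 12, prefix = "P")  # g009, g010 missing
  resp <- setNames(rep(c("responder", "non_responder"), each = 10),
                   colnames(pexpr))
  expect_warning(out <- filter_direction_consistent(tab, pexpr, resp),
                 "absent")
  expect_false(any(c("g009", "g010") %in% out$gene_id))
})
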