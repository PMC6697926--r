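test_that("LUMP score matches its closed forms", {
  m <- toy_beta(rep(0.85, 6), 3, 2, probe_ids = c("L1", "L2", "L3"))
  s <- lump_score(m, c("L1", "L2", "L3"))
  expect_equal(s$purity, c(1, 1))

  m0 <- toy_beta(rep(0, 6), 3, 2, probe_ids = c("L1", "L2", "L3"))
  expect_equal(lump_score(m0, c("L1", "L2", "L3"))$purity, c(0, 0))

  m3 <- toy_beta(rep(c(0.2, 0.4, 0.6), 2), 3, 2,
                 probe_ids = c("L1", "L2", "L3"))
  expect_equal(lump_score(m3, c("L1", "L2", "L3"))$purity,
               rep(0.4 / 0.85, 2))

  # doubling the scale halves uncapped scores
  expect_equal(lump_score(m3, c("L1", "L2", "L3"), scale = 1.7,
                          cap = FALSE)$purity,
               lump_score(m3, c("L1", "L2", "L3"), scale = 0.85,
                          cap = FALSE)$purity / 2)
})

test_that("LUMP score uses only present panel probes and is monotone in betas", {
  m <- toy_beta(c(0.2, 0.6, 0.3, 0.7), 2, 2, probe_ids = c("L1", "L2"))
  s <- lump_score(m, c("L1", "L2", "ABSENT"))
  expect_equal(s$n_panel_probes, c(2L, 2L))
  expect_equal(attr(s, "panel_used"), c("L1", "L2"))
  expect_error(lump_score(m, "ABSENT"), "no panel probe")
  expect_error(lump_score(m, character(0)), "empty")

  m_up <- m; m_up[1, 1] <- m[1, 1] + 0.1
  expect_gte(lump_score(m_up, c("L1", "L2"))$purity[1],
             lump_score(m, c("L1", "L2"))$purity[1])
})

test_that("evaluation metrics match identity, anti-correlation and hand arithmetic", {
  a <- toy_purity(c(0.1, 0.4, 0.8), source = "RF_PREDICTED")
  ev <- evaluate_predictions(a, a)
  expect_equal(ev$pearson_r, 1)
  expect_equal(ev$mse, 0)
  expect_equal(ev$median_abs_diff, 0)

  b <- a; b$purity <- 1 - a$purity; b$source <- "ESTIMATE"
  expect_equal(evaluate_predictions(a, b)$pearson_r, -1)

  x <- c(0.10, 0.30, 0.50, 0.70, 0.90)
  y <- c(0.15, 0.25, 0.60, 0.65, 0.95)
  ev2 <- evaluate_predictions(
    toy_purity(x, source = "RF_PREDICTED"),
    toy_purity(y, source = "ABSOLUTE"))
  expect_equal(ev2$pearson_r, cor(x, y), tolerance = 1e-12)
  expect_equal(ev2$mse, mean((x - y)^2), tolerance = 1e-12)
  expect_equal(ev2$median_abs_diff, median(abs(x - y)), tolerance = 1e-12)
  expect_equal(ev2$n, 5L)
})

test_that("evaluation works on the intersection, is symmetric, and flags zero variance", {
  a <- toy_purity(c(0.1, 0.4, 0.8, 0.3), sample_ids = c("s1", "s2", "s3", "s4"),
                  source = "RF_PREDICTED")
  b <- toy_purity(c(0.2, 0.5, 0.9, 0.6), sample_ids = c("s2", "s3", "s4", "s9"),
                  source = "ABSOLUTE")
  ev <- evaluate_predictions(a, b)
  expect_equal(ev$n, 3L)
  ev_swapped <- evaluate_predictions(b, a)
  expect_equal(ev_swapped$pearson_r, ev$pearson_r)
  expect_equal(ev_swapped$mse, ev$mse)
  expect_equal(ev_swapped$median_abs_diff, ev$median_abs_diff)

  expect_error(evaluate_predictions(a, toy_purity(0.5, sample_ids = "s1")),
               "at least 3")
  const <- toy_purity(rep(0.5, 4), sample_ids = a$sample_id)
  evc <- evaluate_predictions(a, const)
  expect_true(evc$r_undefined)
  expect_true(is.na(evc$pearson_r))
  expect_false(is.na(evc$mse))
})

test_that("pairwise correlations form a symmetric unit-diagonal matrix with flagged gaps", {
  a <- toy_purity(runif(10), source = "SYNTHETIC_TRUTH")
  b <- a; b$purity <- pmin(1, a$purity + 0.05); b$source <- "ESTIMATE"
  m <- pairwise_correlations(list(a, b))
  expect_equal(diag(m), c(SYNTHETIC_TRUTH = 1, ESTIMATE = 1))
  expect_equal(m[1, 2], m[2, 1])
  expect_equal(m[1, 2], cor(a$purity, b$purity))

  ident <- pairwise_correlations(list(x = a, y = a))
  expect_true(all(ident == 1))

  disjoint <- toy_purity(runif(5), sample_ids = sprintf("Q%02d", 1:5),
                         source = "LUMP")
  m2 <- pairwise_correlations(list(a = a, b = b, c = disjoint))
  expect_true(is.na(m2["a", "c"]) && is.na(m2["b", "c"]))
  expect_false(is.na(m2["a", "b"]))
})

test_that("grouped quantiles interpolate order statistics per group", {
  p <- toy_purity(seq(0.1, 1.0, by = 0.1), group = rep("g1", 10))
  q <- purity_quantiles_by_group(p, probs = 0.5)
  expect_equal(q$purity, 0.55)

  # two identical groups give identical rows
  p2 <- toy_purity(rep(seq(0.1, 1.0, by = 0.1), 2),
                   group = rep(c("g1", "g2"), each = 10),
                   sample_ids = sprintf("W%02d", 1:20))
  q2 <- purity_quantiles_by_group(p2)
  expect_equal(q2$purity[q2$group == "g1"], q2$purity[q2$group == "g2"])
  # rows are non-decreasing in the probabilities
  for (g in unique(q2$group)) {
    expect_false(is.unsorted(q2$purity[q2$group == g]))
  }

  expect_error(purity_quantiles_by_group(p, probs = c(0, 0.5)), "probs")
  expect_error(purity_quantiles_by_group(toy_purity(runif(4))), "no group")

  small <- toy_purity(c(0.2, 0.4, 0.9), group = c("a", "a", "b"),
                      sample_ids = c("s1", "s2", "s3"))
  qs <- purity_quantiles_by_group(small, probs = 0.5)
  expect_true(all(qs$small_group[qs$group == "b"]))
})

test_that("absolute-difference summaries match hand arithmetic", {
  a <- toy_purity(c(0.10, 0.20, 0.50, 0.90), source = "RF_PREDICTED",
                  sample_ids = sprintf("s%d", 1:4))
  expect_equal(abs_difference_summary(a, a)$median, 0)

  b <- a; b$purity <- pmin(1, a$purity + 0.05); b$source <- "ESTIMATE"
  expect_equal(abs_difference_summary(a, b)$median, 0.05)

  c4 <- a; c4$purity <- c(0.12, 0.28, 0.47, 0.80); c4$source <- "ABSOLUTE"
  s <- abs_difference_summary(a, c4)
  expect_equal(s$median, median(c(0.02, 0.08, 0.03, 0.10)), tolerance = 1e-12)
  expect_equal(s$mean, mean(c(0.02, 0.08, 0.03, 0.10)), tolerance = 1e-12)
  expect_equal(s$n, 4)
  expect_equal(sum(s$histogram$count), 4)

  disjoint <- toy_purity(0.5, sample_ids = "zz")
  expect_error(abs_difference_summary(a, disjoint), "no shared")
})

test_that("evaluation and grouped plots build", {
  a <- toy_purity(runif(10), source = "RF_PREDICTED")
  b <- a; b$purity <- pmin(1, a$purity + 0.03); b$source <- "ABSOLUTE"
  expect_s3_class(ggplot2::autoplot(evaluate_predictions(a, b)), "ggplot")
  g <- toy_purity(runif(12), group = rep(c("x", "y"), 6))
  expect_s3_class(plot_purity_by_group(g), "ggplot")
})
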