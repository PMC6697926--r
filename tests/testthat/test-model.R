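test_that("partition respects the 70/30 split and per-stratum arithmetic", {
  p100 <- toy_purity(runif(100), sample_ids = sprintf("T%03d", 1:100))
  part <- partition_samples(p100, 0.70, seed = 3)
  expect_equal(sum(part$set == "train"), 70)
  expect_equal(sum(part$set == "test"), 30)
  expect_setequal(part$sample_id, p100$sample_id)

  two <- toy_purity(runif(100), group = rep(c("g1", "g2"), each = 50),
                    sample_ids = sprintf("T%03d", 1:100))
  part2 <- partition_samples(two, 0.70, seed = 3)
  tab <- table(part2$stratum, part2$set)
  expect_equal(unname(tab[, "train"]), c(35, 35))
  expect_equal(attr(part2, "stratify_on"), "group")
})

test_that("partition is deterministic and disjoint, and falls back on tiny strata", {
  set.seed(11)
  p <- toy_purity(runif(40), group = sample(c("a", "b"), 40, TRUE),
                  sample_ids = sprintf("U%02d", 1:40))
  a <- partition_samples(p, 0.70, seed = 7)
  b <- partition_samples(p, 0.70, seed = 7)
  expect_identical(a, b)
  expect_length(intersect(a$sample_id[a$set == "train"],
                          a$sample_id[a$set == "test"]), 0)

  singleton <- toy_purity(runif(5), group = c("a", "a", "a", "a", "b"),
                          sample_ids = sprintf("V%02d", 1:5))
  expect_warning(part <- partition_samples(singleton, 0.70, seed = 1),
                 "pooled")
  expect_true(attr(part, "pooled_fallback"))
})

test_that("initial forest recovers planted signal probes by importance", {
  # 25 planted probes carrying the purity signal among 500
  set.seed(2)
  n <- 80
  p <- runif(n, 0.1, 0.9)
  betas <- matrix(runif(500 * n), nrow = 500,
                  dimnames = list(sprintf("cg%04d", 1:500),
                                  sprintf("S%03d", 1:n)))
  planted <- sprintf("cg%04d", 1:25)
  for (i in 1:25) {
    betas[i, ] <- pmin(pmax(0.1 + 0.8 * p + rnorm(n, 0, 0.05), 0), 1)
  }
  y <- toy_purity(p, sample_ids = colnames(betas))
  r <- train_initial_forest(betas, y, n_trees = 300, seed = 4)
  expect_gte(sum(planted %in% r$probe_id[1:50]), 23)
  # fixed seed: identical ranking on rerun
  r2 <- train_initial_forest(betas, y, n_trees = 300, seed = 4)
  expect_identical(r, r2)
})

test_that("initial forest flags degenerate outcomes and bad input", {
  m <- toy_beta(runif(40), 10, 4)
  y0 <- toy_purity(rep(0.5, 4))
  expect_warning(r <- train_initial_forest(m, y0, n_trees = 20, seed = 1),
                 "zero variance")
  expect_true(attr(r, "zero_variance_outcome"))

  expect_error(train_initial_forest(m, toy_purity(0.5, sample_ids = "ZZZ"),
                                    n_trees = 20, seed = 1), "missing from")
  mna <- m; mna[1, 1] <- NA
  expect_error(train_initial_forest(mna, toy_purity(runif(4)), n_trees = 20,
                                    seed = 1), "missing values")
})

test_that("candidate probe counts reproduce the 856-probe arithmetic", {
  expect_identical(candidate_probe_counts(85600, c(0.001, 0.01, 0.05, 0.10)),
                   c(86L, 856L, 4280L, 8560L))
  expect_identical(candidate_probe_counts(7, 1.0), 7L)
  expect_error(candidate_probe_counts(100, c(0.001, 0.002)), "duplicate")
  expect_error(candidate_probe_counts(100, c(-0.1, 0.5)), "\\(0, 1\\]")
})

test_that("sweep records OOB errors and picks the minimum", {
  co <- small_cohort()
  part <- partition_samples(co$truth, 0.7, seed = 2)
  tr <- part$sample_id[part$set == "train"]
  xt <- co$betas[, tr]
  top <- select_top_fraction(rank_probes_by_dip(xt), 0.20)
  y <- co$truth[co$truth$sample_id %in% tr, ]
  imp <- train_initial_forest(xt[top, ], y, n_trees = 200, seed = 2)
  sw <- sweep_candidates(xt[top, ], y, imp, n_trees = 200, seed = 2)
  expect_equal(sw$n_probes, ceiling(c(0.001, 0.01, 0.05, 0.10) * length(top)))
  expect_equal(which(sw$chosen), which.min(sw$oob_mse))
  expect_lte(sw$oob_mse[sw$chosen], min(sw$oob_mse))

  # a single fraction degenerates to one chosen candidate
  sw1 <- sweep_candidates(xt[top, ], y, imp, fractions = 1.0,
                          n_trees = 100, seed = 2)
  expect_equal(nrow(sw1), 1)
  expect_true(sw1$chosen)
})

test_that("the trained model predicts held-out purity well", {
  co <- small_cohort()
  fit <- small_model()
  pred <- predict_purity(fit, co$betas[, fit$test_ids])
  truth <- co$truth[match(fit$test_ids, co$truth$sample_id), ]
  ev <- evaluate_predictions(pred, truth)
  expect_gte(ev$pearson_r, 0.90)
  expect_lte(ev$median_abs_diff, 0.05)
  # the chosen candidate minimizes the stored OOB record
  expect_equal(fit$candidate_record$oob_mse[fit$selected_candidate],
               min(fit$candidate_record$oob_mse))
})

test_that("screening the top 20 percent beats the top 5 percent on OOB error", {
  co <- small_cohort()
  # candidate fractions that stay distinct on a 5%-screened 2,000-probe set
  sweep <- c(0.01, 0.05, 0.10)
  f20 <- train_purity_model(co$betas, co$truth,
                            purity_config(screening_fraction = 0.20,
                                          sweep_fractions = sweep, seed = 1))
  f05 <- train_purity_model(co$betas, co$truth,
                            purity_config(screening_fraction = 0.05,
                                          sweep_fractions = sweep, seed = 1))
  expect_lte(f20$candidate_record$oob_mse[f20$selected_candidate],
             f05$candidate_record$oob_mse[f05$selected_candidate])
})

test_that("training is deterministic and free of test-set leakage", {
  cfg <- small_config(seed = 3)
  co <- simulate_cohort(cfg)
  pcfg <- purity_config(seed = 3)
  f1 <- train_purity_model(co$betas, co$truth, pcfg)
  f2 <- train_purity_model(co$betas, co$truth, pcfg)
  expect_identical(f1$final_probes, f2$final_probes)
  expect_identical(predict_purity(f1, co$betas[, 1:8]),
                   predict_purity(f2, co$betas[, 1:8]))

  # dropping the held-out samples from the input changes nothing when the
  # same train/test assignment is kept
  keep <- f1$train_ids
  f3 <- train_purity_model(co$betas[, keep],
                           co$truth[co$truth$sample_id %in% keep, ], pcfg,
                           partition = f1$partition)
  expect_identical(f3$screening$n_selected, f1$screening$n_selected)
  expect_identical(f3$final_probes, f1$final_probes)
  expect_identical(f3$importance, f1$importance)
})

test_that("training rejects unusable label input", {
  co <- small_cohort()
  empty <- co$truth[0, ]
  expect_error(train_purity_model(co$betas, empty), "empty|at least 4")
  disjoint <- toy_purity(runif(10), sample_ids = sprintf("XX%02d", 1:10))
  expect_error(train_purity_model(co$betas, disjoint), "at least 4")
})

test_that("predictions stay in range, match fitted values, and order the pure limits", {
  co <- small_cohort()
  fit <- small_model()
  pred <- predict_purity(fit, co$betas)
  expect_true(all(pred$purity >= 0 & pred$purity <= 1))
  expect_identical(pred$source, rep("RF_PREDICTED", nrow(pred)))
  expect_equal(pred$imputed_fraction, rep(0, nrow(pred)))

  # an exact copy of a training sample reproduces its fitted value
  s <- fit$train_ids[1]
  copy <- co$betas[, s, drop = FALSE]
  colnames(copy) <- "copy01"
  expect_equal(predict_purity(fit, copy)$purity,
               pred$purity[pred$sample_id == s])

  # noise-free pure tumor vs pure stroma from the generator's references
  prof <- co$profiles
  pure <- cbind(tumor1 = prof$tumor[, 1], stroma0 = prof$stroma)
  pp <- predict_purity(fit, pure)
  expect_gt(pp$purity[pp$sample_id == "tumor1"],
            pp$purity[pp$sample_id == "stroma0"])
})

test_that("prediction imputes absent model probes and reports the fraction", {
  co <- small_cohort()
  fit <- small_model()
  drop_n <- ceiling(length(fit$final_probes) / 3)
  keep <- setdiff(rownames(co$betas), fit$final_probes[seq_len(drop_n)])
  pred <- predict_purity(fit, co$betas[keep, 1:5])
  expect_equal(pred$imputed_fraction,
               rep(drop_n / length(fit$final_probes), 5))
  expect_true(all(pred$purity >= 0 & pred$purity <= 1))

  none <- co$betas[setdiff(rownames(co$betas), fit$final_probes), 1:5]
  expect_error(predict_purity(fit, none), "none of the model's")
})

test_that("tidy, glance and autoplot expose the fitted model", {
  fit <- small_model()
  td <- generics::tidy(fit)
  expect_true(all(c("probe_id", "importance", "rank", "in_final_model")
                  %in% names(td)))
  expect_equal(sum(td$in_final_model), length(fit$final_probes))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_probes_final, length(fit$final_probes))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
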