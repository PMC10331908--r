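rfc <- rf_config(n_trees = 150, seed = 42)

test_that("a perfectly learnable signal yields near-perfect OOB accuracy", {
  set.seed(1)
  pred <- noise_predictors(500, p = 3, seed = 1)
  y <- factor(ifelse(pred$x1 > 0, "hi", "lo"))
  rep <- oob_report(fit_forest(pred, y, rfc))
  expect_gt(rep$overall_accuracy, 95)
})

test_that("labels independent of predictors score at the permutation baseline", {
  set.seed(2)
  pred <- noise_predictors(500, p = 4, seed = 2)
  y <- factor(rep(c("a", "b"), each = 250))
  rep <- oob_report(fit_forest(pred, y, rfc))
  expect_lt(abs(rep$overall_accuracy - 50), 5)
})

test_that("species never out of bag are excluded from accuracy with a warning", {
  pred <- noise_predictors(10, p = 2, seed = 3)
  y <- factor(rep(c("a", "b"), 5))
  suppressWarnings(fit <- fit_forest(pred, y, rf_config(n_trees = 1, seed = 1)))
  expect_warning(rep <- oob_report(fit), "out-of-bag")
  expect_equal(rep$n_total + rep$n_excluded, 10)
})

test_that("report arithmetic matches hand counts and the trace identity", {
  fake <- structure(list(forest = NULL,
                         oob = factor(c("a", "b", "b", "b"), c("a", "b")),
                         observed = factor(c("a", "a", "b", "b"), c("a", "b")),
                         species_id = paste0("s", 1:4),
                         config = rf_config(n_trees = 10), encoding = "factor",
                         n_dropped = 0L),
                    class = "beaknest_forest")
  rep <- oob_report(fake)
  expect_equal(rep$overall_accuracy, 75)
  expect_equal(unname(rep$confusion["a", ]), c(1, 1))
  expect_equal(unname(rep$confusion["b", ]), c(0, 2))
  expect_equal(unname(rowSums(rep$confusion)), unname(as.integer(rep$n)))
  expect_equal(sum(diag(rep$confusion)) / sum(rep$confusion),
               rep$overall_accuracy / 100)
  expect_equal(unname(rowSums(rep$confusion_prop)), c(1, 1))
})

test_that("single-class labels error and fixed seeds reproduce bit-identically", {
  pred <- noise_predictors(40, p = 2, seed = 4)
  expect_error(fit_forest(pred, factor(rep("a", 40)), rfc), "single class")
  y <- factor(rep(c("a", "b"), 20))
  r1 <- oob_report(fit_forest(pred, y, rfc))
  r2 <- oob_report(fit_forest(pred, y, rfc))
  expect_identical(r1$confusion, r2$confusion)
})

test_that("the three model families run on synthetic data with sane contracts", {
  cfg <- synth_config(n_species = 250, n_trees = 1, seed = 70)
  ds <- generate_dataset(cfg)
  small <- rf_config(n_trees = 100, seed = 5)

  bins <- run_binary_models(ds$profiles, ds$predictors, small)
  expect_equal(sort(names(bins)), material_categories())
  for (rep in bins) {
    expect_equal(sum(diag(rep$confusion)) / sum(rep$confusion),
                 rep$overall_accuracy / 100)
  }

  # a category everyone uses is skipped with a warning
  prof_all <- ds$profiles
  prof_all$used_grass <- 1L
  expect_warning(b2 <- run_binary_models(prof_all, ds$predictors, small),
                 "grass")
  expect_false("grass" %in% names(b2))

  prim <- run_primary_model(ds$profiles, ds$predictors, small)
  expect_equal(prim$n_total, 250)
  spec <- run_specialist_model(ds$profiles, ds$predictors, small)
  expect_equal(spec$n_total, sum(ds$profiles$specialist))
  expect_true(all(names(spec$n) %in% material_categories()))
})

test_that("toggling the mixed class changes membership, not other rows", {
  cfg <- synth_config(n_species = 150, n_trees = 1, seed = 71)
  ds <- generate_dataset(cfg)
  # inject some mixed species by hand
  ds$profiles$primary[1:20] <- "mixed"
  small <- rf_config(n_trees = 100, seed = 5)
  with_mixed <- run_primary_model(ds$profiles, ds$predictors, small, include_mixed = TRUE)
  without <- run_primary_model(ds$profiles, ds$predictors, small, include_mixed = FALSE)
  expect_equal(with_mixed$n_total - without$n_total, 20)
  expect_true("mixed" %in% rownames(with_mixed$confusion))
  expect_false("mixed" %in% rownames(without$confusion))
})

test_that("contribution decomposition isolates the informative predictor", {
  set.seed(6)
  n <- 300
  pred <- data.frame(species_id = sprintf("sp%04d", 1:n),
                     signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  pred$dup <- pred$signal  # exact copy: redundancy probe
  y <- factor(ifelse(pred$signal > 0, "u", "v"))
  prof <- data.frame(species_id = pred$species_id, primary = y,
                     specialist = FALSE, omit = FALSE)
  small <- rf_config(n_trees = 100, seed = 9)
  tab <- contribution_analysis(prof, pred, small, model_family = "primary")
  full <- attr(tab, "full_accuracy")
  base <- attr(tab, "baseline_accuracy")
  get <- function(p, col) tab[tab$predictor == p, col]

  # the sole informative predictor carries the model on its own
  expect_gt(get("signal", "independent"), full - 5)
  # pure-noise predictors: independent near chance, marginal near zero
  for (p in c("noise1", "noise2")) {
    expect_lt(abs(get(p, "independent") - base), 8)
    expect_lt(abs(get(p, "marginal")), 5)
  }
  # duplicated column: each copy individually sufficient, individually removable
  expect_gt(get("dup", "independent"), full - 5)
  expect_lt(abs(get("dup", "marginal")), 5)
  expect_lt(abs(get("signal", "marginal")), 5)
})
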