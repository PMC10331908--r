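test_that("standardization is exact, idempotent and invertible", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize(m)
  expect_equal(unname(colMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 2, stats::sd)), c(1, 1))
  z2 <- standardize(z)
  expect_equal(as.matrix(z2), as.matrix(z), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(unstandardize(z)), unname(m), tolerance = 1e-12)
  m2 <- cbind(ok = c(1, 2, 3), flat = c(4, 4, 4))
  expect_error(standardize(m2), "flat")
})

test_that("beak PCA matches an independent eigendecomposition up to sign", {
  set.seed(31)
  m <- matrix(rnorm(500), 100, 5,
              dimnames = list(NULL, c("L", "Ln", "W", "D", "M")))
  pca <- beak_pca(m, scale. = TRUE)
  # oracle: eigen of the correlation matrix
  eg <- eigen(stats::cor(m))
  expect_equal(pca$var_explained, eg$values, tolerance = 1e-8)
  sc <- scale(m) %*% eg$vectors
  for (j in 1:5) {
    expect_equal(abs(pca$loadings[, j]), abs(eg$vectors[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(abs(pca$scores[, j]), abs(sc[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # deterministic sign convention: dominant loading positive
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  }
  # scores are uncorrelated and variance decomposes completely
  cv <- stats::cov(pca$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
  expect_equal(sum(pca$var_explained), sum(diag(stats::cor(m))), tolerance = 1e-10)

  # rank-1 input concentrates all variance on PC1
  r1 <- outer(rnorm(50), c(1, 2, 3, 4, 5))
  expect_warning(p1 <- beak_pca(r1, scale. = TRUE), "rank-deficient")
  expect_equal(p1$prop_explained[1], 1, tolerance = 1e-10)
})

test_that("on a star phylogeny the fit reduces to ordinary logistic regression", {
  set.seed(32)
  n <- 120
  st <- star_tree(n)
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(st$tip.label, c("p", "q")))
  y <- stats::setNames(rbinom(n, 1, stats::plogis(0.2 + X[, 1] - 0.8 * X[, 2])),
                       st$tip.label)
  fit <- phylo_logistic(y, X, st)
  # oracle: glm IRLS on the identical data
  g <- stats::glm(y ~ X, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(stats::coef(g)), tolerance = 1e-3)
  expect_equal(unname(fit$se), unname(summary(g)$coefficients[, 2]), tolerance = 0.02)
})

test_that("degenerate responses are refused explicitly", {
  st <- star_tree(40)
  X <- matrix(rnorm(40), dimnames = list(st$tip.label, "x"))
  expect_error(phylo_logistic(stats::setNames(rep(1, 40), st$tip.label), X, st),
               "constant")
  y_sep <- stats::setNames(as.integer(X[, 1] > 0), st$tip.label)
  expect_error(phylo_logistic(y_sep, X, st), "separation")
})

test_that("null coefficients have centered z-scores across replicates", {
  tr <- unit_tree(150, seed = 33)
  zs <- sapply(1:20, function(s) {
    set.seed(900 + s)
    X <- matrix(rnorm(150), dimnames = list(tr$tip.label, "x"))
    y <- simulate_binary_trait(tr, X, beta = c(0, 0), phylo_sd = 0.8, alpha = 2)
    if (length(unique(y)) < 2) return(NA)
    phylo_logistic(y, X, tr)$zscore[2]
  })
  zs <- zs[!is.na(zs)]
  # y is generated independently of X, so the slope z-score is symmetric
  # about zero; the residual phylogenetic correlation fattens its tails
  expect_lt(abs(stats::median(zs)), 1)
  expect_lt(mean(abs(zs) > 2.5), 0.5)
})

test_that("AIC ordering is invariant to affine predictor rescaling", {
  tr <- unit_tree(120, seed = 34)
  X <- matrix(rnorm(120), dimnames = list(tr$tip.label, "x"))
  y <- simulate_binary_trait(tr, X, beta = c(-0.3, 1), phylo_sd = 0.5,
                             alpha = 2, seed = 35)
  f1 <- phylo_logistic(y, X, tr)
  f2 <- phylo_logistic(y, X * 10 + 3, tr)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-3)
  expect_equal(f1$coefficients["x"] / 10, f2$coefficients["x"], tolerance = 1e-4)
})

test_that("model selection ranks by AIC, flags ties, and spots strong predictors", {
  tr <- unit_tree(250, seed = 36)
  set.seed(37)
  pred <- data.frame(strong = rnorm(250), noise = rnorm(250))
  rownames(pred) <- tr$tip.label
  y <- simulate_binary_trait(tr, as.matrix(pred$strong), beta = c(0, 2.5),
                             phylo_sd = 0.4, alpha = 2, seed = 38)
  cands <- list(none = character(0), strong = "strong",
                strong_dup = "strong",  # identical candidate: forced tie
                both = c("strong", "noise"))
  sel <- select_model(cands, y, pred, tr)
  expect_equal(sel$delta_aic[1], 0)
  expect_true(sel$model[1] %in% c("strong", "strong_dup", "both"))
  # the duplicated candidate is an exact tie, reported indistinguishable
  d_dup <- abs(sel$aic[sel$model == "strong"] - sel$aic[sel$model == "strong_dup"])
  expect_lt(d_dup, 1e-6)
  # dropping the only informative predictor is decisively worse
  expect_gt(sel$delta_aic[sel$model == "none"], 2)
  expect_true(sel$meaningful[sel$model == "none"])
  # adding pure noise costs roughly the 2-unit parameter penalty
  d_noise <- sel$aic[sel$model == "both"] - sel$aic[sel$model == "strong"]
  expect_lt(abs(d_noise), 4)

  pred_bad <- pred
  pred_bad$noise[1] <- NA
  expect_error(select_model(cands, y, pred_bad, tr), "row sets")
})
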