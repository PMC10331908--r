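#' Standardize continuous columns to mean 0, variance 1
#'
#' Uses the sample (n - 1) standard deviation; the centers and scales are
#' stored as attributes so the transform is invertible.
#'
#' @param x Numeric matrix or data frame of continuous columns.
#' @return Object of the same shape with attributes `center` and `scale`.
#' @export
standardize <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("standardize expects numeric columns")
  ctr <- colMeans(m)
  scl <- apply(m, 2, stats::sd)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero)) {
    stop("zero-variance column(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  }
  out <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  if (is.data.frame(x)) out <- as.data.frame(out)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Invert a standardization
#'
#' @param z Output of [standardize()].
#' @return The original columns.
#' @export
unstandardize <- function(z) {
  m <- as.matrix(z)
  out <- sweep(sweep(m, 2, attr(z, "scale"), "*"), 2, attr(z, "center"), "+")
  attr(out, "center") <- NULL
  attr(out, "scale") <- NULL
  out
}

#' PCA of the beak morphospace
#'
#' Principal components analysis of the four beak measurements together with
#' body mass, used to collapse the strongly inter-correlated size variables
#' before regression modelling. By default the analysis is on the correlation
#' matrix (columns scaled), since the inputs mix millimetres and grams; PC1 is
#' then interpretable as overall bill/body size and PC2 as a width/depth-to-
#' length shape ratio. A deterministic sign convention is applied: within each
#' component the largest-magnitude loading is positive.
#'
#' @param traits Numeric matrix/data frame (>= 5 complete rows); typically the
#'   5 columns of [beak_predictors()].
#' @param scale. Scale columns to unit variance before the eigendecomposition
#'   (default `TRUE`; recorded in the result).
#' @return A `pca_result` list: `loadings` (orthonormal columns), `scores`,
#'   `var_explained` (variance per component), `prop_explained`, `scaled`.
#' @export
beak_pca <- function(traits, scale. = TRUE) {
  m <- as.matrix(traits)
  if (anyNA(m)) stop("traits must be complete")
  if (nrow(m) < ncol(m)) stop("need at least as many rows as columns")
  pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  var_exp <- pc$sdev^2
  if (any(var_exp < 1e-12 * max(var_exp))) {
    warning("rank-deficient input: trailing components have zero variance")
  }
  structure(list(loadings = pc$rotation, scores = pc$x,
                 var_explained = var_exp,
                 prop_explained = var_exp / sum(var_exp),
                 scaled = scale.),
            class = "pca_result")
}

#' Phylogenetic logistic regression (estimating-equation method)
#'
#' Logistic regression of a binary trait with phylogenetically correlated
#' residual structure, in the estimating-equation spirit of Ives & Garland
#' (2010): the latent trait is attracted back toward its optimum at rate
#' `alpha` (an OU-type process), so the residual correlation between two
#' species decays as `exp(-alpha * d)` with their patristic distance `d`
#' (normalized so the maximum tip-to-tip distance is 1; large `alpha` = less
#' phylogenetic signal). For fixed `alpha`, coefficients solve the GEE score
#' equation by Fisher scoring; `alpha` is chosen by maximizing the Gaussian
#' quasi-likelihood of the correlated residuals. On a star phylogeny the
#' estimating equation reduces exactly to the ordinary logistic-regression
#' score equation.
#'
#' @param y Binary response (0/1, logical, or 2-level factor), named by tip
#'   label or aligned with `tree$tip.label`.
#' @param X Numeric predictor matrix/data frame (no intercept column; one is
#'   added). Continuous predictors should be standardized beforehand.
#' @param tree A rooted `phylo` whose tips are the rows.
#' @param alpha_bounds Search interval for `alpha` on the normalized-distance
#'   scale.
#' @details Model comparison uses a QIC-style criterion, the standard choice
#'   for estimating-equation fits (Pan 2001, Biometrics): the reported
#'   `loglik` is the independence-model Bernoulli log-likelihood evaluated at
#'   the estimating-equation coefficients, and `aic = 2k - 2 loglik` with `k`
#'   = coefficients + 1 for `alpha`. The Gaussian quasi-likelihood of the
#'   correlated residuals (returned as `alpha_profile_loglik`) is used only
#'   to profile `alpha`.
#' @return A `phylo_glm` list: `coefficients`, `se`, `zscore`, `alpha`,
#'   `loglik`, `alpha_profile_loglik`, `aic`, `fitted`, `converged`, `n`.
#' @export
phylo_logistic <- function(y, X, tree, alpha_bounds = c(0.01, 5000)) {
  validate_tree(tree)
  n <- ape::Ntip(tree)
  y <- align_tip_values(tree, y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  if (length(unique(y)) < 2) stop("y is constant; nothing to regress")
  Xm <- as.matrix(X)
  if (is.null(rownames(Xm))) rownames(Xm) <- tree$tip.label else {
    Xm <- Xm[tree$tip.label, , drop = FALSE]
  }
  if (ncol(Xm) > 0 && !is.numeric(Xm)) {
    stop("X must be numeric (encode factors beforehand)")
  }
  storage.mode(Xm) <- "double"
  if (nrow(Xm) != n) stop("X rows must match tree tips")
  Xd <- cbind(`(Intercept)` = 1, Xm)

  D <- stats::cophenetic(tree)[tree$tip.label, tree$tip.label]
  D <- D / max(D)

  # detect complete/quasi-complete separation once, in the independent-case
  # fit (separation is a property of (y, X), not of the correlation)
  g0 <- suppressWarnings(stats::glm.fit(Xd, y, family = stats::binomial()))
  if (all(abs(y - g0$fitted.values) < 1e-4) || max(abs(g0$coefficients)) > 1e3) {
    stop("complete (or quasi-complete) separation: coefficients diverge")
  }
  beta0 <- g0$coefficients

  fit_at_alpha <- function(alpha) {
    R <- exp(-alpha * D)
    ch <- tryCatch(chol(R), error = function(e) {
      tryCatch(chol(R + diag(1e-8, n)), error = function(e2) NULL)
    })
    if (is.null(ch)) return(list(loglik = -Inf))
    Rinv <- function(b) backsolve(ch, forwardsolve(t(ch), b))
    beta <- beta0
    converged <- FALSE
    for (it in seq_len(100)) {
      eta <- drop(Xd %*% beta)
      p <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
      s <- sqrt(p * (1 - p))
      Xs <- Xd * s
      U <- crossprod(Xs, Rinv((y - p) / s))
      I_f <- crossprod(Xs, Rinv(Xs))
      step <- tryCatch(drop(solve(I_f, U)), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) return(list(loglik = -Inf))
      # damp large steps: keeps the solver on track under near-singular R
      sm <- max(abs(step))
      if (sm > 5) step <- step * (5 / sm)
      beta <- beta + step
      if (max(abs(beta)) > 1e3) return(list(loglik = -Inf))
      if (max(abs(step)) < 1e-10) {
        converged <- TRUE
        break
      }
    }
    eta <- drop(Xd %*% beta)
    p <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
    s <- sqrt(p * (1 - p))
    r <- (y - p) / s
    logdetV <- 2 * sum(log(diag(ch))) + 2 * sum(log(s))
    ll <- -0.5 * (n * log(2 * pi) + logdetV + sum(r * Rinv(r)))
    if (!is.finite(ll)) return(list(loglik = -Inf))
    Xs <- Xd * s
    I_f <- crossprod(Xs, Rinv(Xs))
    bern_ll <- sum(stats::dbinom(y, 1, p, log = TRUE))
    list(beta = beta, loglik = ll, bern_loglik = bern_ll,
         vcov = solve(I_f), fitted = p, converged = converged)
  }

  opt <- stats::optimize(function(la) -fit_at_alpha(exp(la))$loglik,
                         interval = log(alpha_bounds))
  alpha <- exp(opt$minimum)
  fit <- fit_at_alpha(alpha)
  if (!is.finite(fit$loglik)) {
    stop("phylogenetic logistic fit failed to converge at the selected alpha")
  }
  se <- sqrt(diag(fit$vcov))
  k <- length(fit$beta) + 1L
  structure(list(coefficients = fit$beta, se = se,
                 zscore = fit$beta / se,
                 alpha = alpha, loglik = fit$bern_loglik,
                 alpha_profile_loglik = fit$loglik,
                 aic = 2 * k - 2 * fit$bern_loglik, k = k,
                 fitted = fit$fitted, converged = fit$converged, n = n),
            class = "phylo_glm")
}

#' @export
print.phylo_glm <- function(x, ...) {
  cat("Phylogenetic logistic regression (estimating equations)\n")
  print(data.frame(estimate = x$coefficients, se = x$se, z = x$zscore))
  cat(sprintf("alpha = %.3f, logLik = %.2f, AIC = %.2f, n = %d\n",
              x$alpha, x$loglik, x$aic, x$n))
  invisible(x)
}

#' Simulate a binary trait from the phylogenetic logistic model class
#'
#' Draws a latent phylogenetic deviation `u ~ MVN(0, phylo_sd^2 *
#' exp(-alpha * d))` on the (distance-normalized) tree and samples
#' `y ~ Bernoulli(plogis(X beta + u))`. Used for parameter-recovery and
#' calibration checks of [phylo_logistic()].
#'
#' @inheritParams phylo_logistic
#' @param beta Coefficient vector, intercept first (length `ncol(X) + 1`).
#' @param phylo_sd Standard deviation of the latent phylogenetic deviation.
#' @param alpha Attraction rate of the latent process.
#' @param seed Optional integer seed.
#' @return Named 0/1 vector over the tree's tips.
#' @export
simulate_binary_trait <- function(tree, X, beta, phylo_sd = 0.5, alpha = 2,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  Xd <- cbind(1, as.matrix(X))
  stopifnot(length(beta) == ncol(Xd))
  eta <- drop(Xd %*% beta)
  if (phylo_sd > 0) {
    D <- stats::cophenetic(tree)[tree$tip.label, tree$tip.label]
    D <- D / max(D)
    R <- exp(-alpha * D)
    u <- drop(t(chol(R + diag(1e-10, n))) %*% stats::rnorm(n)) * phylo_sd
    eta <- eta + u
  }
  stats::setNames(stats::rbinom(n, 1, stats::plogis(eta)), tree$tip.label)
}

#' AIC model selection over candidate predictor subsets
#'
#' Fits [phylo_logistic()] for each candidate subset of predictor columns on
#' an identical row set and ranks the fits by AIC. Candidates within 2 AIC
#' units of the best are reported as statistically indistinguishable from it,
#' never silently resolved; a competitor is flagged `meaningful` only when its
#' disadvantage exceeds 2 units.
#'
#' @param candidates Named list of character vectors; each vector names the
#'   predictor columns of one candidate model (use `character(0)` for the
#'   intercept-only model).
#' @param y Binary response named by species/tip.
#' @param predictors Data frame of (standardized) numeric predictor columns
#'   with rownames = tip labels, or a `species_id` column.
#' @param tree A rooted `phylo`.
#' @return Data frame ranked by AIC with columns `model`, `k`, `loglik`,
#'   `aic`, `delta_aic`, `indistinguishable` (ΔAIC <= 2) and `meaningful`
#'   (ΔAIC > 2); the fits are attached as attribute `fits`.
#' @export
select_model <- function(candidates, y, predictors, tree) {
  stopifnot(length(candidates) >= 2)
  if (is.null(names(candidates))) {
    names(candidates) <- vapply(candidates, function(cl) {
      if (length(cl) == 0) "(intercept)" else paste(cl, collapse = "+")
    }, character(1))
  }
  if ("species_id" %in% names(predictors)) {
    rownames(predictors) <- predictors$species_id
    predictors$species_id <- NULL
  }
  all_cols <- unique(unlist(candidates))
  missing <- setdiff(all_cols, names(predictors))
  if (length(missing) > 0) stop("unknown predictor columns: ", paste(missing, collapse = ", "))
  cc <- stats::complete.cases(predictors[all_cols])
  if (!all(cc)) stop("incomplete rows would give candidates different row sets: ",
                     sum(!cc), " rows with missing values")
  fits <- lapply(candidates, function(cl) {
    X <- as.matrix(predictors[tree$tip.label, cl, drop = FALSE])
    phylo_logistic(y, X, tree)
  })
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  out <- data.frame(model = names(candidates),
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    aic = aic,
                    stringsAsFactors = FALSE)
  out <- out[order(out$aic), ]
  out$delta_aic <- out$aic - out$aic[1]
  out$indistinguishable <- out$delta_aic <= 2
  out$meaningful <- out$delta_aic > 2
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
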