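# direct numerical maximization of the multivariate-normal BM likelihood,
# independent of the closed-form GLS path
oracle_bm_fit <- function(tree, x) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  n <- length(x)
  nll <- function(par) {
    s2 <- exp(par[1])
    V <- s2 * C
    ch <- chol(V)
    r <- x - par[2]
    0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
             sum(r * backsolve(ch, forwardsolve(t(ch), r))))
  }
  opt <- stats::optim(c(log(stats::var(x)), mean(x)), nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  list(sigma2 = exp(opt$par[1]), z0 = opt$par[2], loglik = -opt$value)
}

test_that("BM fit matches direct likelihood maximization and closed forms", {
  # constant trait: degenerate rate
  tr <- unit_tree(10, seed = 1)
  fit <- fit_bm(tr, stats::setNames(rep(2.5, 10), tr$tip.label))
  expect_equal(fit$sigma2, 0)
  expect_equal(fit$z0, 2.5)

  # generic optimizer oracle on 10-tip trees
  for (s in 1:3) {
    tr <- unit_tree(10, seed = 30 + s)
    x <- simulate_bm(tr, bm_params(2, 1), seed = s)[, 1]
    fit <- fit_bm(tr, x)
    orc <- oracle_bm_fit(tr, x)
    expect_equal(fit$sigma2, orc$sigma2, tolerance = 1e-5)
    expect_equal(fit$z0, orc$z0, tolerance = 1e-6)
    expect_equal(fit$loglik, orc$loglik, tolerance = 1e-6)
  }

  # star tree with unit branches: GLS collapses to iid moments
  st <- star_tree(25)
  set.seed(4)
  x <- stats::setNames(rnorm(25, 3, 2), st$tip.label)
  fit <- fit_bm(st, x)
  expect_equal(fit$z0, mean(x), tolerance = 1e-12)
  expect_equal(fit$sigma2, mean((x - mean(x))^2), tolerance = 1e-12)
})

test_that("BM simulation has the analytic tip variances and covariances", {
  # variance grows as sigma2 * depth
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  sims <- simulate_bm(tr, bm_params(3, 0), n_reps = 10000, seed = 5)
  v <- stats::var(sims["A", ])
  se <- 3 * 2 * sqrt(2 / 10000)  # 3 MC SEs of a variance estimate, var = sigma2*d = 6
  expect_lt(abs(v - 6), 3 * 6 * sqrt(2 / 10000) * 1.5)
  # sister tips share the stem covariance sigma2 * s
  cv <- stats::cov(sims["A", ], sims["B", ])
  expect_lt(abs(cv - 3), 0.35)
  # zero rate: everything sits at the root state
  expect_true(all(simulate_bm(tr, bm_params(0, 1.5), n_reps = 5) == 1.5))
})

test_that("pruning preserves the BM likelihood of the retained tips", {
  tr <- unit_tree(30, seed = 12)
  x <- simulate_bm(tr, bm_params(1.5, 0), seed = 3)[, 1]
  keep <- sort(sample(tr$tip.label, 12))
  pruned <- prune_to_taxa(tr, keep)
  pars <- bm_params(1.5, 0)
  # oracle: MVN density from the submatrix of the full tree's covariance
  C <- ape::vcv(tr)[keep, keep]
  ch <- chol(1.5 * C)
  r <- x[keep]
  ll_direct <- -0.5 * (length(keep) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                         sum(r * backsolve(ch, forwardsolve(t(ch), r))))
  expect_equal(bm_loglik(pruned, x[keep], pars), ll_direct, tolerance = 1e-8)
})

test_that("Mk transition probabilities match the matrix exponential", {
  # oracle: eigendecomposition of the ER rate matrix
  k <- 4; q <- 0.7; t <- 0.9
  Q <- matrix(q, k, k); diag(Q) <- -(k - 1) * q
  eg <- eigen(Q)
  P <- eg$vectors %*% diag(exp(t * eg$values)) %*% solve(eg$vectors)
  tp <- beaknest:::mk_transition(k, q, t)
  expect_equal(P[1, 1], tp$stay, tolerance = 1e-10)
  expect_equal(P[1, 2], tp$switch, tolerance = 1e-10)

  # two tips separated by total path t, k = 2: P(differ) = (1 - e^(-2qt))/2
  tr <- read_newick(text = "(A:0.45,B:0.45);")
  sims <- simulate_mk(tr, mk_params(2, 0.7), n_reps = 20000, seed = 6)
  p_diff <- mean(sims["A", ] != sims["B", ])
  p_exact <- (1 - exp(-2 * 0.7 * 0.9)) / 2
  expect_lt(abs(p_diff - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 20000))

  # zero rate: all tips inherit the root state
  sims0 <- simulate_mk(unit_tree(12, seed = 2), mk_params(3, 0), n_reps = 20, seed = 1)
  expect_true(all(apply(sims0, 2, function(cl) length(unique(cl)) == 1)))
})

test_that("Mk rate estimate is the likelihood maximizer and matches phytools", {
  tr <- unit_tree(60, seed = 15)
  states <- simulate_mk(tr, mk_params(3, 1.2), seed = 8)[, 1]
  fit <- fit_mk(tr, states)
  q <- fit$params$q
  for (alt in c(q / 2, 2 * q)) {
    expect_gte(fit$loglik, mk_loglik(tr, states, mk_params(3, alt, fit$params$levels)))
  }
  skip_if_not_installed("phytools")
  ph <- phytools::fitMk(tr, states, model = "ER", pi = "equal")
  expect_equal(q, ph$rates, tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ph)), tolerance = 1e-4)
})

test_that("a single observed state yields a zero rate with a warning", {
  tr <- unit_tree(8, seed = 3)
  expect_warning(fit <- fit_mk(tr, stats::setNames(rep("a", 8), tr$tip.label)),
                 "single observed state")
  expect_equal(fit$params$q, 0)
})
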