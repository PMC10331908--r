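#' Brownian-motion and Mk parameter containers
#'
#' @param sigma2 Evolutionary rate (trait units squared per unit branch length).
#' @param z0 Root state (trait units).
#' @return A `bm_params` / `mk_params` list.
#' @export
bm_params <- function(sigma2, z0) {
  stopifnot(is.numeric(sigma2), length(sigma2) == 1, sigma2 >= 0,
            is.numeric(z0), length(z0) == 1)
  structure(list(sigma2 = sigma2, z0 = z0), class = "bm_params")
}

#' @rdname bm_params
#' @param k Number of discrete states (>= 2).
#' @param q Single transition rate of the equal-rates Mk model (per unit
#'   branch length).
#' @param levels State labels (length `k`).
#' @export
mk_params <- function(k, q, levels = paste0("S", seq_len(k))) {
  stopifnot(k >= 2, q >= 0, length(levels) == k)
  structure(list(k = as.integer(k), q = q, levels = as.character(levels)),
            class = "mk_params")
}

align_tip_values <- function(tree, x) {
  if (!is.null(names(x))) {
    missing <- setdiff(tree$tip.label, names(x))
    if (length(missing) > 0) {
      stop("tip values missing for: ", paste(missing, collapse = ", "))
    }
    x <- x[tree$tip.label]
  } else if (length(x) != ape::Ntip(tree)) {
    stop("unnamed tip values must match the number of tips")
  }
  x
}

#' Fit Brownian motion to continuous tip values by maximum likelihood
#'
#' Under Brownian motion the tip values are multivariate normal with mean `z0`
#' and covariance `sigma2 * C`, where `C[i, j]` is the shared root-to-tip path
#' length of tips i and j. The ML estimates have closed forms: `z0` is the GLS
#' mean and `sigma2` the GLS mean squared deviation (ML, not REML, matching
#' the convention of standard continuous-trait fitters).
#'
#' @param tree A rooted `phylo` with branch lengths (>= 3 tips). Polytomies
#'   are resolved with zero-length branches.
#' @param x Numeric tip values, named by tip label (or in tip order).
#' @return A `bm_fit` list: `sigma2`, `z0`, `loglik`, `n`.
#' @export
fit_bm <- function(tree, x) {
  validate_tree(tree)
  tree <- resolve_binary(tree)
  if (ape::Ntip(tree) < 3) stop("need >= 3 tips")
  x <- align_tip_values(tree, x)
  if (any(!is.finite(x))) stop("non-finite tip values")
  C <- ape::vcv(tree)
  ch <- tryCatch(chol(C), error = function(e) {
    stop("singular phylogenetic covariance (e.g. zero-length star with duplicate tips)")
  })
  fit <- bm_fit_chol(ch, x)
  structure(c(fit, list(n = length(x))), class = "bm_fit")
}

# Closed-form GLS fit given chol(C); reused across predictors sharing a tree.
bm_fit_chol <- function(ch, x) {
  n <- length(x)
  one <- rep(1, n)
  Cinv_x <- backsolve(ch, forwardsolve(t(ch), x))
  Cinv_1 <- backsolve(ch, forwardsolve(t(ch), one))
  z0 <- sum(Cinv_x) / sum(Cinv_1)
  r <- x - z0
  Cinv_r <- Cinv_x - z0 * Cinv_1
  sigma2 <- sum(r * Cinv_r) / n
  logdetC <- 2 * sum(log(diag(ch)))
  loglik <- if (sigma2 > 0) {
    -0.5 * (n * log(2 * pi * sigma2) + logdetC + n)
  } else {
    Inf  # degenerate: constant trait
  }
  list(sigma2 = sigma2, z0 = z0, loglik = loglik)
}

#' Brownian-motion log-likelihood at fixed parameters
#'
#' @inheritParams fit_bm
#' @param params A `bm_params` object.
#' @return Log-likelihood of the tip values.
#' @export
bm_loglik <- function(tree, x, params) {
  x <- align_tip_values(tree, x)
  C <- ape::vcv(resolve_binary(tree))
  n <- length(x)
  V <- params$sigma2 * C
  ch <- chol(V)
  r <- x - params$z0
  q <- sum(r * backsolve(ch, forwardsolve(t(ch), r)))
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
}

#' Simulate Brownian motion on a tree
#'
#' Starts at the root state and adds an independent Gaussian increment along
#' each branch with variance `sigma2 * branch length`.
#'
#' @inheritParams fit_bm
#' @param params A `bm_params` object.
#' @param n_reps Number of independent replicate traits.
#' @param seed Optional integer seed.
#' @return Numeric matrix, tips x replicates, rownames = tip labels.
#' @export
simulate_bm <- function(tree, params, n_reps = 1, seed = NULL) {
  validate_tree(tree)
  stopifnot(inherits(params, "bm_params"), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_tip <- ape::Ntip(tree)
  post <- ape::reorder.phylo(tree, "postorder")
  val <- matrix(NA_real_, n_tip + tree$Nnode, n_reps)
  root <- n_tip + 1L
  val[root, ] <- params$z0
  for (e in rev(seq_len(nrow(post$edge)))) {  # preorder
    par <- post$edge[e, 1]
    ch <- post$edge[e, 2]
    val[ch, ] <- val[par, ] +
      stats::rnorm(n_reps, 0, sqrt(params$sigma2 * post$edge.length[e]))
  }
  out <- val[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

# Equal-rates Mk transition-probability entries at time t:
# P(stay) = 1/k + (k-1)/k e^{-kqt}, P(each switch) = 1/k - 1/k e^{-kqt}.
mk_transition <- function(k, q, t) {
  decay <- exp(-k * q * t)
  p_stay <- 1 / k + (k - 1) / k * decay
  p_switch <- 1 / k - decay / k
  list(stay = p_stay, switch = p_switch)
}

mk_loglik_tree <- function(post, tip_states_int, k, q) {
  n_tip <- length(tip_states_int)
  n_all <- n_tip + post$Nnode
  L <- matrix(1, n_all, k)
  L[seq_len(n_tip), ] <- 0
  L[cbind(seq_len(n_tip), tip_states_int)] <- 1
  logscale <- 0
  edge <- post$edge
  len <- post$edge.length
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]
    ch <- edge[e, 2]
    tp <- mk_transition(k, q, len[e])
    s <- sum(L[ch, ])
    contrib <- tp$switch * s + (tp$stay - tp$switch) * L[ch, ]
    L[par, ] <- L[par, ] * contrib
    m <- max(L[par, ])
    if (m <= 0) return(-Inf)
    L[par, ] <- L[par, ] / m
    logscale <- logscale + log(m)
  }
  root <- n_tip + 1L
  log(sum(L[root, ]) / k) + logscale
}

#' Fit the equal-rates Mk model to discrete tip states
#'
#' Maximum-likelihood estimation of the single transition rate of the
#' equal-rates (ER) Mk model via Felsenstein's pruning algorithm with a
#' uniform root prior, optimized over log(q).
#'
#' @inheritParams fit_bm
#' @param states Character/factor tip states, named by tip label (or in tip
#'   order). Factor levels define the state space; unused levels are kept.
#' @return An `mk_fit` list: `params` (an [mk_params()]), `loglik`.
#' @export
fit_mk <- function(tree, states) {
  validate_tree(tree)
  tree <- resolve_binary(tree)
  states <- align_tip_values(tree, states)
  f <- if (is.factor(states)) states else factor(states)
  k <- nlevels(f)
  if (k < 2 || length(unique(as.integer(f))) < 2) {
    warning("single observed state: q estimated as 0")
    lev <- levels(f)
    if (length(lev) < 2) lev <- c(lev, "other")
    k <- length(lev)
    return(structure(list(params = mk_params(k, 0, levels = lev),
                          loglik = log(1 / k)), class = "mk_fit"))
  }
  post <- ape::reorder.phylo(tree, "postorder")
  tips_int <- as.integer(f)
  H <- max(ape::node.depth.edgelength(tree))
  opt <- stats::optimize(function(lq) -mk_loglik_tree(post, tips_int, k, exp(lq)),
                         interval = c(log(1e-7 / H), log(500 / H)))
  structure(list(params = mk_params(k, exp(opt$minimum), levels = levels(f)),
                 loglik = -opt$objective),
            class = "mk_fit")
}

#' Mk log-likelihood at a fixed rate
#'
#' @inheritParams fit_mk
#' @param params An `mk_params` object whose levels cover the observed states.
#' @return Log-likelihood under the equal-rates Mk model, uniform root prior.
#' @export
mk_loglik <- function(tree, states, params) {
  tree <- resolve_binary(tree)
  states <- align_tip_values(tree, states)
  f <- factor(states, levels = params$levels)
  if (anyNA(f)) stop("states outside params$levels")
  post <- ape::reorder.phylo(tree, "postorder")
  mk_loglik_tree(post, as.integer(f), params$k, params$q)
}

#' Simulate the equal-rates Mk model on a tree
#'
#' The root state is drawn uniformly; states evolve down each branch under the
#' ER rate matrix using the closed-form transition probabilities.
#'
#' @inheritParams simulate_bm
#' @param params An `mk_params` object.
#' @return Character matrix of tip states (tips x replicates).
#' @export
simulate_mk <- function(tree, params, n_reps = 1, seed = NULL) {
  validate_tree(tree)
  stopifnot(inherits(params, "mk_params"), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- params$k
  n_tip <- ape::Ntip(tree)
  post <- ape::reorder.phylo(tree, "postorder")
  st <- matrix(NA_integer_, n_tip + tree$Nnode, n_reps)
  st[n_tip + 1L, ] <- sample.int(k, n_reps, replace = TRUE)
  for (e in rev(seq_len(nrow(post$edge)))) {
    par <- post$edge[e, 1]
    ch <- post$edge[e, 2]
    tp <- mk_transition(k, params$q, post$edge.length[e])
    stay <- stats::runif(n_reps) < tp$stay
    shift <- sample.int(k - 1L, n_reps, replace = TRUE)
    st[ch, ] <- ifelse(stay, st[par, ], (st[par, ] - 1L + shift) %% k + 1L)
  }
  out <- matrix(params$levels[st[seq_len(n_tip), ]], n_tip, n_reps)
  rownames(out) <- tree$tip.label
  out
}
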