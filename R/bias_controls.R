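#' Null-distribution report
#'
#' @param accuracies Numeric vector of replicate accuracies (percent).
#' @param null_kind `"phylogenetic"` or `"downsampled"`.
#' @return A `null_report` list: `accuracies`, `summary` (median and
#'   interquartile range), `n_replicates`, `null_kind`.
#' @export
null_report <- function(accuracies, null_kind = c("phylogenetic", "downsampled")) {
  null_kind <- match.arg(null_kind)
  qs <- stats::quantile(accuracies, c(0.25, 0.75), names = FALSE)
  structure(list(accuracies = accuracies,
                 summary = list(median = stats::median(accuracies),
                                iqr = c(lower = qs[1], upper = qs[2])),
                 n_replicates = length(accuracies),
                 null_kind = null_kind),
            class = "null_report")
}

#' @export
print.null_report <- function(x, ...) {
  cat(sprintf("%s null: median accuracy %.1f%% (IQR %.1f-%.1f, %d replicates)\n",
              x$null_kind, x$summary$median, x$summary$iqr["lower"],
              x$summary$iqr["upper"], x$n_replicates))
  invisible(x)
}

fit_family_forest <- function(predictors, labels, config, predictor_cols = NULL) {
  oob_report(fit_forest(predictors, labels, config, predictor_cols))$overall_accuracy
}

#' Phylogenetic-simulation null for classifier accuracy
#'
#' Quantifies how much classifier accuracy is attributable to phylogenetic
#' signal alone. Per topology, every continuous predictor is replaced by a
#' Brownian-motion simulation at its own maximum-likelihood parameters on that
#' topology, and every categorical predictor by an equal-rates Mk simulation
#' at its fitted rate; the random forest is then refit against the *observed*
#' labels and its out-of-bag accuracy recorded. Labels are never simulated.
#' A null accuracy close to the observed accuracy indicates that shared
#' evolutionary history, not ecology, can carry the prediction; a null near
#' chance indicates the phylogeny explains little.
#'
#' @param labels Observed class labels, named by species id.
#' @param predictors Predictor data frame (`species_id` + columns). Numeric
#'   columns are treated as continuous, factor/character as categorical.
#' @param trees A `multiPhylo` sample of topologies; every species must be a
#'   tip of every tree.
#' @param config An [rf_config()].
#' @param n_topologies Number of topologies used (default: all supplied).
#' @param seed Base seed; replicate t uses `seed + t`, so results are
#'   reproducible per (seed, topology-index) pair.
#' @param simulate_predictors If `FALSE` the observed predictors are passed
#'   through unsimulated (the null machinery then reproduces the observed
#'   accuracy exactly; useful as a self-check).
#' @return A `null_report` with `null_kind = "phylogenetic"`.
#' @export
phylo_null <- function(labels, predictors, trees, config = rf_config(),
                       n_topologies = NULL, seed = 1L,
                       simulate_predictors = TRUE) {
  if (is.null(names(labels))) stop("labels must be named by species id")
  species <- names(labels)
  predictors <- predictors[match(species, predictors$species_id), , drop = FALSE]
  if (anyNA(predictors$species_id)) stop("predictors missing for some labelled species")
  if (!simulate_predictors) {
    n_top <- if (is.null(n_topologies)) length(as_multiphylo(trees)) else n_topologies
    acc <- rep(fit_family_forest(predictors, labels, config), n_top)
    return(null_report(acc, "phylogenetic"))
  }
  sims <- simulate_phylo_predictors(predictors, trees, n_topologies, seed)
  acc <- vapply(sims, fit_family_forest, numeric(1),
                labels = labels, config = config)
  null_report(unname(acc), "phylogenetic")
}

#' Simulate predictor replacement sets on a sample of topologies
#'
#' The workhorse behind [phylo_null()], exposed so several model families can
#' share one set of simulated predictors. Per topology, each continuous
#' predictor is refit ([fit_bm()]) and re-simulated under Brownian motion, and
#' each categorical predictor refit ([fit_mk()]) and re-simulated under the
#' equal-rates Mk model; all 12 predictors are simulated jointly per replicate
#' (full replacement). Simulated columns that come out constant (e.g. from a
#' zero fitted rate) are dropped from that replicate with a warning.
#'
#' @inheritParams phylo_null
#' @return List of simulated predictor data frames, one per topology.
#' @export
simulate_phylo_predictors <- function(predictors, trees, n_topologies = NULL,
                                      seed = 1L) {
  trees <- as_multiphylo(trees)
  species <- predictors$species_id
  for (i in seq_along(trees)) {
    missing <- setdiff(species, trees[[i]]$tip.label)
    if (length(missing) > 0) {
      stop("species missing from tree ", i, ": ", paste(missing, collapse = ", "))
    }
  }
  n_top <- if (is.null(n_topologies)) length(trees) else min(n_topologies, length(trees))
  cols <- setdiff(names(predictors), "species_id")
  sims <- vector("list", n_top)
  for (t in seq_len(n_top)) {
    tree <- if (setequal(trees[[t]]$tip.label, species)) trees[[t]] else prune_to_taxa(trees[[t]], species)
    tree <- resolve_binary(tree)
    set.seed(seed + t)
    ch <- chol(ape::vcv(tree))
    sim <- data.frame(species_id = species, stringsAsFactors = FALSE)
    for (nm in cols) {
      v <- predictors[[nm]]
      if (is.numeric(v)) {
        names(v) <- species
        fit <- bm_fit_chol(ch, v[tree$tip.label])
        s <- simulate_bm(tree, bm_params(fit$sigma2, fit$z0))[, 1]
        sim[[nm]] <- unname(s[species])
      } else {
        v <- factor(v)
        names(v) <- species
        fit <- suppressWarnings(fit_mk(tree, v[tree$tip.label]))
        s <- simulate_mk(tree, fit$params)[, 1]
        sim[[nm]] <- factor(unname(s[species]), levels = fit$params$levels)
      }
      col <- sim[[nm]]
      degenerate <- if (is.numeric(col)) stats::sd(col) == 0 else length(unique(col)) < 2
      if (degenerate) {
        warning("simulated predictor '", nm, "' is constant on topology ", t,
                "; dropped from this replicate")
        sim[[nm]] <- NULL
      }
    }
    sims[[t]] <- sim
  }
  sims
}

#' Class-balanced downsampling null
#'
#' Quantifies how much classifier accuracy rests on class-frequency bias.
#' Per replicate, species from the more frequent classes are omitted at
#' random until every class retains exactly the smallest class's size; the
#' model is refit and its out-of-bag accuracy recorded. The retained species'
#' rows are untouched (subsampling only, no reweighting). The headline
#' summary is the median over replicates.
#'
#' @inheritParams phylo_null
#' @param n_reps Number of downsampling replicates (default 100).
#' @return A `null_report` with `null_kind = "downsampled"`.
#' @export
downsample_null <- function(labels, predictors, config = rf_config(),
                            n_reps = 100, seed = 1L) {
  if (is.null(names(labels))) stop("labels must be named by species id")
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2) stop("need >= 2 classes")
  tab <- table(y)
  m <- min(tab)
  if (m < 2) stop("smallest class has fewer than 2 members (", m, ")")
  predictors <- predictors[match(names(labels), predictors$species_id), , drop = FALSE]
  acc <- numeric(n_reps)
  sizes <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    idx <- sort(unlist(lapply(levels(y), function(cl) {
      cand <- which(y == cl)
      if (length(cand) == m) cand else sample(cand, m)
    }), use.names = FALSE))  # original row order: subsampling only
    sizes[[r]] <- table(y[idx])
    acc[r] <- fit_family_forest(predictors[idx, , drop = FALSE],
                                labels[idx], config)
  }
  out <- null_report(acc, "downsampled")
  attr(out, "replicate_class_sizes") <- sizes
  out
}
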