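#' Continuous and categorical predictor layouts
#'
#' The predictor set mirrors the standard avian trait-database layout: four
#' beak measurements (mm), body mass (g) and hand-wing index (continuous), and
#' six ecological factors (trophic level, trophic niche, trophic lifestyle,
#' habitat density, habitat, migration).
#'
#' @return Character vector of column names (or a named list of factor levels).
#' @export
continuous_predictors <- function() {
  c("bill_length_total", "bill_length_nares", "bill_width_nares",
    "bill_depth_nares", "body_mass", "hand_wing_index")
}

#' @rdname continuous_predictors
#' @export
categorical_predictors <- function() {
  list(
    trophic_level = c("Carnivore", "Herbivore", "Omnivore", "Scavenger"),
    trophic_niche = c("Aquatic.predator", "Frugivore", "Granivore",
                      "Herbivore.aquatic", "Herbivore.terrestrial",
                      "Invertivore", "Nectarivore", "Omnivore", "Scavenger",
                      "Vertivore"),
    trophic_lifestyle = c("Aerial", "Aquatic", "Generalist", "Insessorial",
                          "Terrestrial"),
    habitat_density = c("Dense", "Semi.open", "Open"),
    habitat = c("Coastal", "Desert", "Forest", "Grassland", "Human.modified",
                "Marine", "Riverine", "Rock", "Shrubland", "Wetland",
                "Woodland"),
    migration = c("Sedentary", "Partial", "Migratory")
  )
}

# log-scale location/spread used to place simulated continuous predictors on
# plausible positive scales (mm, g, index units)
cont_log_scales <- function() {
  data.frame(
    name = continuous_predictors(),
    mu = c(3.2, 2.9, 2.0, 2.0, 3.9, 3.2),
    s = c(0.5, 0.5, 0.45, 0.5, 1.0, 0.35),
    stringsAsFactors = FALSE
  )
}

#' Default multinomial-logit structure of the generator
#'
#' `default_effect_matrix()` is the 7 x 6 coefficient matrix mapping the
#' standardized continuous predictors to category scores;
#' `default_class_bias()` the per-category intercepts that produce the
#' strongly imbalanced class frequencies typical of nest-material data.
#' @return Matrix (7 x 6) or named numeric vector (length 7).
#' @export
default_effect_matrix <- function() {
  m <- rbind(
    binder  = c( 0.0,  0.0,  0.5,  1.0,  0.5,  0.0),
    fibre   = c(-0.8, -0.5,  0.0,  0.0, -0.5,  0.0),
    grass   = c( 0.0,  0.5,  0.0,  0.0,  0.0, -0.5),
    leaf    = c( 0.0,  0.0,  0.5,  0.0,  0.0, -0.8),
    mineral = c( 0.5,  0.0,  0.0,  0.0,  0.8,  0.8),
    silk    = c(-0.5,  0.0,  0.0, -0.5, -1.0,  0.0),
    twig    = c( 0.8,  0.5,  0.0,  0.0,  0.8,  0.0)
  )
  colnames(m) <- continuous_predictors()
  m
}

#' @rdname default_effect_matrix
#' @export
default_class_bias <- function() {
  c(binder = 0.8, fibre = 1.0, grass = 1.2, leaf = 0.2,
    mineral = -1.0, silk = -0.6, twig = 0.9)
}

#' Configuration for the synthetic dataset generator
#'
#' Defines the statistical structure of a simulated study: a pure-birth tree
#' (plus branch-length-jittered copies standing in for a posterior sample of
#' topologies), continuous predictors blending a Brownian-motion component
#' with independent noise, categorical predictors evolving under equal-rates
#' Mk, and 7-category material labels from a multinomial logit on the
#' standardized predictors plus per-category latent Brownian effects and
#' imbalance-controlling intercepts.
#'
#' @param n_species Number of species (tips).
#' @param n_trees Number of trees in the emitted sample (default 100).
#' @param birth_rate Per-lineage speciation rate of the Yule simulator.
#' @param signal_mix Weight in `[0, 1]` blending the Brownian component (1 =
#'   pure phylogenetic signal) with iid noise per continuous predictor; scalar
#'   or length-6 vector.
#' @param effect_matrix 7 x 6 coefficient matrix mapping standardized
#'   continuous predictors to category scores (rows = categories).
#' @param phylo_effect_sd Standard deviation of the per-category latent
#'   Brownian trait added to category scores; dials how much of label
#'   variation is phylogenetic rather than ecological.
#' @param class_bias Per-category intercepts (length 7) controlling class
#'   imbalance via the softmax of the score.
#' @param extra_p Probability that the 2nd-ranked category also enters the
#'   used set; halves per further rank (generates both specialists and
#'   generalists).
#' @param mk_rate Total leave-rate of each categorical predictor per unit tree
#'   height (converted to the ER per-pair rate internally).
#' @param tree_jitter_sd Lognormal SD of multiplicative branch-length jitter
#'   applied to the extra trees (topology kept fixed).
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_species = 300, n_trees = 100, birth_rate = 1,
                         signal_mix = 0.7,
                         effect_matrix = default_effect_matrix(),
                         phylo_effect_sd = 1,
                         class_bias = default_class_bias(),
                         extra_p = 0.35, mk_rate = 1, tree_jitter_sd = 0.1,
                         seed = 1L) {
  stopifnot(n_species >= 3, n_trees >= 1, birth_rate > 0,
            all(signal_mix >= 0 & signal_mix <= 1),
            length(signal_mix) %in% c(1, 6),
            is.matrix(effect_matrix), nrow(effect_matrix) == 7,
            ncol(effect_matrix) == 6,
            phylo_effect_sd >= 0, length(class_bias) == 7,
            extra_p >= 0 && extra_p <= 1, mk_rate >= 0, tree_jitter_sd >= 0)
  structure(list(n_species = as.integer(n_species),
                 n_trees = as.integer(n_trees), birth_rate = birth_rate,
                 signal_mix = rep(signal_mix, length.out = 6),
                 effect_matrix = effect_matrix,
                 phylo_effect_sd = phylo_effect_sd,
                 class_bias = class_bias, extra_p = extra_p,
                 mk_rate = mk_rate, tree_jitter_sd = tree_jitter_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate a pure-birth (Yule) tree
#'
#' @param n_species Number of tips (>= 3).
#' @param birth_rate Per-lineage speciation rate.
#' @param seed Optional integer seed.
#' @return An ultrametric `phylo` with `n_species` tips labelled `sp0001, ...`.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  stopifnot(n_species >= 3)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tr$tip.label <- sprintf("sp%04d", seq_len(n_species))
  tr
}

scale_to_unit_height <- function(tree) {
  H <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / H
  tree
}

std <- function(x) (x - mean(x)) / stats::sd(x)

#' Generate a synthetic nest-material study dataset
#'
#' Produces a tree sample, a 12-column predictor table and material profiles
#' whose generating process matches the assumptions of the downstream models:
#' continuous predictors carry tunable phylogenetic signal, categorical
#' predictors evolve under Mk, and material labels follow a multinomial logit
#' on the predictors with an independently tunable latent phylogenetic
#' component — so ecology-driven and phylogeny-driven classifier accuracy can
#' be dialled separately.
#'
#' @param config A [synth_config()] object.
#' @return A `beaknest_dataset` list: `trees` (`multiPhylo`, tree 1 is the
#'   generating tree), `predictors` (data frame, `species_id` + 12 columns),
#'   `profiles` (a `material_profiles` data frame), `scores` (n x 7 matrix of
#'   pre-noise category scores, for diagnostics) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_species
  cats <- material_categories()

  base <- scale_to_unit_height(simulate_tree(n, config$birth_rate))
  trees <- vector("list", config$n_trees)
  trees[[1]] <- base
  if (config$n_trees > 1) {
    for (i in 2:config$n_trees) {
      tr <- base
      jit <- stats::rnorm(length(tr$edge.length), 0, config$tree_jitter_sd)
      tr$edge.length <- tr$edge.length * exp(jit - config$tree_jitter_sd^2 / 2)
      trees[[i]] <- tr
    }
  }
  class(trees) <- "multiPhylo"

  # continuous predictors: standardized mix of BM and iid noise, mapped to
  # positive measurement scales by exponentiation
  scales <- cont_log_scales()
  Z <- matrix(NA_real_, n, 6, dimnames = list(base$tip.label, scales$name))
  pred <- data.frame(species_id = base$tip.label, stringsAsFactors = FALSE)
  for (j in seq_len(6)) {
    w <- config$signal_mix[j]
    bm <- simulate_bm(base, bm_params(1, 0))[, 1]
    noise <- stats::rnorm(n)
    raw <- w * std(bm) + (1 - w) * noise
    Z[, j] <- std(raw)
    pred[[scales$name[j]]] <- exp(scales$mu[j] + scales$s[j] * Z[, j])
  }

  cat_levels <- categorical_predictors()
  for (nm in names(cat_levels)) {
    k <- length(cat_levels[[nm]])
    q <- if (k > 1) config$mk_rate / (k - 1) else 0
    sim <- simulate_mk(base, mk_params(k, q, levels = cat_levels[[nm]]))[, 1]
    pred[[nm]] <- factor(sim, levels = cat_levels[[nm]])
  }

  # category scores: ecology + imbalance intercepts + latent phylogeny
  S <- Z %*% t(config$effect_matrix)
  S <- sweep(S, 2, config$class_bias, "+")
  if (config$phylo_effect_sd > 0) {
    lat <- simulate_bm(base, bm_params(1, 0), n_reps = 7)
    lat <- apply(lat, 2, std)
    S <- S + config$phylo_effect_sd * lat
  }
  colnames(S) <- cats

  gumbel <- matrix(-log(-log(stats::runif(n * 7))), n, 7)
  noisy <- S + gumbel
  ord <- t(apply(noisy, 1, order, decreasing = TRUE))
  primary <- cats[ord[, 1]]
  used <- matrix(0L, n, 7, dimnames = list(base$tip.label, cats))
  used[cbind(seq_len(n), ord[, 1])] <- 1L
  for (r in 2:7) {
    p_r <- config$extra_p * 0.5^(r - 2)
    add <- stats::runif(n) < p_r
    used[cbind(seq_len(n), ord[, r])[add, , drop = FALSE]] <- 1L
  }

  profiles <- data.frame(species_id = base$tip.label, stringsAsFactors = FALSE)
  for (cat in cats) profiles[[paste0("used_", cat)]] <- used[, cat]
  profiles$primary <- primary
  profiles$specialist <- rowSums(used) == 1L
  profiles$omit <- FALSE
  class(profiles) <- c("material_profiles", "data.frame")

  structure(list(trees = trees, predictors = pred, profiles = profiles,
                 scores = S, config = config),
            class = "beaknest_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits the same delimited-text + multi-Newick layout the real-data entry
#' point consumes: `predictors.csv`, `profiles.csv`, `trees.nwk`.
#'
#' @param dataset A `beaknest_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$predictors, file.path(dir, "predictors.csv"),
                   row.names = FALSE)
  write_material_profiles(dataset$profiles, file.path(dir, "profiles.csv"))
  write_newick(dataset$trees, file.path(dir, "trees.nwk"))
  invisible(dir)
}
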