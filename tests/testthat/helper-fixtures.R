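# shared fixtures built in code

unit_tree <- function(n, seed = NULL) {
  tr <- simulate_tree(n, birth_rate = 1, seed = seed)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

star_tree <- function(n, labels = NULL) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  if (!is.null(labels)) tr$tip.label <- labels
  tr
}

record_row <- function(species, source, descriptors, emphasized = NA) {
  data.frame(species_id = species, source_id = source,
             descriptors = paste(descriptors, collapse = ";"),
             emphasized = emphasized, stringsAsFactors = FALSE)
}

# independent clade-frequency scorer used as the MCC oracle
oracle_mcc_scores <- function(trees) {
  pp <- ape::prop.part(trees)
  labs <- attr(pp, "labels")
  key_of <- function(idx) paste(sort(labs[idx]), collapse = "|")
  freq <- stats::setNames(attr(pp, "number") / length(trees),
                          vapply(pp, key_of, character(1)))
  vapply(trees, function(tr) {
    parts <- ape::prop.part(tr)
    l2 <- attr(parts, "labels")
    sum(log(freq[vapply(parts, function(i) paste(sort(l2[i]), collapse = "|"),
                        character(1))]))
  }, numeric(1))
}

# iid-noise predictor table with no relation to any labels
noise_predictors <- function(n, p = 3, seed = 1) {
  set.seed(seed)
  out <- data.frame(species_id = sprintf("sp%04d", seq_len(n)))
  for (j in seq_len(p)) out[[paste0("x", j)]] <- rnorm(n)
  out
}
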