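#' Read and write Newick trees
#'
#' Thin wrappers over the ape Newick parser that add the validation the rest
#' of the pipeline relies on: unique tip labels, branch lengths present and
#' nonnegative. Multi-tree files are returned as `multiPhylo`; individual
#' trees are addressed by index.
#'
#' @param path Path to a Newick file, or a Newick string (`text =`).
#' @param text Optional Newick text (used instead of `path`).
#' @return A `phylo` object, or `multiPhylo` when the source holds several trees.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tr)) {
    stop("malformed Newick input: ", if (!is.null(text)) text else path)
  }
  if (inherits(tr, "multiPhylo")) {
    lapply(tr, validate_tree)
    return(tr)
  }
  validate_tree(tr)
  tr
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths")
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths")
  }
  invisible(tree)
}

#' @rdname read_newick
#' @param tree A `phylo` or `multiPhylo` object.
#' @param digits Printed precision for branch lengths.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  out <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}

#' Prune a tree to a set of taxa
#'
#' Drops all tips outside `taxa`, collapsing the resulting degree-2 internal
#' nodes and summing their branch lengths, so that patristic distances among
#' the retained tips are unchanged.
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip labels to retain (subset of the tips).
#' @return The pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, taxa) {
  validate_tree(tree)
  taxa <- unique(as.character(taxa))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0) {
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(taxa) < 2) stop("need at least 2 taxa to keep")
  ape::keep.tip(tree, taxa)
}

clade_key <- function(tips) paste(sort(tips), collapse = "\r")

# For each node of a rooted tree, the sorted tip set of its clade and the
# length of the edge subtending it (NA for the root).
tree_clades <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_node <- tree$Nnode
  desc <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- tree$tip.label[i]
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]
    ch <- post$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  sub_len <- rep(NA_real_, n_tip + n_node)
  sub_len[tree$edge[, 2]] <- tree$edge.length
  list(keys = vapply(desc, clade_key, character(1)), sub_len = sub_len)
}

#' Maximum-clade-credibility consensus of a tree sample
#'
#' Summarizes a sample of rooted trees over an identical tip set by the
#' maximum-clade-credibility (MCC) tree: the member of the sample whose product
#' of clade frequencies (clade credibilities) across the sample is largest —
#' the TreeAnnotator summary. Branch lengths of the selected tree are replaced
#' by per-clade medians over the trees containing that clade; terminal edges
#' are treated as singleton clades.
#'
#' @param trees A `multiPhylo` (or list) of rooted trees with branch lengths.
#' @return A `phylo`: the MCC tree with median-annotated branch lengths. The
#'   index of the selected tree is attached as attribute `mcc_index`, and the
#'   per-tree log clade-credibility scores as `log_scores`.
#' @export
consensus_tree <- function(trees) {
  trees <- as_multiphylo(trees)
  if (length(trees) < 1) stop("empty tree sample")
  tipsets <- lapply(trees, function(t) sort(t$tip.label))
  for (i in seq_along(tipsets)) {
    if (!identical(tipsets[[i]], tipsets[[1]])) {
      d <- union(setdiff(tipsets[[i]], tipsets[[1]]), setdiff(tipsets[[1]], tipsets[[i]]))
      stop("tree ", i, " has a different tip set; symmetric difference: ",
           paste(d, collapse = ", "))
    }
  }
  info <- lapply(trees, tree_clades)
  # clade frequencies and per-clade branch-length collections over the sample
  freq <- new.env(hash = TRUE, parent = emptyenv())
  lens <- new.env(hash = TRUE, parent = emptyenv())
  for (ti in seq_along(trees)) {
    keys <- info[[ti]]$keys
    sl <- info[[ti]]$sub_len
    for (j in seq_along(keys)) {
      k <- keys[j]
      freq[[k]] <- (if (is.null(freq[[k]])) 0L else freq[[k]]) + 1L
      if (!is.na(sl[j])) lens[[k]] <- c(lens[[k]], sl[j])
    }
  }
  n <- length(trees)
  # score each sample member by the product of its internal-clade frequencies
  scores <- vapply(seq_along(trees), function(ti) {
    keys <- info[[ti]]$keys
    internal <- keys[(ape::Ntip(trees[[ti]]) + 1):length(keys)]
    sum(log(vapply(internal, function(k) freq[[k]], numeric(1)) / n))
  }, numeric(1))
  best <- which.max(scores)
  mcc <- trees[[best]]
  keys <- info[[best]]$keys
  for (e in seq_len(nrow(mcc$edge))) {
    k <- keys[mcc$edge[e, 2]]
    mcc$edge.length[e] <- stats::median(lens[[k]])
  }
  attr(mcc, "mcc_index") <- best
  attr(mcc, "log_scores") <- scores
  mcc
}

as_multiphylo <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!inherits(trees, "multiPhylo")) {
    stopifnot(all(vapply(trees, inherits, logical(1), "phylo")))
    class(trees) <- "multiPhylo"
  }
  if (!is.null(attr(trees, "TipLabel"))) {
    trees <- ape::.uncompressTipLabel(trees)
  }
  trees
}

# Resolve polytomies arbitrarily with zero-length branches (likelihood-neutral
# for the BM/Mk machinery, which assumes binary trees).
resolve_binary <- function(tree) {
  if (ape::is.binary(tree)) return(tree)
  ape::multi2di(tree, random = FALSE)
}
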