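#' Read a neutral phylogeny from a newick file
#'
#' Thin wrapper around [ape::read.tree()] that checks branch lengths are
#' present and non-negative and that the reference species occurs exactly
#' once among the tips.
#'
#' @param path newick file.
#' @param ref_species tip label of the reference species.
#' @return an [ape::phylo] object with attribute `ref_species`.
#' @export
read_phylo <- function(path, ref_species) {
  tree <- ape::read.tree(path)
  validate_phylo(tree, ref_species)
}

validate_phylo <- function(tree, ref_species) {
  if (is.null(tree$edge.length)) stop("phylogeny has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in phylogeny")
  if (sum(tree$tip.label == ref_species) != 1) {
    stop("reference species '", ref_species,
         "' must appear exactly once in the tree")
  }
  attr(tree, "ref_species") <- ref_species
  tree
}

#' Total branch length of the subtree induced by a set of species
#'
#' Sums the branch lengths of the edges on the minimal subtree connecting
#' the given species together with the reference species (substitutions
#' per site). Adding a species never decreases the value; the empty set
#' gives 0.
#'
#' @param species character vector of preserving species (the reference is
#'   added implicitly and contributes its own pendant branch, if any).
#' @param tree an [ape::phylo] with branch lengths.
#' @param ref_species reference tip label; defaults to the tree's
#'   `ref_species` attribute.
#' @return non-negative numeric (substitutions/site).
#' @export
preserved_branch_length <- function(species, tree,
                                    ref_species = attr(tree, "ref_species")) {
  species <- setdiff(unique(as.character(species)), ref_species)
  if (length(species) == 0) return(0)
  unknown <- setdiff(species, tree$tip.label)
  if (length(unknown)) {
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  }
  selected <- c(species, ref_species)
  sel_tip <- match(selected, tree$tip.label)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  cnt <- integer(nnode)
  cnt[sel_tip] <- 1L
  # postorder accumulation of selected-tip counts per clade
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    cnt[po$edge[e, 1]] <- cnt[po$edge[e, 1]] + cnt[po$edge[e, 2]]
  }
  total <- length(selected)
  below <- cnt[tree$edge[, 2]]
  sum(tree$edge.length[below > 0 & below < total])
}
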