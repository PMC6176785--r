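# Distance-based tree building and rooting utilities (thin layer over
# ape/phangorn, with the cleanup conventions used throughout the package).

#' BIONJ tree from a distance matrix
#'
#' Builds the unrooted BIONJ tree.  Negative branch lengths produced by
#' the agglomeration are clamped to zero, with the total clamped amount
#' reported in a message.
#'
#' @param dm symmetric distance matrix with taxon dimnames and no
#'   undefined (NA) entries; at least 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
bionj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("need at least 3 taxa")
  if (anyNA(dm)) stop("distance matrix contains undefined entries")
  tr <- ape::bionj(stats::as.dist(dm))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sprintf("clamped %d negative branch length(s) (total %.3g)",
                    sum(neg), -sum(tr$edge.length[neg])))
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Root a tree with an outgroup, then drop it
#'
#' @param tree a `phylo` tree.
#' @param outgroup a tip label.
#' @return the rooted ingroup tree (outgroup removed).
#' @export
root_by_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) stop("outgroup not in tree")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::drop.tip(rooted, outgroup)
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest tip-to-tip path.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @return a rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length) || sum(tree$edge.length) == 0) {
    warning("tree has zero total length; rooting arbitrarily")
    return(ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}
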