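# Punctuated-evolution analysis: outgroup choice, root-to-tip statistics,
# the delta-test for the node-density artifact, PGLS regression of node
# counts on path lengths, and the Holm-Bonferroni decision rule.

#' Nearest outgroup of a family
#'
#' The non-member taxon with the minimal average distance to the family's
#' members; ties broken lexicographically.
#'
#' @param dm distance matrix over all taxa.
#' @param family_taxa taxon names of the family.
#' @return a taxon name.
#' @export
nearest_outgroup <- function(dm, family_taxa) {
  cand <- setdiff(rownames(dm), family_taxa)
  if (length(cand) == 0) stop("no taxa outside the family")
  means <- rowMeans(dm[cand, family_taxa, drop = FALSE])
  cand[order(means, cand)][1]
}

#' Root-to-tip path lengths and node counts
#'
#' For each leaf of a rooted tree: the sum of branch lengths from the root
#' and the number of branching internal nodes (at least two children) on
#' the path, the root included, the leaf excluded.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @return data frame `taxon`, `path_length`, `n_nodes`.
#' @export
root_to_tip_statistics <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  n_children <- tabulate(tree$edge[, 1], nbins = max(tree$edge))
  root <- n_tip + 1L
  counts <- vapply(seq_len(n_tip), function(tip) {
    v <- parent[tip]
    k <- 0L
    while (v != 0) {
      if (n_children[v] >= 2) k <- k + 1L
      v <- if (v == root) 0L else parent[v]
    }
    k
  }, integer(1))
  data.frame(taxon = tree$tip.label, path_length = depth[seq_len(n_tip)],
             n_nodes = counts, stringsAsFactors = FALSE)
}

#' Phylogenetic generalized least squares slope
#'
#' GLS regression of `y` on `x` across the leaves of a tree, with residual
#' covariance proportional to shared root-to-node path length (Brownian
#' motion on the given branch lengths, no additional transformation).
#' The estimate is computed in closed form,
#' `beta = (X' V^-1 X)^-1 X' V^-1 y`, with the full Brownian covariance
#' `V`, so tip-specific variances on non-ultrametric trees are respected.
#'
#' @param tree rooted `phylo` tree whose tips are the observations.
#' @param x,y numeric vectors named by (or ordered as) the tip labels.
#' @return list with `slope`, `se`, `p` (two-sided t test), `df`, and the
#'   full coefficient vector `coef`.
#' @export
pgls_slope <- function(tree, x, y) {
  taxa <- tree$tip.label
  if (!is.null(names(x))) x <- x[taxa]
  if (!is.null(names(y))) y <- y[taxa]
  if (sum(tree$edge.length) <= 0) stop("zero-length tree")
  V <- ape::vcv(tree)[taxa, taxa]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular phylogenetic covariance"))
  X <- cbind(`(Intercept)` = 1, x = x)
  XtVi <- crossprod(X, Vi)
  beta <- drop(solve(XtVi %*% X, XtVi %*% y))
  r <- y - drop(X %*% beta)
  n <- length(y)
  s2 <- drop(crossprod(r, Vi %*% r)) / (n - 2)
  covb <- s2 * solve(XtVi %*% X)
  se <- sqrt(covb["x", "x"])
  tstat <- beta["x"] / se
  list(slope = unname(beta["x"]), se = unname(se),
       p = unname(2 * pt(-abs(tstat), n - 2)), df = n - 2, coef = beta)
}

#' Delta-test for the node-density artifact
#'
#' Fits the curvilinear relation `n = beta * x^delta` between root-to-tip
#' node counts n and path lengths x (on log scales, with PGLS covariance).
#' The test is negative — no artifact — when the 95% confidence interval
#' for delta includes or lies below 1; it is positive (artifact present)
#' when the whole interval exceeds 1.
#'
#' @param tree a rooted `phylo` tree with at least 5 leaves.
#' @return list with `delta`, `ci` (95% interval), and logical `negative`.
#' @export
delta_test <- function(tree) {
  if (length(tree$tip.label) < 5) stop("need at least 5 leaves")
  st <- root_to_tip_statistics(tree)
  if (any(st$path_length <= 0) || sd(st$path_length) == 0)
    stop("degenerate path lengths")
  res <- pgls_slope(tree, log(st$path_length), log(st$n_nodes))
  dfree <- nrow(st) - 2
  ci <- res$slope + c(-1, 1) * qt(0.975, dfree) * res$se
  list(delta = res$slope, ci = ci, negative = !(ci[1] > 1))
}

#' Holm-Bonferroni significance flags
#'
#' Standard step-down multiple-testing correction at level `alpha`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param alpha family-wise level (default 0.05).
#' @return logical vector of rejections.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values out of range")
  p.adjust(p, method = "holm") < alpha
}

#' Punctuated-evolution workflow over families
#'
#' For each family with at least `min_taxa` doculects: pick the nearest
#' outgroup by average distance, build (or take) the family tree, root it
#' with the outgroup, screen with the [delta_test()], and regress
#' root-to-tip node counts on path lengths by PGLS.  Evidence for
#' punctuated evolution in a family requires a negative delta-test and a
#' significantly positive slope after Holm-Bonferroni correction across
#' the delta-negative families.
#'
#' @param collection a [wordlist_collection()] (provides the family map).
#' @param dm distance matrix over all doculects.
#' @param trees optional named list of rooted per-family trees; families
#'   without an entry get a BIONJ tree from `dm`, rooted by the outgroup.
#' @param alpha significance level (default 0.05).
#' @param min_taxa minimal family size analyzed (default 10); smaller
#'   families are skipped with a warning.
#' @return data frame `family`, `slope`, `p_value`, `n_taxa`, `delta`,
#'   `delta_negative`, `significant`.
#' @export
punctuation_workflow <- function(collection, dm, trees = NULL, alpha = 0.05,
                                 min_taxa = 10) {
  fam_of <- setNames(collection$doculects$family, collection$doculects$name)
  fams <- unique(fam_of)
  rows <- list()
  for (f in fams) {
    members <- names(fam_of)[fam_of == f]
    if (length(members) < min_taxa) {
      warning("family ", f, " has fewer than ", min_taxa, " taxa; skipped")
      next
    }
    tr <- trees[[f]]
    if (is.null(tr)) {
      o <- nearest_outgroup(dm, members)
      sub <- dm[c(members, o), c(members, o)]
      tr <- root_by_outgroup(bionj_tree(sub), o)
    }
    dt <- tryCatch(delta_test(tr), error = function(e) NULL)
    st <- root_to_tip_statistics(tr)
    reg <- tryCatch(pgls_slope(tr, st$path_length, st$n_nodes),
                    error = function(e) NULL)
    rows[[f]] <- data.frame(
      family = f,
      slope = if (is.null(reg)) NA_real_ else reg$slope,
      p_value = if (is.null(reg)) NA_real_ else reg$p,
      n_taxa = length(members),
      delta = if (is.null(dt)) NA_real_ else dt$delta,
      delta_negative = if (is.null(dt)) NA else dt$negative,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no eligible family")
  rownames(out) <- NULL
  eligible <- !is.na(out$p_value) & !is.na(out$delta_negative) &
    out$delta_negative
  out$significant <- FALSE
  if (any(eligible))
    out$significant[eligible] <- holm_bonferroni(out$p_value[eligible],
                                                 alpha) &
      out$slope[eligible] > 0
  out
}
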