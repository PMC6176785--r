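# Evaluation statistics: B-cubed clustering scores, generalized quartet
# distance, cosine character distances, great-circle distances, Mantel
# test and correlogram.

#' B-cubed precision, recall and F-score
#'
#' Item-averaged B-cubed scores of a predicted partition against a gold
#' partition: for each item, precision is the fraction of its predicted
#' cluster sharing its gold class, recall the fraction of its gold class
#' in its predicted cluster; F is the harmonic mean of the averages.
#' Invariant to cluster relabeling.
#'
#' @param predicted,gold vectors of cluster labels over the same items.
#' @return named numeric vector `precision`, `recall`, `F`.
#' @export
bcubed_scores <- function(predicted, gold) {
  if (length(predicted) == 0) stop("empty item set")
  if (length(predicted) != length(gold)) stop("partitions over different items")
  tab <- table(predicted, gold)
  inter <- tab[cbind(match(predicted, rownames(tab)),
                     match(gold, colnames(tab)))]
  psize <- table(predicted)[predicted]
  gsize <- table(gold)[gold]
  p <- mean(inter / psize)
  r <- mean(inter / gsize)
  c(precision = p, recall = r, F = 2 * p * r / (p + r))
}

# Tip-to-tip topological distance matrix (all edges length 1).
.topo_dist <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  d <- ape::cophenetic.phylo(t2)
  d[t2$tip.label, t2$tip.label]
}

# Quartet resolution by the four-point condition on path lengths:
# 1 = ab|cd, 2 = ac|bd, 3 = ad|bc, 0 = unresolved.  Vectorized over a
# 4-column index matrix.
.quartet_res <- function(d, q) {
  s1 <- d[q[, c(1, 2)]] + d[q[, c(3, 4)]]
  s2 <- d[q[, c(1, 3)]] + d[q[, c(2, 4)]]
  s3 <- d[q[, c(1, 4)]] + d[q[, c(2, 3)]]
  res <- integer(nrow(q))
  m <- pmin(s1, s2, s3)
  n_min <- (abs(s1 - m) < 1e-9) + (abs(s2 - m) < 1e-9) + (abs(s3 - m) < 1e-9)
  one <- n_min == 1
  res[one & abs(s1 - m) < 1e-9] <- 1L
  res[one & abs(s2 - m) < 1e-9] <- 2L
  res[one & abs(s3 - m) < 1e-9] <- 3L
  res
}

#' Generalized quartet distance
#'
#' The fraction of four-taxon subsets resolved by the reference tree whose
#' resolution differs in the candidate tree.  Quartets the (possibly
#' non-binary) reference leaves unresolved are not counted; a quartet the
#' candidate leaves unresolved counts as differing.  Both trees are first
#' restricted to their shared taxa.
#'
#' @param tree candidate `phylo` tree.
#' @param reference reference (expert) `phylo` tree; may contain
#'   polytomies.
#' @param mode `"exact"` enumerates all quartets, `"sampled"` estimates
#'   from a random sample, `"auto"` (default) picks exact up to 30 taxa.
#' @param n_samples quartets sampled in sampled mode (default 1e5).
#' @param seed integer seed for sampled mode.
#' @return GQD in \[0, 1\].
#' @export
generalized_quartet_distance <- function(tree, reference,
                                         mode = c("auto", "exact", "sampled"),
                                         n_samples = 1e5, seed = 1) {
  mode <- match.arg(mode)
  shared <- intersect(tree$tip.label, reference$tip.label)
  if (length(shared) < 4) stop("need at least 4 shared taxa")
  prune <- function(tr) ape::keep.tip(tr, shared)
  d1 <- .topo_dist(prune(tree))[shared, shared]
  d2 <- .topo_dist(prune(reference))[shared, shared]
  n <- length(shared)
  if (mode == "auto") mode <- if (n <= 30) "exact" else "sampled"
  if (mode == "exact") {
    q <- t(combn(n, 4))
  } else {
    set.seed(seed)
    q <- t(replicate(n_samples, sample.int(n, 4)))
    q <- t(apply(q, 1, sort))
  }
  r_ref <- .quartet_res(d2, q)
  resolved <- r_ref != 0L
  if (!any(resolved)) stop("reference resolves no sampled quartet")
  r_tree <- .quartet_res(d1, q[resolved, , drop = FALSE])
  mean(r_tree != r_ref[resolved])
}

#' Cosine distance between character vectors
#'
#' One minus the cosine similarity over the coordinates where both vectors
#' are defined; undefined coordinates never affect the value.
#'
#' @param v1,v2 numeric vectors over \{0, 1, NA\}.
#' @return distance in \[0, 1\] for non-negative vectors.
#' @export
cosine_character_distance <- function(v1, v2) {
  ok <- !is.na(v1) & !is.na(v2)
  if (!any(ok)) stop("no jointly defined character")
  a <- v1[ok]; b <- v2[ok]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero vector after masking")
  1 - sum(a * b) / (na * nb)
}

#' Pairwise cosine character distance matrix
#'
#' @param m character matrix (taxa in rows).
#' @return symmetric distance matrix.
#' @export
character_distance_matrix <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      out[i, j] <- out[j, i] <- cosine_character_distance(m[i, ], m[j, ])
  out
}

#' Great-circle distance
#'
#' Spherical (haversine) distance with mean Earth radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return distance in kilometers.
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 360))
    stop("coordinates out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Geographic distance matrix of a collection
#'
#' @param collection a [wordlist_collection()] with coordinates.
#' @return symmetric matrix of great-circle distances (km).
#' @export
geo_distance_matrix <- function(collection) {
  d <- collection$doculects
  if (anyNA(d$latitude) || anyNA(d$longitude))
    stop("collection has doculects without coordinates")
  n <- nrow(d)
  out <- matrix(0, n, n, dimnames = list(d$name, d$name))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    v <- great_circle_distance(d$latitude[i], d$longitude[i],
                               d$latitude[j], d$longitude[j])
    out[i, j] <- out[j, i] <- v
  }
  out
}

#' Mantel test
#'
#' Permutation Mantel test of the correlation between two distance
#' matrices over the same taxa, with
#' `p = (1 + #\{r_perm >= r\}) / (1 + n_perm)`.
#'
#' @param dm1,dm2 symmetric distance matrices over the same taxa.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `r` and `p`.
#' @export
mantel_test <- function(dm1, dm2, method = c("spearman", "pearson"),
                        n_perm = 999, seed = 1) {
  method <- match.arg(method)
  if (!identical(rownames(dm1), rownames(dm2)))
    stop("matrices must share taxa (same order)")
  set.seed(seed)
  res <- vegan::mantel(stats::as.dist(dm1), stats::as.dist(dm2),
                       method = method, permutations = n_perm)
  list(r = unname(res$statistic), p = unname(res$signif))
}

#' Mantel correlogram
#'
#' Per geographic distance class, the Mantel statistic between the
#' linguistic distances and the class-membership indicator, with
#' permutation p-values.  The statistic is oriented so that a positive
#' value in a class means pairs in that class are linguistically more
#' similar than average (positive spatial autocorrelation at short range).
#'
#' @param dm_ling linguistic distance matrix.
#' @param dm_geo geographic distance matrix (km), same taxa.
#' @param bin_edges class break points in km (default 1000-km bins up to
#'   the observed maximum).
#' @param n_perm permutations per class (default 999).
#' @param seed integer seed.
#' @param holm apply Holm correction across classes before flagging
#'   significance (default `FALSE`).
#' @param alpha significance level for the flag (default 0.05).
#' @return data frame with per-bin `midpoint` (km), `n_pairs`, `r`, `p`,
#'   and logical `significant`.
#' @export
mantel_correlogram <- function(dm_ling, dm_geo, bin_edges = NULL,
                               n_perm = 999, seed = 1, holm = FALSE,
                               alpha = 0.05) {
  if (!identical(rownames(dm_ling), rownames(dm_geo)))
    stop("matrices must share taxa (same order)")
  if (is.null(bin_edges))
    bin_edges <- seq(0, max(dm_geo), by = 1000)
  if (max(bin_edges) < max(dm_geo))
    bin_edges <- c(bin_edges, max(dm_geo))
  set.seed(seed)
  res <- vegan::mantel.correlog(stats::as.dist(dm_ling),
                                stats::as.dist(dm_geo),
                                break.pts = bin_edges, nperm = n_perm,
                                cutoff = FALSE, mult = "holm",
                                progressive = FALSE)
  m <- as.data.frame(res$mantel.res)
  p <- if (holm) m[["Pr(corrected)"]] else m[["Pr(Mantel)"]]
  skipped <- m[["n.dist"]] == 0 | is.na(m[["Mantel.cor"]])
  if (any(skipped)) warning(sum(skipped), " empty bin(s) skipped")
  out <- data.frame(midpoint = m[["class.index"]],
                    n_pairs = m[["n.dist"]] / 2,
                    r = m[["Mantel.cor"]],
                    p = p,
                    significant = !is.na(p) & p < alpha)
  out[!skipped, , drop = FALSE]
}
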