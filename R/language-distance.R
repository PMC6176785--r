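# Calibrated pairwise language distances.
#
# Word-level similarities are aggregated per concept (max over the synonym
# cross-product), calibrated against the cross-concept (presumed
# non-cognate) score distribution into per-concept p-values, combined
# Fisher-style into a Z statistic, and rescaled to [0, 1] with the two
# closed-form bounds.

# A scorer maps two per-doculect views (list(concept, word, enc)) to the
# word-by-word similarity matrix.
pmi_scorer <- function(model) {
  function(lw1, lw2)
    cpp_pmi_score_matrix(lw1$enc, lw2$enc, model$pmi,
                         model$gap_open, model$gap_extend)
}

ldn_scorer <- function() {
  function(lw1, lw2) ldn_sim_matrix(lw1$word, lw2$word)
}

as_scorer <- function(sim) {
  if (inherits(sim, "scoring_model")) return(pmi_scorer(sim))
  if (is.function(sim)) return(sim)
  if (identical(sim, "ldn")) return(ldn_scorer())
  stop("sim must be a scoring_model, a function, or \"ldn\"")
}

# Concept-level similarity matrix and derived statistics for one doculect
# pair.  Returns NULL if the pair shares no concept.
pair_statistics <- function(collection, l1, l2, sim,
                            keep_word_matrix = FALSE) {
  scorer <- as_scorer(sim)
  lw1 <- lang_words(collection, l1)
  lw2 <- lang_words(collection, l2)
  if (length(lw1$word) == 0 || length(lw2$word) == 0)
    stop("doculect without entries")
  c1 <- sort(unique(lw1$concept)); c2 <- sort(unique(lw2$concept))
  g1 <- match(lw1$concept, c1); g2 <- match(lw2$concept, c2)
  wm <- scorer(lw1, lw2)
  S <- cpp_group_max(wm, g1, g2, length(c1), length(c2))
  dimnames(S) <- list(c1, c2)
  shared <- intersect(c1, c2)
  null_mask <- outer(c1, c2, "!=")
  null <- S[null_mask]
  p <- NULL
  z <- NA_real_
  if (length(shared) > 0 && length(null) > 0) {
    syn <- S[cbind(match(shared, c1), match(shared, c2))]
    p <- setNames(vapply(syn, function(s)
      (1 + sum(null >= s)) / (1 + length(null)), numeric(1)), shared)
    n <- length(shared)
    z <- (sum(-log(p)) - n) / sqrt(n)
  }
  out <- list(S = S, concepts1 = c1, concepts2 = c2, shared = shared,
              null = null, p = p, z = z, n_shared = length(shared))
  if (keep_word_matrix) {
    out$word_matrix <- wm
    out$lw1 <- lw1
    out$lw2 <- lw2
  }
  out
}

#' Concept-level similarity between two doculects
#'
#' The maximal similarity between any pair of entries for concept `concept`
#' (max over the synonym cross-product).  The similarity is pluggable: a
#' [scoring_model()] for PMI alignment scores, or `"ldn"` for the 1-LDN
#' bootstrap similarity.
#'
#' @param collection a [wordlist_collection()].
#' @param l1,l2 doculect names.
#' @param concept concept name; both doculects must have an entry for it.
#' @param sim similarity: a [scoring_model()], `"ldn"`, or a function.
#' @return a single similarity score.
#' @export
concept_similarity <- function(collection, l1, l2, concept, sim) {
  scorer <- as_scorer(sim)
  w1 <- lang_words(collection, l1, concept)
  w2 <- lang_words(collection, l2, concept)
  if (length(w1$word) == 0 || length(w2$word) == 0)
    stop("concept '", concept, "' undefined for this pair")
  max(scorer(w1, w2))
}

#' Cross-concept null similarity sample
#'
#' One max-over-synonyms similarity score per ordered concept pair
#' (c1, c2), c1 != c2, with c1 among the first doculect's defined concepts
#' and c2 among the second's.  Under the assumption that cognates share
#' their meaning, this samples the similarity distribution of non-cognate
#' word pairs for this doculect pair.
#'
#' @inheritParams concept_similarity
#' @return numeric vector of null scores.
#' @export
null_similarity_sample <- function(collection, l1, l2, sim) {
  st <- pair_statistics(collection, l1, l2, sim)
  if (length(st$null) < 2) stop("fewer than 2 cross-concept pairs")
  st$null
}

#' Calibrated per-concept p-value
#'
#' Maximum-likelihood estimate of the p-value for the null hypothesis that
#' the words compared for a concept are non-cognate: the relative rank of
#' the synonymous score within the null sample, with the synonymous pair
#' itself included in numerator and denominator, so
#' `p = (1 + #\{null >= score\}) / (1 + #null)`.
#'
#' @param score synonymous similarity score for the concept.
#' @param null numeric vector of cross-concept null scores.
#' @return p-value in (0, 1\].
#' @export
calibrated_p <- function(score, null) {
  if (length(null) == 0) stop("empty null sample")
  (1 + sum(null >= score)) / (1 + length(null))
}

#' Combined language similarity Z statistic
#'
#' Fisher-style combination of the per-concept calibrated p-values over the
#' N concepts shared by the two doculects, normalized to a Z score:
#' `Z = (sum(-log p_c) - N) / sqrt(N)`.
#'
#' @inheritParams concept_similarity
#' @return the Z statistic.
#' @export
language_z <- function(collection, l1, l2, sim) {
  st <- pair_statistics(collection, l1, l2, sim)
  if (st$n_shared == 0) stop("no shared concepts")
  if (length(st$null) == 0) stop("empty null sample")
  st$z
}

#' Bounds of the Z statistic for complete word lists
#'
#' Closed-form maximal and minimal attainable Z for two complete lists of
#' `n_concepts` concepts: the maximum is reached when every synonymous pair
#' outscores all cross-concept pairs (every `p_c` at its minimum
#' `1 / (n^2 - n + 1)`), the minimum when all `p_c` equal 1.
#'
#' @param n_concepts word-list length (default 40).
#' @return list with `z_max` and `z_min`.
#' @examples
#' z_constants()  # z_max ~ 40.18, z_min ~ -6.32
#' @export
z_constants <- function(n_concepts = 40) {
  n <- n_concepts
  list(z_max = (n * log(n^2 - n + 1) - n) / sqrt(n),
       z_min = -n / sqrt(n))
}

#' Calibrated language distance
#'
#' Rescales the Z statistic into a dissimilarity in \[0, 1\]:
#' `d = (z_max - Z) / (z_max - z_min)`, with the bounds always computed for
#' complete 40-concept lists (the `sqrt(N)` normalization inside Z already
#' accounts for incomplete lists).  Not a metric.
#'
#' @inheritParams concept_similarity
#' @return distance value.
#' @export
language_distance <- function(collection, l1, l2, sim) {
  z_to_distance(language_z(collection, l1, l2, sim))
}

z_to_distance <- function(z, n_concepts = 40) {
  zc <- z_constants(n_concepts)
  (zc$z_max - z) / (zc$z_max - zc$z_min)
}

#' Full pairwise distance matrix
#'
#' Computes the calibrated distance for every unordered doculect pair.
#' Pairs without shared concepts are left `NA` (undefined), never zeroed.
#'
#' @param collection a [wordlist_collection()].
#' @param sim similarity: a [scoring_model()], `"ldn"`, or a function.
#' @return symmetric numeric matrix with doculect names as dimnames and a
#'   zero diagonal.
#' @export
distance_matrix <- function(collection, sim) {
  taxa <- doculect_names(collection)
  n <- length(taxa)
  if (n < 2) stop("need at least 2 doculects")
  m <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      st <- pair_statistics(collection, taxa[i], taxa[j], sim)
      d <- if (st$n_shared == 0 || length(st$null) == 0) NA_real_
           else z_to_distance(st$z)
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}

# Mean distance over a given set of unordered pairs (training objective).
mean_pair_distance <- function(collection, pairs, sim) {
  d <- vapply(seq_len(nrow(pairs)), function(k) {
    st <- pair_statistics(collection, pairs$l1[k], pairs$l2[k], sim)
    if (st$n_shared == 0 || length(st$null) == 0) NA_real_
    else z_to_distance(st$z)
  }, numeric(1))
  mean(d, na.rm = TRUE)
}

#' Write / read a distance matrix
#'
#' `write_nexus_distances` emits a Nexus `DISTANCES` block
#' (`triangle=both`), `read_nexus_distances` parses it back;
#' `write_distances_csv` writes plain CSV.  Taxon labels are used as is;
#' see `taxon_labels` conventions in the package vignette.
#'
#' @param dm symmetric distance matrix with dimnames.
#' @param path output file.
#' @export
write_nexus_distances <- function(dm, path) {
  taxa <- rownames(dm)
  rows <- vapply(seq_along(taxa), function(i)
    paste(taxa[i], paste(sprintf("%.10g", dm[i, ]), collapse = " ")),
    character(1))
  writeLines(c("#NEXUS", "", "BEGIN distances;",
               sprintf("DIMENSIONS ntax=%d;", length(taxa)),
               "FORMAT triangle=both labels=left;",
               "MATRIX", rows, ";", "END;"), path)
  invisible(path)
}

#' @rdname write_nexus_distances
#' @export
read_nexus_distances <- function(path) {
  ln <- readLines(path)
  i0 <- grep("^MATRIX$", ln)[1]
  i1 <- grep("^;$", ln)
  i1 <- i1[i1 > i0][1]
  rows <- ln[(i0 + 1):(i1 - 1)]
  parts <- strsplit(trimws(rows), "\\s+")
  taxa <- vapply(parts, `[`, character(1), 1)
  m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(length(taxa))))
  dimnames(m) <- list(taxa, taxa)
  m
}

#' @rdname write_nexus_distances
#' @export
write_distances_csv <- function(dm, path) {
  write.csv(dm, path)
  invisible(path)
}
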