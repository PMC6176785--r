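# Learning the PMI scoring model from a word-list collection:
# LDN bootstrap -> probable-relatedness screen -> potential cognates ->
# iterative score re-estimation -> Nelder-Mead over the gap penalties and
# the cognacy threshold.

#' Probably related doculect pairs
#'
#' Screens all unordered doculect pairs with the calibrated language
#' distance computed from the 1-LDN bootstrap similarity; pairs at distance
#' `threshold` or less are considered probably related and are the training
#' material for score estimation.
#'
#' @param collection a [wordlist_collection()].
#' @param threshold distance cutoff (default 0.7, a conservative screen).
#' @return data frame with columns `l1`, `l2`, `distance` (unordered pairs).
#' @export
probably_related_pairs <- function(collection, threshold = 0.7) {
  dm <- distance_matrix(collection, "ldn")
  taxa <- rownames(dm)
  idx <- which(upper.tri(dm) & !is.na(dm) & dm <= threshold, arr.ind = TRUE)
  data.frame(l1 = taxa[idx[, 1]], l2 = taxa[idx[, 2]],
             distance = dm[idx], stringsAsFactors = FALSE)
}

#' Potential cognate pairs
#'
#' For each probably related doculect pair and each concept both have an
#' entry for, the synonym pair with the lowest normalized Levenshtein
#' distance (ties broken by synonym input order, first pair wins).
#'
#' @param collection a [wordlist_collection()].
#' @param related data frame of related pairs as returned by
#'   [probably_related_pairs()].
#' @return data frame with columns `l1`, `l2`, `concept`, `w1`, `w2` and a
#'   `pairs_enc` attribute holding the integer encodings.
#' @export
potential_cognate_pairs <- function(collection, related) {
  if (nrow(related) == 0) stop("no related pairs")
  rows <- vector("list", nrow(related))
  for (k in seq_len(nrow(related))) {
    l1 <- related$l1[k]; l2 <- related$l2[k]
    lw1 <- lang_words(collection, l1); lw2 <- lang_words(collection, l2)
    shared <- intersect(unique(lw1$concept), unique(lw2$concept))
    if (length(shared) == 0) next
    per_concept <- lapply(shared, function(cc) {
      i1 <- which(lw1$concept == cc); i2 <- which(lw2$concept == cc)
      d <- utils::adist(lw1$word[i1], lw2$word[i2]) /
        outer(nchar(lw1$word[i1]), nchar(lw2$word[i2]), pmax)
      best <- which(d == min(d), arr.ind = TRUE)
      best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
      data.frame(l1 = l1, l2 = l2, concept = cc,
                 w1 = lw1$word[i1[best[1]]], w2 = lw2$word[i2[best[2]]],
                 stringsAsFactors = FALSE)
    })
    rows[[k]] <- do.call(rbind, per_concept)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Encode the word columns once for the C++ kernels.
encode_pairs <- function(pairs, inventory) {
  list(x = lapply(pairs$w1, encode_word, inventory = inventory),
       y = lapply(pairs$w2, encode_word, inventory = inventory))
}

# Add-k smoothed occurrence probabilities used inside score estimation
# (raw relative frequencies would give -Inf scores for unseen symbols).
smoothed_q <- function(collection, k = 0.5) {
  counts <- symbol_counts(collection)
  (counts + k) / (sum(counts) + k * length(counts))
}

# Symmetrized, smoothed PMI table from an aligned-pair count matrix.
pmi_from_counts <- function(counts, q, k = 0.5) {
  cs <- counts + t(counts)
  s <- (cs + k) / sum(cs + k)
  log(s / outer(q, q))
}

#' Initial PMI estimate from Levenshtein alignments
#'
#' Aligns all potential cognate pairs with the (unit-cost) Levenshtein
#' algorithm, counts aligned symbol pairs (gap columns excluded), pools the
#' counts symmetrically, applies add-k smoothing, and converts to
#' log-odds scores `PMI(a, b) = log(s(a, b) / (q(a) q(b)))`.
#'
#' @param collection a [wordlist_collection()].
#' @param pairs potential cognate pairs ([potential_cognate_pairs()]).
#' @param k add-k smoothing constant for the aligned-pair counts and the
#'   occurrence probabilities (default 0.5).
#' @return the PMI score matrix.
#' @export
estimate_initial_pmi <- function(collection, pairs, k = 0.5) {
  if (is.null(pairs) || nrow(pairs) == 0) stop("no potential cognate pairs")
  inv <- collection$inventory
  enc <- encode_pairs(pairs, inv)
  counts <- cpp_lev_align_counts(enc$x, enc$y, length(inv$symbols))
  pmi <- pmi_from_counts(counts, smoothed_q(collection, k), k)
  dimnames(pmi) <- list(inv$symbols, inv$symbols)
  pmi
}

#' Iterative PMI re-estimation
#'
#' Runs the fixed 10-round refinement: in round i all potential cognate
#' pairs are re-aligned with the round i-1 scores and the given gap
#' penalties; pairs whose alignment score reaches `theta` contribute their
#' aligned (non-gap) symbol columns to the counts from which the round-i
#' scores are computed.
#'
#' @inheritParams estimate_initial_pmi
#' @param gap_open,gap_extend gap penalties.
#' @param theta cognacy threshold for retaining a pair in the counts.
#' @param iterations number of re-estimation rounds (default 10).
#' @param initial_pmi optional starting score table (defaults to
#'   [estimate_initial_pmi()]).
#' @return a [scoring_model()]; the number of retained pairs per round is
#'   attached as attribute `n_kept`.
#' @export
refine_pmi <- function(collection, pairs, gap_open, gap_extend, theta,
                       iterations = 10, k = 0.5, initial_pmi = NULL) {
  inv <- collection$inventory
  if (is.null(initial_pmi))
    initial_pmi <- estimate_initial_pmi(collection, pairs, k)
  enc <- encode_pairs(pairs, inv)
  q <- smoothed_q(collection, k)
  pmi <- initial_pmi
  kept <- integer(iterations)
  for (i in seq_len(iterations)) {
    res <- cpp_pmi_align_counts(enc$x, enc$y, pmi, gap_open, gap_extend,
                                theta, length(inv$symbols))
    if (res$n_kept == 0)
      stop("no potential cognate pair reaches theta = ", theta,
           "; threshold too high for these data")
    kept[i] <- res$n_kept
    pmi <- pmi_from_counts(res$counts, q, k)
    dimnames(pmi) <- list(inv$symbols, inv$symbols)
  }
  m <- scoring_model(pmi, gap_open, gap_extend, theta, inv)
  attr(m, "n_kept") <- kept
  m
}

#' Nelder-Mead search over gap penalties and threshold
#'
#' Minimizes the mean calibrated distance between all probably related
#' doculect pairs, where distances are computed with the refined
#' (10-round) scores for the candidate `(gap_open, gap_extend, theta)`.
#' The related-pair screen and the potential cognates are computed once
#' from the LDN bootstrap and kept fixed during the search.
#'
#' @param collection a [wordlist_collection()].
#' @param init numeric vector `c(gap_open, gap_extend, theta)` used as the
#'   optimizer start (default `c(-2.5, -1.75, 4.5)`).
#' @param related optional precomputed [probably_related_pairs()].
#' @param pairs optional precomputed [potential_cognate_pairs()].
#' @param iterations re-estimation rounds per objective evaluation.
#' @param max_eval objective evaluation budget; if exceeded, the best
#'   parameters found so far are returned with a warning.
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param k smoothing constant, see [estimate_initial_pmi()].
#' @return a list with the optimized `model` ([scoring_model()]), the
#'   parameters `par`, the objective `value`, and the evaluation `trace`.
#' @export
optimize_hyperparameters <- function(collection, init = c(-2.5, -1.75, 4.5),
                                     related = NULL, pairs = NULL,
                                     iterations = 10, max_eval = 200,
                                     reltol = 1e-3, k = 0.5) {
  if (is.null(related)) related <- probably_related_pairs(collection)
  if (nrow(related) == 0) stop("no probably related pairs")
  if (is.null(pairs)) pairs <- potential_cognate_pairs(collection, related)
  init_pmi <- estimate_initial_pmi(collection, pairs, k)

  trace <- list()
  best <- list(value = Inf, par = init)
  n_eval <- 0L
  objective <- function(par) {
    if (n_eval >= max_eval) stop(structure(class = c("budget_exceeded",
                                                     "error", "condition"),
                                           list(message = "budget", call = NULL)))
    n_eval <<- n_eval + 1L
    if (par[1] > 0 || par[2] > 0) return(10)
    val <- tryCatch({
      model <- refine_pmi(collection, pairs, par[1], par[2], par[3],
                          iterations = iterations, k = k,
                          initial_pmi = init_pmi)
      mean_pair_distance(collection, related, model)
    }, budget_exceeded = function(e) stop(e),
       error = function(e) 10)
    trace[[length(trace) + 1L]] <<- c(par, f = val)
    if (val < best$value) best <<- list(value = val, par = par)
    val
  }
  res <- tryCatch(
    optim(init, objective, method = "Nelder-Mead",
          control = list(reltol = reltol, maxit = max_eval)),
    budget_exceeded = function(e) {
      warning("optimizer exceeded evaluation budget; returning best so far")
      list(par = best$par, value = best$value)
    })
  par <- res$par
  model <- refine_pmi(collection, pairs, par[1], par[2], par[3],
                      iterations = iterations, k = k, initial_pmi = init_pmi)
  list(model = model, par = setNames(par, c("gap_open", "gap_extend", "theta")),
       value = res$value, trace = do.call(rbind, trace),
       related = related, pairs = pairs)
}

#' Train a scoring model end to end
#'
#' Convenience wrapper: LDN bootstrap screen, potential cognates, initial
#' estimate, and either the full Nelder-Mead search (`optimize = TRUE`) or
#' a single 10-round refinement at `init`.
#'
#' @inheritParams optimize_hyperparameters
#' @param optimize run the hyperparameter search (default `TRUE`).
#' @return a [scoring_model()] (with the search summary attached as
#'   attribute `training` when `optimize = TRUE`).
#' @export
train_pmi_model <- function(collection, init = c(-2.5, -1.75, 4.5),
                            optimize = TRUE, iterations = 10,
                            max_eval = 200, reltol = 1e-3, k = 0.5) {
  related <- probably_related_pairs(collection)
  if (nrow(related) == 0) stop("no probably related pairs")
  pairs <- potential_cognate_pairs(collection, related)
  if (!optimize) {
    return(refine_pmi(collection, pairs, init[1], init[2], init[3],
                      iterations = iterations, k = k))
  }
  res <- optimize_hyperparameters(collection, init, related = related,
                                  pairs = pairs, iterations = iterations,
                                  max_eval = max_eval, reltol = reltol, k = k)
  model <- res$model
  attr(model, "training") <- res[c("par", "value", "trace")]
  model
}
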