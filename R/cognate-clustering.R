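# Supervised cognate detection: per-word-pair features, an RBF-kernel SVM
# with Platt-scaled probabilities, label-propagation clustering per
# concept, and exhaustive feature-subset model selection.

FEATURE_NAMES <- c("f1", "f2", "f3", "f4", "f5", "f6", "f7")

# Per-concept average word length across the whole collection.
.avg_word_length <- function(collection) {
  tapply(nchar(collection$entries$transcription),
         collection$entries$concept, mean)
}

#' Word-pair feature table
#'
#' Computes, for every synonymous cross-doculect word pair (or a supplied
#' subset of doculect pairs), the seven classifier features:
#' `f1` PMI alignment similarity; `f2` the calibrated p-value of `f1`
#' against the language pair's cross-concept null sample; `f3 = -log f2`;
#' `f4` the calibrated language distance d; `f5 = -log(1 - d)` (d capped
#' at 1 - 1e-9); `f6` the concept's average word length over the whole
#' collection; `f7` the per-concept Pearson correlation between `f3` and
#' `f4` over all word pairs of that concept.
#'
#' @param collection a [wordlist_collection()].
#' @param model a [scoring_model()].
#' @param doculect_pairs optional data frame with columns `l1`, `l2`
#'   restricting the doculect pairs (default: all unordered pairs).
#' @return data frame with identification columns (`l1`, `l2`, `concept`,
#'   `w1`, `w2`, `i1`, `i2` — entry row indices) and `f1` ... `f7`.
#' @export
pair_feature_table <- function(collection, model, doculect_pairs = NULL) {
  taxa <- doculect_names(collection)
  if (is.null(doculect_pairs)) {
    idx <- which(upper.tri(diag(length(taxa))), arr.ind = TRUE)
    doculect_pairs <- data.frame(l1 = taxa[idx[, 1]], l2 = taxa[idx[, 2]],
                                 stringsAsFactors = FALSE)
  }
  f6_tab <- .avg_word_length(collection)
  entry_key <- paste(collection$entries$doculect, collection$entries$concept,
                     collection$entries$transcription)
  rows <- vector("list", nrow(doculect_pairs))
  for (k in seq_len(nrow(doculect_pairs))) {
    l1 <- doculect_pairs$l1[k]; l2 <- doculect_pairs$l2[k]
    st <- pair_statistics(collection, l1, l2, model, keep_word_matrix = TRUE)
    if (st$n_shared == 0 || length(st$null) == 0) next
    d <- z_to_distance(st$z)
    M <- length(st$null)
    nullv <- sort(st$null)
    lw1 <- st$lw1; lw2 <- st$lw2
    pair_idx <- which(outer(lw1$concept, lw2$concept, "=="), arr.ind = TRUE)
    if (nrow(pair_idx) == 0) next
    f1 <- st$word_matrix[pair_idx]
    # right tail count via sorted null sample
    ge <- M - findInterval(f1 - 1e-12, nullv)
    f2 <- (1 + ge) / (1 + M)
    cc <- lw1$concept[pair_idx[, 1]]
    rows[[k]] <- data.frame(
      l1 = l1, l2 = l2, concept = cc,
      w1 = lw1$word[pair_idx[, 1]], w2 = lw2$word[pair_idx[, 2]],
      i1 = match(paste(l1, cc, lw1$word[pair_idx[, 1]]), entry_key),
      i2 = match(paste(l2, cc, lw2$word[pair_idx[, 2]]), entry_key),
      f1 = f1, f2 = f2, f3 = -log(f2),
      f4 = d, f5 = -log(1 - pmin(d, 1 - 1e-9)),
      f6 = as.numeric(f6_tab[cc]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no comparable word pairs")
  rownames(out) <- NULL
  # f7: concept-language correlation, computed once per concept
  f7_tab <- tapply(seq_len(nrow(out)), out$concept, function(i) {
    if (length(i) < 2 || sd(out$f3[i]) == 0 || sd(out$f4[i]) == 0) return(0)
    cor(out$f3[i], out$f4[i])
  })
  out$f7 <- as.numeric(f7_tab[out$concept])
  out
}

#' Features of a single word pair
#'
#' Single-pair convenience wrapper around [pair_feature_table()].
#'
#' @inheritParams pair_feature_table
#' @param w1,w2 words (normalized transcriptions) for `concept` in
#'   doculects `l1`, `l2`.
#' @param l1,l2 doculect names (must differ).
#' @param concept shared concept.
#' @return one-row data frame of features `f1` ... `f7`.
#' @export
compute_pair_features <- function(collection, model, w1, w2, l1, l2, concept) {
  if (l1 == l2) stop("word pairs must come from different doculects")
  tab <- pair_feature_table(collection, model,
                            data.frame(l1 = l1, l2 = l2))
  row <- tab[tab$concept == concept & tab$w1 == w1 & tab$w2 == w2, ]
  if (nrow(row) == 0) stop("word pair not found in the collection")
  row[1, FEATURE_NAMES]
}

#' Train the cognacy classifier
#'
#' Fits a support-vector machine with RBF kernel on (a sample of) labeled
#' synonymous word pairs and calibrates its margins into probabilities by
#' Platt scaling.  Features are standardized on the training sample.
#'
#' @param features data frame or matrix containing the feature columns.
#' @param labels logical (or 0/1) cognacy labels, one per row.
#' @param subset character vector of feature columns to use (default the
#'   two-feature model `c("f3", "f5")`: word similarity and language
#'   log-distance).
#' @param n_train number of training pairs sampled at random (default
#'   7000; all rows if fewer).
#' @param seed integer seed (sampling and calibration).
#' @return object of class `cognacy_classifier`.
#' @export
train_cognacy_classifier <- function(features, labels, subset = c("f3", "f5"),
                                     n_train = 7000, seed = 1) {
  x <- as.data.frame(features)[, subset, drop = FALSE]
  y <- factor(as.logical(labels), levels = c(FALSE, TRUE))
  set.seed(seed)
  if (nrow(x) > n_train) {
    pick <- sample.int(nrow(x), n_train)
    x <- x[pick, , drop = FALSE]; y <- y[pick]
  }
  if (length(unique(y)) < 2)
    stop("training sample contains a single class")
  fit <- e1071::svm(x = x, y = y, kernel = "radial", probability = TRUE,
                    scale = TRUE)
  structure(list(fit = fit, subset = subset,
                 cost = fit$cost, gamma = fit$gamma),
            class = "cognacy_classifier")
}

#' @export
print.cognacy_classifier <- function(x, ...) {
  cat("Cognacy classifier (RBF SVM + Platt scaling)\n")
  cat("  features:", paste(x$subset, collapse = ", "),
      sprintf(" cost = %g, gamma = %g\n", x$cost, x$gamma))
  invisible(x)
}

#' Predict probability of cognacy
#'
#' @param classifier a [train_cognacy_classifier()] fit.
#' @param features data frame containing the classifier's feature columns.
#' @return numeric vector of cognacy probabilities in \[0, 1\].
#' @export
predict_cognacy <- function(classifier, features) {
  x <- as.data.frame(features)[, classifier$subset, drop = FALSE]
  pr <- predict(classifier$fit, x, probability = TRUE)
  attr(pr, "probabilities")[, "TRUE"]
}

#' Label propagation partition
#'
#' Community detection by label propagation on an undirected graph:
#' labels start unique; nodes are visited in random order and adopt the
#' majority label among their neighbors, ties broken uniformly at random;
#' sweeps repeat until no label changes (at most `max_sweeps`).
#' Deterministic under `seed`.
#'
#' @param adjacency logical (or 0/1) symmetric adjacency matrix.
#' @param seed integer seed.
#' @param max_sweeps sweep budget (default 100).
#' @return integer vector of cluster ids (1-based, dense).
#' @export
label_propagation <- function(adjacency, seed = 1, max_sweeps = 100) {
  a <- adjacency
  n <- nrow(a)
  if (n == 0) return(integer(0))
  diag(a) <- FALSE
  labels <- seq_len(n)
  set.seed(seed)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (v in sample.int(n)) {
      nb <- which(a[v, ] != 0)
      if (length(nb) == 0) next
      tab <- table(labels[nb])
      cands <- as.integer(names(tab)[tab == max(tab)])
      if (!(labels[v] %in% cands)) {
        labels[v] <- if (length(cands) == 1) cands else sample(cands, 1)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(labels, unique(labels))
}

#' Cluster the words of one concept
#'
#' Builds the cognacy graph (edge iff predicted probability >= `threshold`)
#' and partitions it with [label_propagation()].
#'
#' @param probabilities symmetric matrix of pairwise cognacy
#'   probabilities for the concept's words (NA = no prediction, treated
#'   as no edge).
#' @param threshold edge threshold (default 0.25).
#' @param seed integer seed.
#' @return integer vector of cluster ids, one per word.
#' @export
cluster_words <- function(probabilities, threshold = 0.25, seed = 1) {
  adj <- !is.na(probabilities) & probabilities >= threshold
  label_propagation(adj, seed = seed)
}

#' Cluster a whole collection into cognate classes
#'
#' Computes features for all synonymous cross-doculect pairs, predicts
#' cognacy probabilities, and clusters each concept's words independently.
#' Labels follow the `concept_serial` convention (e.g. `dog_3`).
#'
#' @param collection a [wordlist_collection()].
#' @param model a [scoring_model()].
#' @param classifier a [train_cognacy_classifier()] fit.
#' @param threshold edge threshold (default 0.25).
#' @param seed integer seed.
#' @return data frame `doculect`, `concept`, `word`, `class`: one row per
#'   word token of the collection.
#' @export
cluster_collection <- function(collection, model, classifier,
                               threshold = 0.25, seed = 1) {
  feats <- pair_feature_table(collection, model)
  feats$prob <- predict_cognacy(classifier, feats)
  ent <- collection$entries
  out_class <- character(nrow(ent))
  for (cc in unique(ent$concept)) {
    items <- which(ent$concept == cc)
    pm <- matrix(NA_real_, length(items), length(items))
    rows <- feats[feats$concept == cc, ]
    if (nrow(rows) > 0) {
      a <- match(rows$i1, items); b <- match(rows$i2, items)
      pm[cbind(a, b)] <- rows$prob
      pm[cbind(b, a)] <- rows$prob
    }
    part <- cluster_words(pm, threshold = threshold, seed = seed)
    out_class[items] <- paste0(cc, "_", part)
  }
  data.frame(doculect = ent$doculect, concept = ent$concept,
             word = ent$transcription, class = out_class,
             stringsAsFactors = FALSE)
}

#' Build a labeled pair table from gold-standard data
#'
#' Converts expert cognate judgments (one row per word with its class)
#' into the pair table used for training and model selection.  Pairs of
#' words from different families are labeled non-cognate.
#'
#' @param gold data frame with columns `doculect`, `family`, `concept`,
#'   `transcription`, `cognate_class`.
#' @param model a [scoring_model()].
#' @param collection optional prebuilt [wordlist_collection()] matching
#'   `gold` (constructed from `gold` if omitted).
#' @return pair table as from [pair_feature_table()] with added columns
#'   `family1`, `family2`, `class1`, `class2`, and logical `label`.
#' @export
gold_pair_table <- function(gold, model, collection = NULL) {
  if (is.null(collection)) {
    first <- !duplicated(gold$doculect)
    doculects <- data.frame(name = gold$doculect[first],
                            family = gold$family[first],
                            genus = gold$family[first],
                            latitude = NA_real_, longitude = NA_real_,
                            stringsAsFactors = FALSE)
    collection <- wordlist_collection(
      doculects,
      data.frame(doculect = gold$doculect, concept = gold$concept,
                 transcription = gold$transcription, stringsAsFactors = FALSE),
      normalize = FALSE)
  }
  tab <- pair_feature_table(collection, model)
  key <- paste(gold$doculect, gold$concept, gold$transcription)
  k1 <- match(paste(tab$l1, tab$concept, tab$w1), key)
  k2 <- match(paste(tab$l2, tab$concept, tab$w2), key)
  tab$family1 <- gold$family[k1]
  tab$family2 <- gold$family[k2]
  tab$class1 <- gold$cognate_class[k1]
  tab$class2 <- gold$cognate_class[k2]
  tab$label <- tab$family1 == tab$family2 & tab$class1 == tab$class2
  tab
}

# B-cubed evaluation of a clustering of the items of `pairs` against gold
# classes; clusters each concept from predicted probabilities.
.evaluate_clustering <- function(pairs, probs, threshold, seed) {
  items <- unique(c(paste(pairs$l1, pairs$concept, pairs$w1, sep = "\r"),
                    paste(pairs$l2, pairs$concept, pairs$w2, sep = "\r")))
  gold_class <- setNames(character(length(items)), items)
  gold_class[paste(pairs$l1, pairs$concept, pairs$w1, sep = "\r")] <- pairs$class1
  gold_class[paste(pairs$l2, pairs$concept, pairs$w2, sep = "\r")] <- pairs$class2
  item_concept <- vapply(strsplit(items, "\r", fixed = TRUE), `[`, character(1), 2)
  pred <- character(length(items))
  names(pred) <- items
  for (cc in unique(item_concept)) {
    sel <- which(item_concept == cc)
    pm <- matrix(NA_real_, length(sel), length(sel))
    rows <- which(pairs$concept == cc)
    if (length(rows)) {
      a <- match(paste(pairs$l1[rows], pairs$concept[rows], pairs$w1[rows],
                       sep = "\r"), items[sel])
      b <- match(paste(pairs$l2[rows], pairs$concept[rows], pairs$w2[rows],
                       sep = "\r"), items[sel])
      pm[cbind(a, b)] <- probs[rows]
      pm[cbind(b, a)] <- probs[rows]
    }
    part <- cluster_words(pm, threshold = threshold, seed = seed)
    pred[sel] <- paste0(cc, "_", part)
  }
  bcubed_scores(pred, gold_class[items])
}

#' Exhaustive feature-subset model selection
#'
#' For each of the 127 non-empty subsets of the seven features, trains the
#' classifier on synonymous pairs from a random selection of training
#' families, clusters the held-out families' words, and scores the result
#' with the B-cubed F-score against the gold classes; repeated over
#' `n_splits` random family splits and averaged.
#'
#' @param gold_pairs labeled pair table from [gold_pair_table()].
#' @param n_splits number of random training/test splits (default 10).
#' @param n_train training pairs sampled per fit (default 7000).
#' @param n_train_families families in each training set (default 6,
#'   capped at one less than the number of families).
#' @param threshold clustering edge threshold (default 0.25).
#' @param seed integer seed.
#' @return list with `best` (feature subset with the highest mean F) and
#'   `scores` (127-row data frame of mean B-cubed F per subset).
#' @export
select_feature_subset <- function(gold_pairs, n_splits = 10, n_train = 7000,
                                  n_train_families = 6, threshold = 0.25,
                                  seed = 1) {
  fams <- unique(c(gold_pairs$family1, gold_pairs$family2))
  if (length(fams) < 2) stop("need at least 2 families")
  n_train_families <- min(n_train_families, length(fams) - 1)
  subsets <- unlist(lapply(seq_along(FEATURE_NAMES), function(k)
    combn(FEATURE_NAMES, k, simplify = FALSE)), recursive = FALSE)
  scores <- matrix(NA_real_, length(subsets), n_splits)
  set.seed(seed)
  split_seeds <- sample.int(1e6, n_splits)
  for (s in seq_len(n_splits)) {
    set.seed(split_seeds[s])
    train_fams <- sample(fams, n_train_families)
    tr <- gold_pairs$family1 %in% train_fams & gold_pairs$family2 %in% train_fams
    te <- !(gold_pairs$family1 %in% train_fams) &
      !(gold_pairs$family2 %in% train_fams)
    if (!any(tr) || !any(te)) next
    train <- gold_pairs[tr, ]
    test <- gold_pairs[te, ]
    for (j in seq_along(subsets)) {
      clf <- tryCatch(
        train_cognacy_classifier(train, train$label, subset = subsets[[j]],
                                 n_train = n_train, seed = split_seeds[s]),
        error = function(e) NULL)
      if (is.null(clf)) next
      probs <- predict_cognacy(clf, test)
      scores[j, s] <- .evaluate_clustering(test, probs, threshold,
                                           seed = split_seeds[s])["F"]
    }
  }
  mean_f <- rowMeans(scores, na.rm = TRUE)
  tab <- data.frame(subset = vapply(subsets, paste, character(1),
                                    collapse = "+"),
                    mean_F = mean_f, stringsAsFactors = FALSE)
  list(best = subsets[[which.max(mean_f)]], scores = tab)
}
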