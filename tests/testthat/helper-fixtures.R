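# Shared fixtures and independent oracles.

# --- brute-force licit-alignment oracle -------------------------------------
# Enumerates every licit global alignment as a move string over
# D (aligned column), U (x symbol against gap), L (y symbol against gap),
# with U and L never adjacent, and scores each explicitly.

enumerate_licit_moves <- function(n, m) {
  rec <- function(i, j, last) {
    if (i == 0 && j == 0) return(list(character(0)))
    out <- list()
    if (i > 0 && j > 0)
      out <- c(out, lapply(rec(i - 1, j - 1, "D"), function(p) c(p, "D")))
    if (i > 0 && last != "L")
      out <- c(out, lapply(rec(i - 1, j, "U"), function(p) c(p, "U")))
    if (j > 0 && last != "U")
      out <- c(out, lapply(rec(i, j - 1, "L"), function(p) c(p, "L")))
    out
  }
  # build forward: enumerate from the right end, disallowing the forbidden
  # adjacency seen from the end (symmetric constraint, so this is licit too)
  rec(n, m, "D")
}

score_moves <- function(moves, x, y, pmi, go, ge) {
  i <- 0; j <- 0; s <- 0; last <- "D"
  for (mv in moves) {
    if (mv == "D") {
      i <- i + 1; j <- j + 1
      s <- s + pmi[x[i], y[j]]
    } else {
      if (mv == "U") i <- i + 1 else j <- j + 1
      s <- s + if (mv == last) ge else go
    }
    last <- mv
  }
  s
}

brute_pmi_score <- function(x, y, pmi, go, ge) {
  max(vapply(enumerate_licit_moves(length(x), length(y)),
             score_moves, numeric(1), x = x, y = y, pmi = pmi,
             go = go, ge = ge))
}

# Small symmetric test score table over k symbols (deterministic).
test_pmi_table <- function(k = 3, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(k * k, -1, 0.7), k, k)
  m <- (m + t(m)) / 2
  diag(m) <- abs(rnorm(k, 2, 0.5))
  m
}

# Full-inventory scoring model with diagonal-dominant scores.
toy_model <- function(seed = 42) {
  inv <- sound_inventory()
  k <- length(inv$symbols)
  set.seed(seed)
  m <- matrix(rnorm(k * k, -1.2, 0.4), k, k)
  m <- (m + t(m)) / 2
  diag(m) <- rnorm(k, 2.5, 0.3)
  dimnames(m) <- list(inv$symbols, inv$symbols)
  scoring_model(m, gap_open = -2.5, gap_extend = -1.75, theta = 4.5,
                inventory = inv)
}

# Tiny hand-built two-language collection.
toy_collection <- function() {
  doculects <- data.frame(
    name = c("A", "B"), family = c("F1", "F1"), genus = c("G1", "G1"),
    latitude = c(0, 10), longitude = c(0, 10), stringsAsFactors = FALSE)
  entries <- data.frame(
    doculect = c("A", "A", "A", "B", "B"),
    concept = c("hand", "sun", "sun", "hand", "sun"),
    transcription = c("mano", "sol", "sole", "man", "sol"),
    stringsAsFactors = FALSE)
  wordlist_collection(doculects, entries)
}

# Random word-list collection of i.i.d. words (no phylogenetic structure).
random_collection <- function(n_lang, n_concepts = 40, len_mean = 4.5,
                              seed = 1) {
  set.seed(seed)
  inv <- sound_inventory()
  concepts <- sprintf("c%02d", seq_len(n_concepts))
  rows <- do.call(rbind, lapply(seq_len(n_lang), function(i) {
    words <- vapply(concepts, function(cc) {
      len <- 1 + rpois(1, len_mean - 1)
      paste(sample(inv$symbols, len, replace = TRUE), collapse = "")
    }, character(1))
    data.frame(doculect = sprintf("R%02d", i), concept = concepts,
               transcription = words, stringsAsFactors = FALSE)
  }))
  doculects <- data.frame(name = sprintf("R%02d", seq_len(n_lang)),
                          family = "RND", genus = "RND",
                          latitude = 0, longitude = 0,
                          stringsAsFactors = FALSE)
  wordlist_collection(doculects, rows, normalize = FALSE)
}

# The Old/Modern English worked example: dog and tree.
english_fixture <- function() {
  doculects <- data.frame(
    name = c("OLD_ENGLISH", "ENGLISH"),
    family = "IE", genus = "GERMANIC", latitude = NA_real_,
    longitude = NA_real_, stringsAsFactors = FALSE)
  entries <- data.frame(
    doculect = c("OLD_ENGLISH", "OLD_ENGLISH", "ENGLISH", "ENGLISH"),
    concept = c("dog", "tree", "dog", "tree"),
    transcription = c("hund", "treow", "dag", "tri"),
    stringsAsFactors = FALSE)
  collection <- wordlist_collection(doculects, entries, normalize = FALSE)
  assignment <- data.frame(
    doculect = entries$doculect, concept = entries$concept,
    word = entries$transcription,
    class = c("dog_149", "tree_17", "dog_150", "tree_17"),
    stringsAsFactors = FALSE)
  list(collection = collection, assignment = assignment)
}

# Labeled pair table with prescribed informative features: gold classes are
# built per concept within families (two classes per family), and the named
# informative features are drawn from label-shifted normals while all other
# features are pure noise.  Used to exercise the model-selection harness.
synthetic_feature_gold <- function(n_families = 8, langs_per_family = 4,
                                   n_concepts = 10,
                                   informative = c("f3", "f5"),
                                   seed = 1) {
  set.seed(seed)
  fams <- sprintf("F%d", seq_len(n_families))
  langs <- paste0(rep(fams, each = langs_per_family), "_L",
                  seq_len(langs_per_family))
  fam_of <- setNames(rep(fams, each = langs_per_family), langs)
  concepts <- sprintf("c%d", seq_len(n_concepts))
  items <- expand.grid(lang = langs, concept = concepts,
                       stringsAsFactors = FALSE)
  items$class <- paste(items$concept, fam_of[items$lang],
                       1 + (match(items$lang, langs) %% 2), sep = "_")
  pr <- t(combn(seq_len(nrow(items)), 2))
  pr <- pr[items$concept[pr[, 1]] == items$concept[pr[, 2]] &
             items$lang[pr[, 1]] != items$lang[pr[, 2]], , drop = FALSE]
  lab <- items$class[pr[, 1]] == items$class[pr[, 2]]
  n <- nrow(pr)
  tab <- data.frame(
    l1 = items$lang[pr[, 1]], l2 = items$lang[pr[, 2]],
    concept = items$concept[pr[, 1]],
    w1 = paste0("w", pr[, 1]), w2 = paste0("w", pr[, 2]),
    stringsAsFactors = FALSE)
  for (f in c("f1", "f2", "f3", "f4", "f5", "f6", "f7"))
    tab[[f]] <- rnorm(n)
  # cognate pairs: high word similarity, low language log-distance
  shift <- c(f1 = 2.4, f2 = -2.4, f3 = 2.4, f4 = -2.4, f5 = -2.4,
             f6 = 2.4, f7 = 2.4)
  for (f in informative)
    tab[[f]] <- tab[[f]] + ifelse(lab, shift[[f]], 0)
  tab$family1 <- fam_of[tab$l1]
  tab$family2 <- fam_of[tab$l2]
  tab$class1 <- items$class[pr[, 1]]
  tab$class2 <- items$class[pr[, 2]]
  tab$label <- lab
  tab
}
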