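test_that("pair features are internally consistent", {
  sim <- simulate_wordlists(sim_config(n_languages = 5, seed = 23))
  model <- toy_model()
  tab <- pair_feature_table(sim$collection, model)
  expect_true(all(tab$f2 > 0 & tab$f2 <= 1))
  expect_equal(tab$f3, -log(tab$f2), tolerance = 1e-12)
  expect_equal(tab$f5, -log(1 - pmin(tab$f4, 1 - 1e-9)), tolerance = 1e-12)
  expect_true(all(tab$f6 >= 1))
  expect_true(all(abs(tab$f7) <= 1))
  # f4/f5 constant within a language pair
  by_pair <- tapply(tab$f4, paste(tab$l1, tab$l2), function(v) diff(range(v)))
  expect_true(all(by_pair == 0))
  # f7 constant within a concept
  by_cc <- tapply(tab$f7, tab$concept, function(v) diff(range(v)))
  expect_true(all(by_cc == 0))
})

test_that("single-pair features equal the hand-computed quantities", {
  coll <- toy_collection()
  model <- toy_model()
  row <- compute_pair_features(coll, model, "mano", "man", "A", "B", "hand")
  expect_equal(row$f1, pmi_similarity("mano", "man", model))
  st <- lexiphylo:::pair_statistics(coll, "A", "B", model)
  expect_equal(row$f2, calibrated_p(row$f1, st$null))
  expect_equal(row$f4, lexiphylo:::z_to_distance(st$z))
  # f6: mean length of the words for 'hand' across the collection
  expect_equal(row$f6, mean(nchar(c("mano", "man"))))
})

test_that("concept-language correlation matches a hand Pearson computation", {
  sim <- simulate_wordlists(sim_config(n_languages = 5, seed = 23))
  tab <- pair_feature_table(sim$collection, toy_model())
  # pick a concept with spread in both features (degenerate ones map to 0)
  spread <- tapply(seq_len(nrow(tab)), tab$concept, function(i)
    min(sd(tab$f3[i]), sd(tab$f4[i])))
  cc <- names(which.max(spread))
  rows <- tab[tab$concept == cc, ]
  expect_equal(rows$f7[1], cor(rows$f3, rows$f4))
  flat <- names(which(spread == 0))
  if (length(flat)) expect_equal(tab$f7[tab$concept == flat[1]][1], 0)
})

test_that("classifier separates separable features and is calibrated", {
  set.seed(2)
  n <- 300
  f <- data.frame(f3 = c(rnorm(n, 3), rnorm(n, -3)), f5 = rnorm(2 * n))
  lab <- rep(c(TRUE, FALSE), each = n)
  clf <- train_cognacy_classifier(f, lab, subset = c("f3", "f5"),
                                  n_train = 400, seed = 3)
  p <- predict_cognacy(clf, f)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(mean((p > 0.5) == lab), 1)
  # increasing along the informative direction (within the data range; the
  # RBF kernel may flatten in the far tails)
  probe <- data.frame(f3 = seq(-3, 3, length.out = 9), f5 = 0)
  pp <- predict_cognacy(clf, probe)
  expect_gt(cor(probe$f3, pp, method = "spearman"), 0.9)
  expect_lt(pp[1], 0.1)
  expect_gt(pp[9], 0.9)
  expect_error(train_cognacy_classifier(f, rep(TRUE, 2 * n)),
               "single class")
})

test_that("label propagation respects components and finds cliques", {
  # all-zero adjacency: all singletons
  expect_equal(label_propagation(matrix(0, 4, 4)), 1:4)
  # two cliques, no bridge: two clusters
  a <- matrix(0, 6, 6); a[1:3, 1:3] <- 1; a[4:6, 4:6] <- 1; diag(a) <- 0
  part <- label_propagation(a, seed = 1)
  expect_equal(length(unique(part)), 2)
  expect_equal(length(unique(part[1:3])), 1)
  expect_equal(length(unique(part[4:6])), 1)
  # communities never span graph components
  b <- matrix(0, 5, 5); b[1:2, 1:2] <- 1; b[3:5, 3:5] <- 1; diag(b) <- 0
  pb <- label_propagation(b, seed = 2)
  expect_true(all(outer(pb[1:2], pb[3:5], "!=")))
  # cross-check against the independent igraph implementation on a graph
  # with unambiguous community structure
  skip_if_not_installed("igraph")
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  set.seed(3)
  ig <- igraph::membership(igraph::cluster_label_prop(g))
  ours <- label_propagation(a, seed = 3)
  expect_equal(length(unique(ig)), length(unique(ours)))
  expect_true(all(table(ours, ig) %in% c(0, 3)))
})

test_that("weak bridge between two triangles is cut by majority rule", {
  # nodes 1-3 and 4-6 are triangles; single bridge 3-4.  Under the
  # majority update each triangle converges to its own label: the bridge
  # endpoint sees two same-triangle neighbors vs one across.
  a <- matrix(0, 6, 6)
  a[1:3, 1:3] <- 1; a[4:6, 4:6] <- 1; a[3, 4] <- a[4, 3] <- 1
  diag(a) <- 0
  for (s in 1:5) {
    part <- label_propagation(a, seed = s)
    expect_equal(length(unique(part[1:3])), 1)
    expect_equal(length(unique(part[4:6])), 1)
  }
})

test_that("cluster_words honours the probability threshold", {
  p <- matrix(0, 4, 4)
  expect_equal(cluster_words(p), 1:4)
  p2 <- matrix(0.3, 4, 4); diag(p2) <- NA
  expect_equal(length(unique(cluster_words(p2, threshold = 0.25))), 1)
  expect_equal(cluster_words(p2, threshold = 0.5), 1:4)
})

test_that("identical doculects cluster together; concepts are independent", {
  sim <- simulate_wordlists(sim_config(n_languages = 4, seed = 29,
                                       replacement_rate = 0))
  model <- toy_model()
  # duplicate doculect: words identical, probabilities near 1 within concept
  tab <- pair_feature_table(sim$collection, model)
  lab <- tab$w1 == tab$w2  # proxy training labels on the synthetic data
  clf <- train_cognacy_classifier(tab, lab, subset = c("f3", "f5"),
                                  n_train = 500, seed = 5)
  ass <- cluster_collection(sim$collection, model, clf, seed = 7)
  expect_equal(nrow(ass), nrow(sim$collection$entries))
  # labels never span concepts
  expect_true(all(startsWith(ass$class, ass$concept)))
})

test_that("feature-subset selection finds the informative features", {
  # synthetic pair table: 6 families, one word per language/concept;
  # only f1 carries signal, the rest is noise
  set.seed(11)
  fams <- sprintf("F%d", 1:6)
  langs <- paste0(rep(fams, each = 3), "_L", 1:3)
  fam_of <- setNames(rep(fams, each = 3), langs)
  concepts <- sprintf("c%d", 1:12)
  items <- expand.grid(lang = langs, concept = concepts,
                       stringsAsFactors = FALSE)
  # two gold classes per concept within each family
  items$class <- paste(items$concept, fam_of[items$lang],
                       1 + (match(items$lang, langs) %% 2), sep = "_")
  pr <- t(combn(seq_len(nrow(items)), 2))
  pr <- pr[items$concept[pr[, 1]] == items$concept[pr[, 2]] &
             items$lang[pr[, 1]] != items$lang[pr[, 2]], ]
  lab <- items$class[pr[, 1]] == items$class[pr[, 2]]
  n <- nrow(pr)
  tab <- data.frame(
    l1 = items$lang[pr[, 1]], l2 = items$lang[pr[, 2]],
    concept = items$concept[pr[, 1]],
    w1 = paste0("w", pr[, 1]), w2 = paste0("w", pr[, 2]),
    f1 = ifelse(lab, 3, -3) + rnorm(n, 0, 0.5),
    f2 = runif(n), f3 = rnorm(n), f4 = rnorm(n), f5 = rnorm(n),
    f6 = rnorm(n), f7 = rnorm(n),
    family1 = fam_of[items$lang[pr[, 1]]],
    family2 = fam_of[items$lang[pr[, 2]]],
    class1 = items$class[pr[, 1]], class2 = items$class[pr[, 2]],
    label = lab, stringsAsFactors = FALSE)
  sel <- select_feature_subset(tab, n_splits = 2, n_train = 400,
                               n_train_families = 4, seed = 3)
  expect_equal(nrow(sel$scores), 127)
  expect_true("f1" %in% sel$best)
})
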