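test_that("probable-relatedness screen keeps identical lists, drops noise", {
  coll <- random_collection(2, n_concepts = 20, seed = 21)
  ent <- coll$entries
  ent$transcription[ent$doculect == "R02"] <-
    ent$transcription[ent$doculect == "R01"]
  ident <- wordlist_collection(coll$doculects, ent, normalize = FALSE)
  rel <- probably_related_pairs(ident)
  expect_equal(nrow(rel), 1)
  # words over disjoint alphabets: distance near 1, excluded
  doc <- data.frame(name = c("A", "B"), family = "F", genus = "G",
                    latitude = 0, longitude = 0)
  set.seed(2)
  cs <- sprintf("c%02d", 1:20)
  mk <- function(sym) vapply(cs, function(cc)
    paste(sample(sym, 4, TRUE), collapse = ""), character(1))
  ent2 <- rbind(
    data.frame(doculect = "A", concept = cs, transcription = mk(c("p", "b", "m"))),
    data.frame(doculect = "B", concept = cs, transcription = mk(c("i", "e", "a"))))
  far <- wordlist_collection(doc, ent2, normalize = FALSE)
  expect_equal(nrow(probably_related_pairs(far)), 0)
})

test_that("potential cognates pick the lowest-LDN synonym pair", {
  coll <- toy_collection()
  rel <- data.frame(l1 = "A", l2 = "B")
  pc <- potential_cognate_pairs(coll, rel)
  # one tuple per shared concept
  expect_equal(sort(pc$concept), c("hand", "sun"))
  # exact match among the 2x1 sun synonyms wins (LDN 0)
  expect_equal(pc$w1[pc$concept == "sun"], "sol")
  expect_equal(pc$w2[pc$concept == "sun"], "sol")
})

test_that("initial PMI estimate matches a hand computation", {
  # three aligned pairs, all length-2 words, no indels needed:
  # ab~ab, ab~ab, ab~cb  ->  aligned pairs: (a,a) x2, (b,b) x3, (a,c) x1
  doc <- data.frame(name = c("A", "B"), family = "F", genus = "G",
                    latitude = 0, longitude = 0)
  ent <- data.frame(doculect = rep(c("A", "B"), each = 3),
                    concept = rep(c("c1", "c2", "c3"), 2),
                    transcription = c("ab", "ab", "ab", "ab", "ab", "cb"))
  coll <- wordlist_collection(doc, ent, normalize = FALSE)
  pairs <- data.frame(l1 = "A", l2 = "B", concept = c("c1", "c2", "c3"),
                      w1 = c("ab", "ab", "ab"), w2 = c("ab", "ab", "cb"))
  k <- 0.5
  pmi <- estimate_initial_pmi(coll, pairs, k = k)
  # hand computation: counts (sym) a-a 4, b-b 6, a-c 1 (+1 symmetrized)
  counts <- matrix(0, 41, 41, dimnames = dimnames(pmi))
  counts["a", "a"] <- 4; counts["b", "b"] <- 6
  counts["a", "c"] <- 1; counts["c", "a"] <- 1
  s <- (counts + k) / sum(counts + k)
  tok <- c(a = 5, b = 6, c = 1)
  q <- setNames(rep(k, 41), rownames(pmi))
  q[names(tok)] <- q[names(tok)] + tok
  q <- q / (12 + 41 * k)
  expect_equal(pmi, log(s / outer(q, q)))
  expect_equal(pmi, t(pmi))
})

test_that("refinement is a fixed point when alignments cannot change", {
  # identical word pairs: every round re-aligns identically, so scores
  # stabilize after the first re-estimation
  doc <- data.frame(name = c("A", "B"), family = "F", genus = "G",
                    latitude = 0, longitude = 0)
  cs <- sprintf("c%02d", 1:12)
  set.seed(31)
  inv <- sound_inventory()
  words <- vapply(cs, function(cc)
    paste(sample(inv$symbols[1:10], 4, TRUE), collapse = ""), character(1))
  ent <- rbind(data.frame(doculect = "A", concept = cs, transcription = words),
               data.frame(doculect = "B", concept = cs, transcription = words))
  coll <- wordlist_collection(doc, ent, normalize = FALSE)
  pairs <- data.frame(l1 = "A", l2 = "B", concept = cs, w1 = words, w2 = words)
  m1 <- refine_pmi(coll, pairs, -2.5, -1.75, theta = -Inf, iterations = 1)
  m10 <- refine_pmi(coll, pairs, -2.5, -1.75, theta = -Inf, iterations = 10)
  expect_equal(m10$pmi, m1$pmi, tolerance = 1e-12)
})

test_that("retained-pair count is monotone in theta; too-high theta errors", {
  sim <- simulate_wordlists(sim_config(n_languages = 6, seed = 13))
  rel <- probably_related_pairs(sim$collection)
  pc <- potential_cognate_pairs(sim$collection, rel)
  kept <- vapply(c(-Inf, 0, 3), function(th)
    attr(refine_pmi(sim$collection, pc, -2.5, -1.75, th,
                    iterations = 2), "n_kept")[2], numeric(1))
  expect_true(all(diff(kept) <= 0))
  expect_equal(kept[1], nrow(pc))
  expect_error(refine_pmi(sim$collection, pc, -2.5, -1.75, theta = 1e6,
                          iterations = 1), "threshold too high")
})

test_that("learned self-scores are positive and propensities are recovered", {
  sim <- simulate_wordlists(sim_config(n_languages = 12, seed = 17))
  rel <- probably_related_pairs(sim$collection)
  pc <- potential_cognate_pairs(sim$collection, rel)
  model <- refine_pmi(sim$collection, pc, -2.5, -1.75, theta = 0)
  q <- estimate_symbol_frequencies(sim$collection)$q
  seen <- names(q)[q > 0.005]
  expect_true(all(diag(model$pmi)[seen] > 0))
  # rank correlation between learned off-diagonal scores and the true
  # substitution propensities, over well-observed symbols
  P <- sim$config$propensity
  sub <- match(seen, rownames(P))
  ut <- which(upper.tri(P[sub, sub]))
  rho <- cor(model$pmi[seen, seen][ut], P[sub, sub][ut], method = "spearman")
  expect_gt(rho, 0.2)
})

test_that("optimization lowers the related-pair mean distance vs bootstrap", {
  sim <- simulate_wordlists(sim_config(n_languages = 8, seed = 19))
  rel <- probably_related_pairs(sim$collection)
  f_ldn <- lexiphylo:::mean_pair_distance(sim$collection, rel, "ldn")
  opt <- suppressWarnings(
    optimize_hyperparameters(sim$collection, max_eval = 25))
  expect_lt(opt$value, f_ldn)
  expect_true(is.matrix(opt$trace))
  # deterministic: same call, same result
  opt2 <- suppressWarnings(
    optimize_hyperparameters(sim$collection, max_eval = 25))
  expect_equal(opt$par, opt2$par)
  expect_equal(opt$value, opt2$value)
})
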