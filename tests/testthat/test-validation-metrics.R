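test_that("bcubed scores match hand formulas", {
  expect_equal(unname(bcubed_scores(c(1, 1, 2), c(1, 1, 2))), c(1, 1, 1))
  # all singletons vs one gold cluster of n: precision 1, recall 1/n
  n <- 5
  b <- bcubed_scores(seq_len(n), rep(1, n))
  expect_equal(unname(b["precision"]), 1)
  expect_equal(unname(b["recall"]), 1 / n)
  expect_equal(unname(b["F"]), 2 * (1 / n) / (1 + 1 / n))
  # relabeling invariance
  pred <- c("a", "a", "b", "c")
  gold <- c(1, 2, 2, 3)
  relab <- c(a = "z", b = "y", c = "x")[pred]
  expect_equal(bcubed_scores(pred, gold), bcubed_scores(relab, gold))
  expect_error(bcubed_scores(character(0), character(0)), "empty")
})

test_that("GQD is 0 on identity and errors on a star reference", {
  sim <- simulate_wordlists(sim_config(n_languages = 8, seed = 47))
  expect_equal(generalized_quartet_distance(sim$tree, sim$tree), 0)
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,E:1);")
  expect_error(generalized_quartet_distance(tr, star), "resolves no")
  # and the candidate's disagreement with a resolved reference is counted
  expect_equal(generalized_quartet_distance(star, tr), 1)
})

test_that("GQD equals a quartet-by-quartet brute check on 6 taxa", {
  t1 <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  t2 <- ape::read.tree(text = "(((A:1,C:1):1,(B:1,D:1):1):1,(E:1,F:1):1);")
  # independent oracle: resolve each of the 15 quartets by pruning and
  # comparing the single internal split
  quartet_split <- function(tr, q) {
    sub <- ape::unroot(ape::keep.tip(tr, q))
    pp <- ape::prop.part(sub)
    labs <- attr(pp, "labels")
    two <- Filter(function(p) length(p) == 2, pp[-1])
    if (length(two) == 0) return(NA_character_)
    paste(sort(labs[two[[1]]]), collapse = "")
  }
  qs <- combn(t1$tip.label, 4, simplify = FALSE)
  hand <- mean(vapply(qs, function(q) {
    s1 <- quartet_split(t1, q); s2 <- quartet_split(t2, q)
    # complement-aware comparison: a quartet has two equivalent cherry codes
    comp <- paste(sort(setdiff(q, strsplit(s2, "")[[1]])), collapse = "")
    !(s1 == s2 || s1 == comp)
  }, logical(1)))
  expect_equal(generalized_quartet_distance(t1, t2, mode = "exact"), hand)
})

test_that("sampled GQD agrees with exact enumeration", {
  cfg <- sim_config(n_languages = 10, seed = 53)
  t1 <- simulate_tree(cfg)
  cfg2 <- sim_config(n_languages = 10, seed = 54)
  t2 <- simulate_tree(cfg2)
  t2$tip.label <- t1$tip.label[order(t1$tip.label)]
  exact <- generalized_quartet_distance(t1, t2, mode = "exact")
  sampled <- generalized_quartet_distance(t1, t2, mode = "sampled",
                                          n_samples = 4000, seed = 5)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(sampled - exact), max(2 * se, 0.02))
})

test_that("cosine character distance masks undefined coordinates", {
  expect_equal(cosine_character_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(cosine_character_distance(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  v1 <- c(1, 0, NA, 1); v2 <- c(1, 0, 1, NA)
  # only coordinates 1-2 are jointly defined
  expect_equal(cosine_character_distance(v1, v2),
               cosine_character_distance(c(1, 0), c(1, 0)))
  v1b <- v1; v1b[3] <- NA; v2b <- v2; v2b[4] <- NA
  expect_equal(cosine_character_distance(v1b, v2b),
               cosine_character_distance(v1, v2))
  expect_error(cosine_character_distance(c(NA, 1), c(1, NA)), "defined")
  expect_error(cosine_character_distance(c(0, 0), c(1, 1)), "zero vector")
})

test_that("great-circle distance has the right fixed points", {
  expect_equal(great_circle_distance(10, 20, 10, 20), 0)
  expect_equal(great_circle_distance(0, 0, 0, 180), pi * 6371,
               tolerance = 1e-6)
  expect_equal(great_circle_distance(12, 34, -45, 100),
               great_circle_distance(-45, 100, 12, 34))
  expect_error(great_circle_distance(95, 0, 0, 0), "range")
})

test_that("mantel test recovers perfect correlation and permutes sanely", {
  set.seed(3)
  x <- matrix(runif(36), 6); dm1 <- as.matrix(dist(x)); diag(dm1) <- 0
  res <- mantel_test(dm1, dm1, n_perm = 99, seed = 2)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 100)
  # joint relabeling leaves the statistic unchanged
  perm <- sample(rownames(dm1))
  res2 <- mantel_test(dm1[perm, perm], dm1[perm, perm], n_perm = 99, seed = 2)
  expect_equal(res2$r, 1)
})

test_that("mantel correlogram flags short-range similarity", {
  set.seed(4)
  pos <- runif(30, 0, 50)
  geo <- as.matrix(dist(pos)) * 100
  ling <- geo / max(geo)
  ling <- ling + (as.matrix(dist(runif(30))) * 0.02)
  diag(ling) <- 0
  dimnames(geo) <- dimnames(ling) <- list(paste0("L", 1:30), paste0("L", 1:30))
  cg <- mantel_correlogram(ling, geo, bin_edges = seq(0, 5000, 1000),
                           n_perm = 199, seed = 6)
  expect_gt(cg$r[1], 0)
  expect_true(cg$significant[1])
  # shuffled linguistic matrix: no systematic signal in the first bin
  set.seed(7)
  hits <- 0
  for (k in 1:5) {
    perm <- sample(30)
    lp <- ling[perm, perm]
    dimnames(lp) <- dimnames(ling)
    cgp <- mantel_correlogram(lp, geo, bin_edges = seq(0, 5000, 1000),
                              n_perm = 99, seed = k)
    hits <- hits + (cgp$significant[1] && cgp$r[1] > 0)
  }
  expect_lte(hits, 1)
})
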