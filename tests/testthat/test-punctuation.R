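test_that("nearest outgroup is the argmin of the mean distance", {
  dm <- matrix(c(0, 1, 2, 5, 4,
                 1, 0, 2, 6, 5,
                 2, 2, 0, 7, 3,
                 5, 6, 7, 0, 1,
                 4, 5, 3, 1, 0), 5, 5,
               dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  expect_equal(nearest_outgroup(dm, c("A", "B")), "C")
  # adding a far candidate never changes the winner
  expect_equal(nearest_outgroup(dm, c("A", "B", "C")), "E")
  expect_error(nearest_outgroup(dm, LETTERS[1:5]), "outside")
})

test_that("root-to-tip statistics match hand counts", {
  two <- ape::read.tree(text = "(A:1,B:2);")
  st <- root_to_tip_statistics(two)
  expect_equal(st$n_nodes, c(1, 1))
  expect_equal(st$path_length, c(1, 2))
  # 5-leaf caterpillar: counts 1..4 pattern
  cat5 <- ape::read.tree(text = "(A:1,(B:1,(C:1,(D:1,E:1):1):1):1);")
  stc <- root_to_tip_statistics(cat5)
  expect_equal(sort(stc$n_nodes), c(1, 2, 3, 4, 4))
  expect_true(all(stc$path_length >= 0))
  expect_error(root_to_tip_statistics(ape::unroot(cat5)), "rooted")
})

test_that("pgls slope agrees with the nlme GLS fit under BM covariance", {
  tr <- simulate_rate_tree(12, rate_sd = 0.4, seed = 61)
  st <- root_to_tip_statistics(tr)
  set.seed(62)
  x <- st$path_length
  y <- st$n_nodes + rnorm(12, 0, 0.3)
  res <- pgls_slope(tr, setNames(x, st$taxon), setNames(y, st$taxon))
  # independent oracle: nlme::gls with the Brownian correlation plus
  # fixed variance weights proportional to root-to-tip depth, which
  # together reproduce the full BM covariance on a non-ultrametric tree
  V <- ape::vcv(tr)[st$taxon, st$taxon]
  df <- data.frame(x = x, y = y, taxon = st$taxon, v = diag(V))
  fit <- nlme::gls(y ~ x, data = df,
                   correlation = ape::corBrownian(1, phy = tr, form = ~taxon),
                   weights = nlme::varFixed(~v), method = "REML")
  tt <- summary(fit)$tTable
  expect_equal(res$slope, tt["x", "Value"], tolerance = 1e-6)
  expect_equal(res$slope / res$se, tt["x", "t-value"], tolerance = 1e-6)
})

test_that("pgls on a star tree equals ordinary least squares", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  star <- ape::collapse.singles(ape::root(star, resolve.root = TRUE,
                                          outgroup = "A"))
  set.seed(8)
  x <- rnorm(6); y <- 2 * x + rnorm(6, 0, 0.1)
  names(x) <- names(y) <- star$tip.label
  res <- pgls_slope(star, x, y)
  ols <- coef(lm(y ~ x))[2]
  expect_equal(res$slope, unname(ols), tolerance = 1e-6)
  # exact linear relation: slope 2, p ~ 0
  y2 <- setNames(2 * x, names(x))
  res2 <- pgls_slope(star, x, y2)
  expect_equal(res2$slope, 2, tolerance = 1e-6)
  expect_lt(res2$p, 1e-8)
})

test_that("delta test separates linear from superlinear node growth", {
  # build a tree-shaped fixture, then impose node counts by construction
  tr <- simulate_rate_tree(40, rate_sd = 0.3, seed = 67)
  st <- root_to_tip_statistics(tr)
  # the real delta test runs on the tree itself; for the two constructed
  # regimes we refit the log-log PGLS directly
  fit_delta <- function(n) {
    res <- pgls_slope(tr, setNames(log(st$path_length), st$taxon),
                      setNames(log(n), st$taxon))
    ci <- res$slope + c(-1, 1) * qt(0.975, nrow(st) - 2) * res$se
    !(ci[1] > 1)
  }
  set.seed(9)
  n_lin <- st$path_length * exp(rnorm(40, 0, 0.05))
  n_quad <- st$path_length^2 * exp(rnorm(40, 0, 0.05))
  expect_true(fit_delta(n_lin))    # delta ~ 1: negative (no artifact)
  expect_false(fit_delta(n_quad))  # delta ~ 2: positive
  # a well-behaved 5-leaf tree runs without error
  expect_error(delta_test(ape::read.tree(
    text = "((A:1,B:1.5):1,((C:1,D:2):1,E:2.5):0.5);")), NA)
  # degenerate input: ultrametric clock tree has equal path lengths
  clock <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1):0;")
  expect_error(delta_test(clock), "at least 5|degenerate")
})

test_that("holm-bonferroni follows the step-down rule", {
  expect_equal(holm_bonferroni(0.01), TRUE)
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(TRUE, TRUE))
  expect_equal(holm_bonferroni(c(0.03, 0.04)), c(FALSE, FALSE))
  expect_equal(holm_bonferroni(rep(1, 4)), rep(FALSE, 4))
  expect_error(holm_bonferroni(1.2), "range")
})

test_that("workflow flags a punctuational family and skips small ones", {
  # punctuational: every split adds a burst of change; the branch-rate
  # noise keeps the delta screen from firing on the clean n ~ x relation
  tr_p <- simulate_rate_tree(30, rate_sd = 0.8, burst = 0.8, seed = 71)
  tr_g <- simulate_rate_tree(30, rate_sd = 0.8, burst = 0, seed = 72)
  doc <- data.frame(
    name = c(tr_p$tip.label, paste0("G", tr_g$tip.label), "TINY1", "TINY2"),
    family = c(rep("PUNC", 30), rep("GRAD", 30), "T", "T"),
    genus = "g", latitude = 0, longitude = 0)
  coll <- list(doculects = doc)
  class(coll) <- "wordlist_collection"
  tr_g2 <- tr_g; tr_g2$tip.label <- paste0("G", tr_g$tip.label)
  trees <- list(PUNC = tr_p, GRAD = tr_g2)
  dm <- diag(0, nrow(doc)); dimnames(dm) <- list(doc$name, doc$name)
  expect_warning(
    res <- punctuation_workflow(coll, dm, trees = trees, min_taxa = 10),
    "fewer than")
  expect_equal(nrow(res), 2)
  p_row <- res[res$family == "PUNC", ]
  g_row <- res[res$family == "GRAD", ]
  expect_gt(p_row$slope, 0)
  expect_lt(p_row$p_value, 0.05)
  # the significance flag requires the delta screen and a positive slope
  expect_true(!p_row$significant ||
                (isTRUE(p_row$delta_negative) && p_row$slope > 0))
  expect_false(g_row$significant)
})
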