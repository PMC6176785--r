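# Synthetic word-list evolution with known ground truth.
#
# Languages evolve down a Yule tree: each concept's word undergoes
# symbol substitutions (a Markov jump process steered by a row-stochastic
# propensity matrix), insertions/deletions, and concept-level lexical
# replacements that start a new cognate class.  The generator therefore
# provides, for every other module, inputs with a recoverable target: a
# true tree, true cognate classes, and true substitution propensities.

#' Default symbol groups of the sound-class alphabet
#'
#' A coarse articulatory grouping (vowels, labials, coronals, dorsals)
#' used to build the default substitution propensity matrix: sound change
#' overwhelmingly stays within such classes.
#'
#' @return named list of symbol vectors partitioning the 41 classes.
#' @export
asjp_symbol_groups <- function() {
  list(vowel = c("i", "e", "E", "3", "a", "u", "o"),
       labial = c("p", "b", "m", "f", "v", "w"),
       coronal = c("8", "4", "t", "d", "s", "z", "c", "n", "r", "l",
                   "S", "Z", "C", "j", "T", "5", "L"),
       dorsal = c("y", "k", "g", "x", "N", "q", "G", "X", "7", "h", "!"))
}

#' Default substitution propensity matrix
#'
#' Row-stochastic matrix giving, for each sound class, the distribution of
#' its replacement when a substitution event hits it: mass `within` is
#' spread uniformly over the other members of its articulatory group, the
#' rest uniformly over all remaining symbols.  Diagonal is zero.
#'
#' @param within probability of staying within the articulatory group
#'   (default 0.75).
#' @param inventory a [sound_inventory()].
#' @return 41 x 41 row-stochastic matrix.
#' @export
default_propensity <- function(within = 0.75, inventory = sound_inventory()) {
  sym <- inventory$symbols
  groups <- asjp_symbol_groups()
  grp <- rep(names(groups), lengths(groups))[match(sym, unlist(groups))]
  n <- length(sym)
  P <- matrix(0, n, n, dimnames = list(sym, sym))
  for (i in seq_len(n)) {
    same <- which(grp == grp[i]); same <- setdiff(same, i)
    other <- setdiff(seq_len(n), c(i, same))
    P[i, same] <- within / length(same)
    P[i, other] <- (1 - within) / length(other)
  }
  P
}

#' Simulation configuration
#'
#' Parameters of the synthetic word-list generator.  Defaults emulate a
#' single language family of moderate depth: on a Yule tree with unit
#' birth rate and 30 tips (expected depth about 3.5 time units), the most
#' divergent language pairs retain roughly a third of their cognate
#' classes per concept and shared cognates differ at a substantial
#' fraction of their segments.
#'
#' @param n_languages number of tip languages.
#' @param n_concepts concepts per word list (default 40).
#' @param birth_rate Yule speciation rate per lineage per time unit.
#' @param substitution_rate substitution events per symbol per time unit.
#' @param indel_rate insertion/deletion events per site per time unit.
#' @param replacement_rate lexical replacement events per concept per time
#'   unit (each starts a new cognate class).
#' @param propensity row-stochastic substitution propensity matrix.
#' @param burst_size extra evolution time added to each daughter branch at
#'   every split (punctuational mode; 0 disables it).
#' @param mean_word_length expected word length in symbols (at least 1).
#' @param geo_sd degrees of Brownian coordinate drift per sqrt time unit.
#' @param seed integer random seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_languages = 30, n_concepts = 40, birth_rate = 1,
                       substitution_rate = 0.2, indel_rate = 0.05,
                       replacement_rate = 0.15,
                       propensity = default_propensity(),
                       burst_size = 0, mean_word_length = 4.5,
                       geo_sd = 10, seed = 1) {
  stopifnot(n_languages >= 2, n_concepts >= 1, birth_rate > 0,
            substitution_rate >= 0, indel_rate >= 0, replacement_rate >= 0,
            burst_size >= 0, mean_word_length >= 1)
  if (max(abs(rowSums(propensity) - 1)) > 1e-9)
    stop("propensity matrix rows must sum to 1")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a tree
#'
#' Rooted binary Yule tree with `n_languages` tips; branch lengths in time
#' units; reproducible under the config seed.
#'
#' @param config a [sim_config()].
#' @return an `ape` `phylo` tree, rooted, with tip labels `L01`, `L02`, ...
#' @export
simulate_tree <- function(config) {
  set.seed(config$seed)
  tr <- ape::rphylo(config$n_languages, birth = config$birth_rate, death = 0)
  tr$tip.label <- sprintf("L%02d", seq_len(config$n_languages))
  tr
}

# One word evolution step along effective time t.
.evolve_word <- function(word, t, cfg) {
  len <- length(word)
  nsub <- rpois(1, cfg$substitution_rate * t * len)
  for (s in seq_len(nsub)) {
    pos <- sample.int(length(word), 1)
    word[pos] <- sample.int(nrow(cfg$propensity), 1,
                            prob = cfg$propensity[word[pos], ])
  }
  nind <- rpois(1, cfg$indel_rate * t * (length(word) + 1))
  for (s in seq_len(nind)) {
    if (runif(1) < 0.5 && length(word) > 1) {
      word <- word[-sample.int(length(word), 1)]
    } else {
      pos <- sample.int(length(word) + 1, 1)
      word <- append(word, sample.int(nrow(cfg$propensity), 1), after = pos - 1)
    }
  }
  word
}

.random_word <- function(cfg) {
  len <- 1 + rpois(1, cfg$mean_word_length - 1)
  sample.int(nrow(cfg$propensity), len, replace = TRUE)
}

#' Evolve word lists down a tree
#'
#' Root words are drawn i.i.d. over the alphabet; along each branch of
#' length t (plus `burst_size` in punctuational mode), each concept
#' undergoes Poisson lexical replacement (new word, new cognate class) and,
#' absent replacement, symbol substitutions and indels.  Doculect
#' coordinates drift by Brownian motion on the tree, so geographic and
#' phylogenetic distances are correlated.
#'
#' @param tree a rooted `phylo` tree (see [simulate_tree()]).
#' @param config a [sim_config()].
#' @param family family name recorded for all doculects.
#' @return list with `collection` (a [wordlist_collection()]),
#'   `assignment` (data frame `doculect`, `concept`, `word`, `class`: the
#'   true cognate classes), and `tree`.
#' @export
evolve_wordlists <- function(tree, config, family = "SIM") {
  cfg <- config
  set.seed(cfg$seed + 1L)
  inv <- sound_inventory()
  concepts <- sprintf("c%02d", seq_len(cfg$n_concepts))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  class_counter <- setNames(rep(1L, cfg$n_concepts), concepts)

  root_state <- list(words = lapply(concepts, function(cc) .random_word(cfg)),
                     classes = setNames(rep(1L, cfg$n_concepts), concepts),
                     lat = 0, lon = 0)
  states <- vector("list", max(tree$edge))
  states[[root]] <- root_state

  # preorder traversal: parents appear before children in reorder(cladewise)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    t_eff <- tr$edge.length[e] + cfg$burst_size
    st <- states[[par]]
    new_words <- st$words
    new_classes <- st$classes
    for (ci in seq_len(cfg$n_concepts)) {
      cc <- concepts[ci]
      if (rpois(1, cfg$replacement_rate * t_eff) > 0) {
        new_words[[ci]] <- .random_word(cfg)
        class_counter[cc] <- class_counter[cc] + 1L
        new_classes[ci] <- class_counter[cc]
      } else {
        new_words[[ci]] <- .evolve_word(new_words[[ci]], t_eff, cfg)
      }
    }
    states[[child]] <- list(words = new_words, classes = new_classes,
                            lat = st$lat + rnorm(1, 0, cfg$geo_sd * sqrt(t_eff)),
                            lon = st$lon + rnorm(1, 0, cfg$geo_sd * sqrt(t_eff)))
  }

  tips <- seq_len(n_tip)
  doculects <- data.frame(
    name = tree$tip.label,
    family = family, genus = family,
    latitude = pmax(-89, pmin(89, vapply(tips, function(i) states[[i]]$lat, 1))),
    longitude = vapply(tips, function(i)
      ((states[[i]]$lon + 180) %% 360) - 180, 1),
    stringsAsFactors = FALSE)
  rows <- lapply(tips, function(i) {
    st <- states[[i]]
    data.frame(doculect = tree$tip.label[i], concept = concepts,
               transcription = vapply(st$words, decode_word, character(1),
                                      inventory = inv),
               class = paste0(concepts, "_", family, "_", st$classes),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  collection <- wordlist_collection(doculects,
                                    long[, c("doculect", "concept", "transcription")],
                                    inv, normalize = FALSE)
  assignment <- data.frame(doculect = long$doculect, concept = long$concept,
                           word = long$transcription, class = long$class,
                           stringsAsFactors = FALSE)
  list(collection = collection, assignment = assignment, tree = tree)
}

#' Simulate a full word-list collection
#'
#' [simulate_tree()] plus [evolve_wordlists()] in one call.
#'
#' @inheritParams evolve_wordlists
#' @return see [evolve_wordlists()]; the config is echoed as `config`.
#' @export
simulate_wordlists <- function(config = sim_config(), family = "SIM") {
  tree <- simulate_tree(config)
  out <- evolve_wordlists(tree, config, family = family)
  out$config <- config
  out
}

#' Simulate a multi-family gold standard
#'
#' Evolves several independent families (separate trees and root words, so
#' cross-family words are non-cognate by construction) and merges them into
#' one collection with family-wide unique cognate-class labels.
#'
#' @param n_families number of independent families.
#' @param n_languages languages per family.
#' @param config base [sim_config()] (its `n_languages` and `seed` are
#'   overridden per family).
#' @return list with `collection`, `gold` (data frame `doculect`,
#'   `family`, `concept`, `transcription`, `cognate_class`), and `trees`.
#' @export
simulate_gold <- function(n_families = 4, n_languages = 8,
                          config = sim_config()) {
  fams <- sprintf("FAM%02d", seq_len(n_families))
  parts <- lapply(seq_len(n_families), function(k) {
    cfg <- config
    cfg$n_languages <- n_languages
    cfg$seed <- config$seed + 1000L * k
    sim <- simulate_wordlists(cfg, family = fams[k])
    # prefix doculect names so they are unique across families
    sim$collection$doculects$name <- paste0(fams[k], "_",
                                            sim$collection$doculects$name)
    sim$collection$entries$doculect <- paste0(fams[k], "_",
                                              sim$collection$entries$doculect)
    sim$assignment$doculect <- paste0(fams[k], "_", sim$assignment$doculect)
    sim
  })
  doculects <- do.call(rbind, lapply(parts, function(p) p$collection$doculects))
  entries <- do.call(rbind, lapply(parts, function(p) p$collection$entries))
  collection <- wordlist_collection(doculects, entries, normalize = FALSE)
  gold <- do.call(rbind, lapply(seq_along(parts), function(k) {
    a <- parts[[k]]$assignment
    data.frame(doculect = a$doculect, family = fams[k], concept = a$concept,
               transcription = a$word, cognate_class = a$class,
               stringsAsFactors = FALSE)
  }))
  list(collection = collection, gold = gold,
       trees = lapply(parts, `[[`, "tree"))
}

#' Simulate a tree with branch lengths in change units
#'
#' For calibrating the punctuated-evolution test: a Yule tree whose branch
#' lengths are time multiplied by lognormal branch-specific rate noise
#' (gradual model), optionally with a constant `burst` added to every
#' branch, so that each split contributes `burst` extra change to its
#' descendants (punctuational model).
#'
#' @param n number of tips.
#' @param rate_sd lognormal sdlog of the branch rate noise.
#' @param burst change added per branch (0 = gradual).
#' @param birth_rate Yule speciation rate.
#' @param seed integer seed.
#' @return a rooted `phylo` tree.
#' @export
simulate_rate_tree <- function(n, rate_sd = 0.5, burst = 0, birth_rate = 1,
                               seed = 1) {
  set.seed(seed)
  tr <- ape::rphylo(n, birth = birth_rate, death = 0)
  rates <- exp(rnorm(nrow(tr$edge), -rate_sd^2 / 2, rate_sd))
  tr$edge.length <- tr$edge.length * rates + burst
  tr$tip.label <- sprintf("L%03d", seq_len(n))
  tr
}
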