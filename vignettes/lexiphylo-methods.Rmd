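---
title: "Methods: from word lists to phylogenies"
author: "lexiphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from word lists to phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexiphylo)
```

# Overview

`lexiphylo` infers phylogenies of language varieties (*doculects*) from
short core-vocabulary word lists transcribed in a 41-symbol sound-class
alphabet, the transcription scheme used by large cross-linguistic
databases such as ASJP.  The pipeline has five stages:

1. learn a pointwise-mutual-information (PMI) substitution-scoring model
   between sound classes by iterative weighted alignment;
2. aggregate word-level alignment scores into calibrated pairwise
   language distances;
3. cluster words into cognate classes with a supervised classifier and
   label propagation;
4. extract binary character matrices (cognate classes;
   soundclass-concept characters) for character-based inference, and
   build distance-based BIONJ trees;
5. evaluate clusterings and trees (B-cubed scores, generalized quartet
   distance, Mantel correlograms) and test for punctuated evolution.

Maximum-likelihood tree search itself is out of scope: the package
produces the distance matrices, Phylip character files and partition
files that external phylogenetics engines consume.

# Transcription model

Words are sequences over 41 sound classes.  Raw transcriptions may carry
modifier characters: the juxtaposition markers `~` and `$` flag the
preceding two or three symbols as one sound (the cluster is reduced to
its first symbol, so an aspirated `th~` becomes `t`), and a small set of
marks (glottalization, the loanword flag, spaces) is dropped outright.
Both tables are data, not code — `sound_inventory()` accepts overrides —
because transcription conventions differ slightly between database
versions.  Normalization is total and idempotent on the documented
alphabet; unknown symbols are reported, not silently dropped.

Symbol occurrence probabilities $q(a)$ are token relative frequencies
over the collection actually being trained on, not a fixed global table:
the scoring model is a property of a corpus, and training on a subset
should use that subset's sound statistics.

# Alignment and the scoring model

The central quantity is the pointwise mutual information between sound
classes,

$$\mathrm{PMI}(a,b) = \log \frac{s(a,b)}{q(a)\,q(b)},$$

where $s(a,b)$ is the probability that $a$ corresponds to $b$ in a pair
of cognate words.  Matches between classes that correspond more often
than chance score positive; in a trained model every $\mathrm{PMI}(a,a)$
with non-trivial support is positive.

Word similarity is the maximal aggregate PMI over *licit* global
alignments: alignments in which a gap in one word is never immediately
followed by a gap in the other.  We enforce this exactly with a
three-state affine-gap Needleman-Wunsch recursion (match, gap-in-first,
gap-in-second) in which transitions between the two gap states are
forbidden.  A gap run of length $k$ costs
$\mathit{gap\_open} + (k-1)\,\mathit{gap\_extend}$; in particular a
length-1 gap is charged the opening penalty alone (a documented,
configurable convention).  Traceback ties are broken by a fixed
preference order so output alignments are deterministic; tie-breaking
never affects the score.  The recursion is implemented in C++ because
training re-aligns hundreds of thousands of short words.

# Learning the scores

Training bootstraps itself from nothing but the word lists:

1. **Screen.**  Language distances are first computed with the
   normalized Levenshtein similarity $1-\mathrm{LDN}$ in place of PMI;
   pairs at distance $\le 0.7$ count as *probably related*.  The
   threshold is conservative: it errs towards excluding genuinely
   related pairs rather than including unrelated ones.
2. **Potential cognates.**  For each related pair and each shared
   concept, the synonym pair with the lowest LDN (ties: first in input
   order) is a *potential cognate*.
3. **Initial estimate.**  Potential cognates are aligned with the
   unit-cost Levenshtein algorithm; aligned symbol pairs (gap columns
   excluded) are counted, pooled symmetrically — alignment is
   undirected — smoothed, and converted to log-odds scores.
4. **Refinement.**  For ten rounds, all potential cognates are
   re-aligned with the current scores and the candidate gap penalties;
   only pairs whose score reaches the threshold $\theta$ feed the next
   round's counts.  Ten rounds is part of the procedure's definition,
   not a convergence criterion, though in practice the retained-pair set
   stabilizes within a few rounds.
5. **Hyperparameters.**  $(\mathit{gap\_open}, \mathit{gap\_extend},
   \theta)$ are chosen by Nelder-Mead to minimize the mean calibrated
   distance between all probably related pairs under the refined scores.
   The related-pair set and the potential cognates are computed once
   from the LDN bootstrap and frozen during the search; re-screening
   inside the objective would change its domain between evaluations.
   Defaults: start $(-2.5, -1.75, 4.5)$, relative tolerance $10^{-3}$,
   budget 200 evaluations, all configurable; exceeding the budget
   returns the best parameters found so far with a warning.  On the full
   ASJP database this procedure is reported to land near
   $\mathit{gp}_1 \approx -2.33$, $\mathit{gp}_2 \approx -1.28$,
   $\theta \approx 4.40$; those values are reference points for real
   data, not constants of the package.

**Smoothing.**  Raw zero counts would give $-\infty$ scores, so add-$k$
smoothing ($k = 0.5$ by default) is applied to the aligned-pair counts
and, inside score estimation only, to the occurrence probabilities.  On
small corpora this pulls rare-symbol scores towards the prior;
`estimate_symbol_frequencies()` itself reports unsmoothed relative
frequencies.

# Calibrated language distances

Averaging raw similarities across concepts would confound relatedness
with sound-inventory overlap, synonym counts, and list length.  Instead,
for a doculect pair:

* the similarity of concept $c$ is the **maximum** over the synonym
  cross-product (robust to synonym-count imbalance);
* the similarity of every *cross*-concept pair $(c_1 \ne c_2)$ samples
  the distribution of non-cognate scores for exactly this pair of sound
  systems (cognates are assumed synonymous within a 40-concept core
  list, so cross-concept pairs are non-cognates);
* each concept gets the maximum-likelihood p-value of its score under
  that null, with the synonymous pair itself included in numerator and
  denominator:
  $p_c = \bigl(1 + \#\{\text{null} \ge \text{score}\}\bigr) /
  (1 + M)$, where $M$ is the null-sample size.  Ties count as $\ge$.
  This makes $p_c \in [1/(M+1), 1]$ and, for complete 40-item lists,
  reproduces the $40^2 - 40 + 1$ term in the distance bounds below.
* p-values are combined Fisher-style and normalized,
  $Z = \bigl(\sum_c -\log p_c - N\bigr)/\sqrt{N}$ over the $N$ shared
  concepts — under the null each $-\log p_c$ is approximately
  exponential with mean 1, so $Z$ is centred regardless of list length;
* $Z$ is rescaled to $[0,1]$ with the two closed-form bounds for
  complete lists,
  $Z_{\max} = (40 \log(40^2-40+1) - 40)/\sqrt{40} \approx 40.18$ and
  $Z_{\min} = -\sqrt{40} \approx -6.32$.  The bounds always use
  $N = 40$; the $\sqrt{N}$ normalization inside $Z$ already handles
  incomplete lists.

```{r}
z_constants()
```

The result is a dissimilarity, not a metric.  Pairs without shared
concepts are reported as missing, never as a fabricated value.  The null
sample is built from ordered cross-concept pairs in both directions, so
the distance is symmetric by construction.

# Supervised cognate clustering

For every synonymous cross-doculect word pair, seven features are
computed: the PMI alignment score (f1); its calibrated p-value against
the language pair's null sample (f2) and $-\log$ thereof (f3); the
language distance $d$ (f4) and $-\log(1-d)$ (f5, with $d$ capped at
$1 - 10^{-9}$ so degenerate pairs stay finite); the concept's average
word length over the collection (f6); and the per-concept Pearson
correlation between f3 and f4 (f7), computed once per concept and
cached.

An RBF-kernel support-vector machine is trained on labeled pairs (7,000
sampled pairs by default) and calibrated with Platt scaling; features
are standardized on the training sample because RBF kernels need
comparable scales.  Kernel width and regularization are the library
defaults and are recorded in the classifier object for reproducibility.
In gold-standard data, pairs from different families are labeled
non-cognate.  The class ratio of the training sample is left at its
natural value; it is exposed through the sampling seed rather than
forced, since the published procedure does not state a balancing rule.

Predicted probabilities feed a per-concept graph (edge iff probability
$\ge 0.25$) clustered by **label propagation**: labels start unique,
nodes are visited in random order and adopt their neighborhood's
majority label, ties are broken uniformly at random, and sweeps repeat
until a fixed point (at most 100).  The variant is pinned down here
because the algorithm family leaves it open; a fixed seed makes runs
reproducible, and communities never span graph components.  Concepts are
clustered independently, and class labels follow the `concept_serial`
convention.

Feature-subset selection enumerates all $2^7 - 1 = 127$ non-empty
subsets; each is scored by training on the pairs of a random sample of
families, clustering the held-out families' words, and averaging the
B-cubed F-score over ten random splits.  Family-wise splitting is
essential: random pair-level splits would leak near-duplicate pairs
between training and test.  The harness operates on a labeled pair
table, so it can run both on real gold standards (via
`gold_pair_table()`) and on constructed feature tables with known
informative features.

# Characters and trees

Two binary character systems are extracted, both with an explicit
undefined state wherever a doculect lacks the underlying concept:

* **cognate-class characters** — one column per inferred class, 1 iff
  the doculect's list contains a member (lexical replacement signal);
* **soundclass-concept characters** — one column per (concept, symbol)
  pair, 1 iff some word for the concept contains the symbol (sound
  change signal within surviving cognates; presence, not counts).

Only *variable* characters (both states among defined values of the
exported taxon set) are kept, filtered per exported sample.  Export is
relaxed Phylip with `?` for the undefined state (configurable to `-`)
plus a two-block binary-model partition file, the input conventions of
common maximum-likelihood engines.

Distance trees use the BIONJ agglomeration (via `ape`); negative branch
lengths, a known artifact of neighbor-joining arithmetic, are clamped to
zero with the clamped total reported.  Rooting is either by an outgroup
(chosen as the non-member with minimal mean distance to the family,
ties lexicographic; the outgroup is removed after rooting) or by the
midpoint of the longest tip-to-tip path.

# Evaluation statistics

* **B-cubed precision/recall/F** are item-averaged and invariant to
  cluster relabeling; F is 1 iff the partitions coincide.
* **Generalized quartet distance** is the fraction of reference-resolved
  four-taxon subsets whose resolution differs in the candidate tree;
  quartets the (possibly polytomous) reference leaves unresolved are not
  counted.  Inferred trees here are binary, so the denominator rule only
  matters for the reference.  Quartet resolutions are read off the
  four-point condition on topological (unit-branch) path lengths; exact
  enumeration is used up to 30 taxa, an unbiased quartet sample
  (default $10^5$, seeded) above.
* **Geography.**  Character rows are compared by cosine distance over
  jointly defined coordinates; geographic distances are great-circle
  (haversine, mean Earth radius 6371 km).  The Mantel test (Spearman by
  default) and a Mantel correlogram (1,000 km classes by default,
  oriented so that positive values mean short-range similarity) ask
  whether linguistic signal decays with distance, as common descent and
  contact predict.  Holm correction across distance classes is
  available but off by default.

# Punctuated evolution

If a disproportionate share of lexical change happens at splits, tips
that accumulated more branching events should show longer root-to-tip
paths (in change units).  Per family: root the tree by the nearest
outgroup; compute per-tip path lengths and counts of branching nodes;
screen with the **delta-test** — a log-log PGLS fit of
$n = \beta x^\delta$, the artifact being flagged when the 95% interval
for $\delta$ lies entirely above 1 (the interval-based reading; the
test's source leaves the variant open); then regress node counts on
path lengths by **PGLS** with Brownian residual covariance on the given
branch lengths (no extra transformation).  A family shows evidence for
punctuation when the delta-test is negative and the slope is
significantly positive after Holm-Bonferroni correction across the
delta-negative families.

The PGLS estimate is computed in closed form,
$\hat\beta = (X^\top V^{-1} X)^{-1} X^\top V^{-1} y$ with $V$ the full
Brownian covariance, rather than through a correlation-structure fit:
generic GLS machinery that normalizes $V$ to a correlation matrix
silently drops the tip-specific variances that non-ultrametric,
change-scaled trees have.  The closed form is exact, and the test suite
cross-checks it against `nlme::gls` with the Brownian correlation plus
fixed variance weights, which together reconstruct the same covariance.

A caveat worth stating: under strong, low-noise punctuation the
node-count/path-length relation becomes so clean that the delta-test
itself can fire, and the conjunction rule then withholds the verdict.
This is a property of the published screening procedure, not of the
implementation; with realistic rate heterogeneity the screen behaves as
intended.

# The synthetic generator

`simulate_wordlists()` provides ground-truthed data: a Yule tree
(`n_languages` tips, unit birth rate), root words drawn i.i.d. over the
alphabet, and along each branch (i) Poisson lexical replacement per
concept, each event starting a new word and a new cognate class, (ii) a
symbol-level Markov jump substitution process steered by a
row-stochastic propensity matrix, and (iii) Poisson indels.  The default
propensity concentrates 75% of substitution mass within coarse
articulatory groups (vowels, labials, coronals, dorsals), giving PMI
training a recoverable target: learned scores should rank-correlate
with the true propensities.  Doculect coordinates drift by Brownian
motion on the tree so that geographic and phylogenetic distances are
correlated, which the Mantel machinery can be exercised against.
Cognate classes never span concepts, matching the assumption that
cross-concept cognacy is negligible in a 40-item core list.

Default rates (substitution 0.2 per symbol, indel 0.05 per site,
replacement 0.15 per concept, all per unit time; mean word length 4.5)
emulate a single family of moderate depth: on a 30-tip Yule tree the
most divergent pairs retain roughly a third of their cognates and
shared cognates differ at a substantial fraction of segments.  What the
generator does **not** emulate: realistic phonotactics, borrowing and
contact, synonym-count biases, and transcription noise.  Passing
recovery tests on synthetic data therefore demonstrates internal
consistency of the pipeline — signal in, signal out — not performance
on real transcriptions.

A separate generator, `simulate_rate_tree()`, produces trees whose
branch lengths are time scaled by lognormal rate noise, optionally with
a constant burst added per branch; it is the calibration bed for the
punctuation test (false-positive rate under the gradual model at the
nominal level; burst recovery under the punctuational model).

# Problem sizes and numerical choices

The test suite runs the full pipeline at desk scale: 30 languages for
end-to-end recovery (hyperparameter search capped at 60 objective
evaluations there), 6 families by 8 languages for gold-standard
training, 200 simulated pairs for the null-calibration check, 100
replicates for the punctuation calibration, and reduced training sizes
(500 pairs) for the 127-subset selection harness.  Alignment scores are
exact dynamic programming, not heuristics; the score table is symmetric
within $10^{-9}$; distance matrices are symmetric within $10^{-12}$.
Degenerate inputs fail loudly: empty transcriptions, unknown symbols,
pairs without shared concepts, references without resolved quartets,
constant path lengths in the delta-test, and thresholds no pair reaches
all raise errors with the offending quantity named.

# Known limitations

* The calibrated distance is not a metric; distance-based trees are
  similarity groupings, and character-based inference on the exported
  matrices is the intended refinement.
* Loanwords are not modeled; contact shows up as signal, as the
  geography analysis makes explicit.
* Word lists of 40 concepts cannot support per-language-pair sound
  correspondences; the PMI table is a global propensity model.
* The Nelder-Mead objective is non-convex; different starts can land in
  different optima.  The defaults are a reasonable basin for sound-class
  data, and the evaluation trace is returned for inspection.
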