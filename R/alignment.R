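# String comparison: normalized Levenshtein distance and maximal-PMI
# global alignment under the licit-alignment restriction.

#' Substitution scoring model
#'
#' A symmetric table of pointwise-mutual-information (PMI) scores between
#' sound classes, in log-odds units, together with affine gap penalties and
#' the cognacy threshold used during score re-estimation.  A gap run of
#' length k is charged `gap_open + (k - 1) * gap_extend`.
#'
#' @param pmi square numeric matrix with the inventory symbols as dimnames.
#' @param gap_open,gap_extend gap penalties (non-positive in trained models).
#' @param theta cognacy threshold used when re-estimating scores.
#' @param inventory the [sound_inventory()] the scores refer to.
#' @return an object of class `scoring_model`.
#' @export
scoring_model <- function(pmi, gap_open, gap_extend, theta = NA_real_,
                          inventory = sound_inventory()) {
  pmi <- as.matrix(pmi)
  ns <- length(inventory$symbols)
  if (!all(dim(pmi) == c(ns, ns))) stop("pmi must be ", ns, "x", ns)
  if (is.null(dimnames(pmi))) dimnames(pmi) <- list(inventory$symbols, inventory$symbols)
  if (max(abs(pmi - t(pmi))) > 1e-9) stop("pmi table must be symmetric")
  structure(list(pmi = pmi, gap_open = gap_open, gap_extend = gap_extend,
                 theta = theta, inventory = inventory),
            class = "scoring_model")
}

#' @export
print.scoring_model <- function(x, ...) {
  cat("PMI scoring model over", nrow(x$pmi), "sound classes\n")
  cat(sprintf("  gap_open = %.4f, gap_extend = %.4f, theta = %.4f\n",
              x$gap_open, x$gap_extend, x$theta))
  invisible(x)
}

#' Normalized Levenshtein distance
#'
#' Edit distance divided by the length of the longer string; 0 iff the
#' strings are equal, 1 at maximal dissimilarity.  Vectorized over pairs.
#'
#' @param x,y character vectors of equal length (recycled).
#' @return numeric vector in \[0, 1\].
#' @examples
#' ldn("sole", "sole")  # 0
#' ldn("ab", "b")       # 0.5
#' @export
ldn <- function(x, y) {
  if (any(!nzchar(x)) || any(!nzchar(y))) stop("empty sequence")
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  d <- diag(utils::adist(x, y))
  d / pmax(nchar(x), nchar(y))
}

# 1 - LDN similarity matrix between two word vectors.
ldn_sim_matrix <- function(wx, wy) {
  1 - utils::adist(wx, wy) / outer(nchar(wx), nchar(wy), pmax)
}

#' Maximal-PMI pairwise alignment
#'
#' Global alignment of two sound sequences maximizing the aggregate PMI
#' score, restricted to licit alignments (a gap in one sequence is never
#' immediately followed by a gap in the other).  Computed by a three-state
#' affine-gap Needleman-Wunsch recursion in which transitions between the
#' two gap states are forbidden.  Traceback ties are broken with the fixed
#' preference match > gap in second sequence > gap in first sequence.
#'
#' @param x,y normalized transcriptions (single strings).
#' @param model a [scoring_model()].
#' @return a list of class `pairwise_alignment` with elements `aligned_x`,
#'   `aligned_y` (gapped strings of equal length, gap symbol `-`) and
#'   `score`.
#' @export
pmi_align <- function(x, y, model) {
  inv <- model$inventory
  ex <- encode_word(x, inv); ey <- encode_word(y, inv)
  al <- cpp_pmi_align(ex, ey, model$pmi, model$gap_open, model$gap_extend)
  gapchr <- function(v) paste(ifelse(v == 0, "-", inv$symbols[pmax(v, 1)]),
                              collapse = "")
  structure(list(aligned_x = gapchr(al$ax), aligned_y = gapchr(al$ay),
                 score = al$score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(x$aligned_x, "\n", x$aligned_y, "\n", sep = "")
  cat(sprintf("score: %.4f\n", x$score))
  invisible(x)
}

#' Maximal-PMI alignment score
#'
#' Score-only variant of [pmi_align()]; vectorized over pairs.
#'
#' @inheritParams pmi_align
#' @return numeric vector of alignment scores.
#' @export
pmi_similarity <- function(x, y, model) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  inv <- model$inventory
  vapply(seq_len(n), function(i)
    cpp_pmi_score(encode_word(x[i], inv), encode_word(y[i], inv),
                  model$pmi, model$gap_open, model$gap_extend),
    numeric(1))
}

#' Serialize / read a scoring model
#'
#' The model is stored as a CSV score table (`pmiScores.csv`) plus a
#' `key=value` sidecar (`gapPenalties.csv`) holding the gap penalties and
#' the threshold.
#'
#' @param model a [scoring_model()].
#' @param dir directory to write to (created if needed).
#' @return `dir`, invisibly (`read_scoring_model` returns the model).
#' @export
write_scoring_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(model$pmi, file.path(dir, "pmiScores.csv"))
  writeLines(c(sprintf("gap_open=%.17g", model$gap_open),
               sprintf("gap_extend=%.17g", model$gap_extend),
               sprintf("theta=%.17g", model$theta)),
             file.path(dir, "gapPenalties.csv"))
  invisible(dir)
}

#' @rdname write_scoring_model
#' @param inventory the [sound_inventory()] for the restored model.
#' @export
read_scoring_model <- function(dir, inventory = sound_inventory()) {
  pmi <- as.matrix(utils::read.csv(file.path(dir, "pmiScores.csv"),
                                   row.names = 1, check.names = FALSE))
  kv <- strsplit(readLines(file.path(dir, "gapPenalties.csv")), "=", fixed = TRUE)
  vals <- setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                   vapply(kv, `[`, character(1), 1))
  scoring_model(pmi, vals[["gap_open"]], vals[["gap_extend"]],
                vals[["theta"]], inventory)
}
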