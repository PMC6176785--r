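# Binary character extraction (cognate-class and soundclass-concept
# characters) and phylogenetics-ready export.
#
# A character matrix is a taxa x characters matrix over {0, 1, NA}; NA
# marks the undefined state (the underlying concept is missing from the
# taxon's word list).

#' Cognate-class characters
#'
#' One binary character per cognate class: a taxon scores 1 if its word
#' list contains a member of the class, 0 if it has words for the class's
#' concept but none in the class, and undefined (NA) if the concept is
#' missing from its list.
#'
#' @param assignment cognate-class assignment (data frame `doculect`,
#'   `concept`, `word`, `class`), e.g. from [cluster_collection()].
#' @param collection the [wordlist_collection()] the assignment covers.
#' @return numeric matrix (taxa x classes) over \{0, 1, NA\}.
#' @export
cognate_characters <- function(assignment, collection) {
  taxa <- doculect_names(collection)
  classes <- sort(unique(assignment$class))
  class_concept <- assignment$concept[match(classes, assignment$class)]
  m <- matrix(NA_real_, length(taxa), length(classes),
              dimnames = list(taxa, classes))
  has_concept <- table(collection$entries$doculect, collection$entries$concept) > 0
  for (j in seq_along(classes)) {
    cc <- class_concept[j]
    defined <- taxa[has_concept[taxa, cc]]
    m[defined, j] <- 0
  }
  hit <- unique(assignment[, c("doculect", "class")])
  m[cbind(hit$doculect, hit$class)] <- 1
  m
}

#' Soundclass-concept characters
#'
#' One binary character per (concept, symbol) pair with any support: a
#' taxon scores 1 if one of its words for the concept contains the symbol,
#' 0 otherwise, and NA if the concept is missing from its list.
#'
#' @param collection a [wordlist_collection()].
#' @return numeric matrix (taxa x `concept:symbol` characters).
#' @export
soundclass_concept_characters <- function(collection) {
  taxa <- doculect_names(collection)
  ent <- collection$entries
  sym_sets <- lapply(strsplit(ent$transcription, "", fixed = TRUE), unique)
  long <- data.frame(doculect = rep(ent$doculect, lengths(sym_sets)),
                     concept = rep(ent$concept, lengths(sym_sets)),
                     symbol = unlist(sym_sets), stringsAsFactors = FALSE)
  chars <- sort(unique(paste0(long$concept, ":", long$symbol)))
  char_concept <- sub(":.*$", "", chars)
  m <- matrix(NA_real_, length(taxa), length(chars),
              dimnames = list(taxa, chars))
  has_concept <- table(ent$doculect, ent$concept) > 0
  for (j in seq_along(chars)) {
    defined <- taxa[has_concept[taxa, char_concept[j]]]
    m[defined, j] <- 0
  }
  m[cbind(long$doculect, paste0(long$concept, ":", long$symbol))] <- 1
  m
}

#' Filter to variable characters
#'
#' Keeps only characters showing both states (at least one 0 and one 1
#' among defined values) within the given taxon subset; column order is
#' preserved.  Errors if no character is variable.
#'
#' @param m character matrix over \{0, 1, NA\}.
#' @param taxa taxon subset (default: all rows).
#' @return the filtered matrix, restricted to `taxa`.
#' @export
filter_variable <- function(m, taxa = rownames(m)) {
  sub <- m[taxa, , drop = FALSE]
  keep <- apply(sub, 2, function(v) any(v == 1, na.rm = TRUE) &&
                  any(v == 0, na.rm = TRUE))
  if (!any(keep)) stop("no variable characters in the sample")
  sub[, keep, drop = FALSE]
}

#' Export character matrices for phylogenetic inference
#'
#' Writes the combined matrix (cognate-class columns first, then
#' soundclass-concept columns) in relaxed Phylip format, with a two-block
#' binary-model partition file delimiting the column ranges, plus CSV
#' dumps of both matrices.  Columns with no defined value for the exported
#' taxa are dropped.
#'
#' @param cc cognate-class character matrix.
#' @param sc soundclass-concept character matrix (same taxa).
#' @param prefix output path prefix; writes `<prefix>.cc_sc.phy`,
#'   `<prefix>.part.txt`, `<prefix>.cc.csv`, `<prefix>.sc.csv`.
#' @param missing character used for the undefined state (default `"?"`).
#' @return named character vector of the written paths, invisibly.
#' @export
export_character_files <- function(cc, sc, prefix, missing = "?") {
  if (!identical(rownames(cc), rownames(sc)))
    stop("character matrices must share taxa")
  drop_empty <- function(m) m[, colSums(!is.na(m)) > 0, drop = FALSE]
  cc <- drop_empty(cc); sc <- drop_empty(sc)
  comb <- cbind(cc, sc)
  paths <- c(phy = paste0(prefix, ".cc_sc.phy"),
             part = paste0(prefix, ".part.txt"),
             cc = paste0(prefix, ".cc.csv"),
             sc = paste0(prefix, ".sc.csv"))
  write_phylip(comb, paths["phy"], missing = missing)
  writeLines(c(sprintf("BIN, cc = 1-%d", ncol(cc)),
               sprintf("BIN, sc = %d-%d", ncol(cc) + 1, ncol(comb))),
             paths["part"])
  write.csv(cc, paths["cc"])
  write.csv(sc, paths["sc"])
  invisible(paths)
}

#' Relaxed Phylip read/write for binary character matrices
#'
#' @param m character matrix over \{0, 1, NA\}.
#' @param path file path.
#' @param missing character encoding the undefined state.
#' @export
write_phylip <- function(m, path, missing = "?") {
  rows <- apply(m, 1, function(v) {
    v <- ifelse(is.na(v), missing, format(v))
    paste(v, collapse = "")
  })
  writeLines(c(sprintf("%d %d", nrow(m), ncol(m)),
               paste(rownames(m), rows)), path)
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path, missing = "?") {
  ln <- readLines(path)
  dims <- as.integer(strsplit(trimws(ln[1]), "\\s+")[[1]])
  parts <- strsplit(trimws(ln[-1]), "\\s+")
  taxa <- vapply(parts, `[`, character(1), 1)
  vals <- t(vapply(parts, function(p) {
    ch <- strsplit(p[2], "", fixed = TRUE)[[1]]
    ifelse(ch == missing, NA_real_, as.numeric(ch))
  }, numeric(dims[2])))
  if (dims[2] == 1) vals <- matrix(vals, ncol = 1)
  rownames(vals) <- taxa
  vals
}
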