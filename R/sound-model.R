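# Sound-class inventory and transcription normalization.

.ASJP_SYMBOLS <- c(
  # vowels
  "i", "e", "E", "3", "a", "u", "o",
  # consonants
  "p", "b", "m", "f", "v", "w",
  "8", "4", "t", "d", "s", "z", "c", "n", "r", "l",
  "S", "Z", "C", "j", "T", "5", "L",
  "y", "k", "g", "x", "N", "q", "G", "X", "7", "h", "!"
)

#' Sound-class inventory
#'
#' The 41-symbol sound-class alphabet used for phonetic transcription, a
#' table of modifier (diacritic) conventions removed during normalization,
#' and, optionally, symbol occurrence probabilities `q`.
#'
#' The modifier conventions follow the transcription code of the ASJP
#' database: the juxtaposition markers `~` and `$` mark the preceding two
#' (resp. three) symbols as jointly representing a single sound, and such a
#' cluster is reduced to its first symbol; the characters in `drop`
#' (glottalization/nasalization marks, the loanword flag, spaces) are
#' removed outright.  Both tables are arguments, so users can override them.
#'
#' @param q optional named numeric vector of occurrence probabilities over
#'   the 41 symbols (must sum to 1).
#' @param symbols character vector of sound-class codes (default: the 41
#'   ASJP classes).
#' @param drop modifier characters removed during normalization.
#' @param join2,join3 juxtaposition markers reducing the preceding two
#'   (three) symbols to the first one.
#' @return an object of class `sound_inventory`.
#' @export
sound_inventory <- function(q = NULL, symbols = .ASJP_SYMBOLS,
                            drop = c('"', "*", "'", "%", " "),
                            join2 = "~", join3 = "$") {
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) stop("duplicated inventory symbols")
  if (any(c(drop, join2, join3) %in% symbols))
    stop("modifier characters must not coincide with inventory symbols")
  if (!is.null(q)) {
    q <- q[symbols]
    q[is.na(q)] <- 0
    names(q) <- symbols
    if (any(q < 0)) stop("negative occurrence probability")
    if (abs(sum(q) - 1) > 1e-9) stop("occurrence probabilities must sum to 1")
  }
  structure(list(symbols = symbols, drop = drop, join2 = join2,
                 join3 = join3, q = q),
            class = "sound_inventory")
}

#' @export
print.sound_inventory <- function(x, ...) {
  cat("Sound inventory:", length(x$symbols), "symbols\n")
  cat(" ", paste(x$symbols, collapse = " "), "\n")
  if (!is.null(x$q)) cat("  with occurrence probabilities\n")
  invisible(x)
}

#' Read a sound inventory from a plain-text config
#'
#' Parses the editable inventory/modifier table shipped at
#' `system.file("extdata", "asjp_inventory.txt", package = "lexiphylo")`
#' (or a user-supplied copy): `#` starts a comment, and each line is a
#' whitespace-separated `key values...` record with keys `symbols`,
#' `drop`, `join2`, `join3`.  The space character may not appear in the
#' file format itself and is always treated as dropped.
#'
#' @param path config file (default: the shipped table).
#' @return a [sound_inventory()].
#' @export
read_sound_inventory <- function(path = system.file("extdata",
                                                    "asjp_inventory.txt",
                                                    package = "lexiphylo")) {
  ln <- readLines(path)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  parts <- strsplit(ln, "\\s+")
  tab <- setNames(lapply(parts, `[`, -1), vapply(parts, `[`, character(1), 1))
  need <- c("symbols", "drop", "join2", "join3")
  if (!all(need %in% names(tab)))
    stop("inventory config lacks key(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  sound_inventory(symbols = tab$symbols, drop = c(tab$drop, " "),
                  join2 = tab$join2[1], join3 = tab$join3[1])
}

#' Normalize a raw transcription to the sound-class alphabet
#'
#' Removes modifier characters and reduces marked symbol clusters (e.g. an
#' aspirated stop written as a two-symbol cluster, `"th~"`) to their first
#' symbol, returning a string over the 41 sound classes only.  The operation
#' is idempotent.
#'
#' @param raw character vector of raw transcriptions.
#' @param inventory a [sound_inventory()].
#' @return character vector of normalized transcriptions.
#' @examples
#' normalize_transcription("th~")  # aspirated t -> plain t
#' normalize_transcription("sole")
#' @export
normalize_transcription <- function(raw, inventory = sound_inventory()) {
  if (any(!nzchar(raw) | is.na(raw))) stop("empty transcription")
  vapply(raw, function(w) {
    ch <- strsplit(w, "", fixed = TRUE)[[1]]
    ch <- ch[!ch %in% inventory$drop]
    out <- character(0)
    for (s in ch) {
      if (s == inventory$join2 || s == inventory$join3) {
        k <- if (s == inventory$join2) 1L else 2L
        if (length(out) < k + 1L)
          stop("malformed cluster marker in '", w, "'")
        out <- out[seq_len(length(out) - k)]
      } else {
        out <- c(out, s)
      }
    }
    bad <- setdiff(out, inventory$symbols)
    if (length(bad))
      stop("unknown symbol(s) in '", w, "': ", paste(bad, collapse = " "))
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Integer encoding of a normalized word (1-based index into the inventory).
encode_word <- function(word, inventory = sound_inventory()) {
  idx <- match(strsplit(word, "", fixed = TRUE)[[1]], inventory$symbols)
  if (anyNA(idx)) stop("word '", word, "' not over the inventory")
  idx
}

decode_word <- function(idx, inventory = sound_inventory()) {
  paste(inventory$symbols[idx], collapse = "")
}

#' Word-list collection
#'
#' Bundles doculect metadata (family, genus, coordinates) with per-concept
#' transcription lists.  Transcriptions are normalized to the sound-class
#' alphabet on construction; synonyms are kept in input order.
#'
#' @param doculects data frame with columns `name`, `family`, `genus`,
#'   `latitude`, `longitude` (coordinates may be `NA`).
#' @param entries data frame with columns `doculect`, `concept`,
#'   `transcription`; one synonym per row.  Rows with empty transcriptions
#'   are dropped (the concept is then missing for that doculect).
#' @param inventory a [sound_inventory()].
#' @param normalize whether to run [normalize_transcription()] on the
#'   entries (set `FALSE` if they already are normalized).
#' @return an object of class `wordlist_collection`.
#' @export
wordlist_collection <- function(doculects, entries,
                                inventory = sound_inventory(),
                                normalize = TRUE) {
  need <- c("name", "family", "genus", "latitude", "longitude")
  missing_cols <- setdiff(need, names(doculects))
  if (length(missing_cols) == 2 && all(c("latitude", "longitude") %in% missing_cols)) {
    doculects$latitude <- NA_real_
    doculects$longitude <- NA_real_
  } else if (length(missing_cols)) {
    stop("doculects lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  doculects$name <- as.character(doculects$name)
  if (anyDuplicated(doculects$name))
    stop("duplicate doculect name(s): ",
         paste(unique(doculects$name[duplicated(doculects$name)]), collapse = ", "))
  entries <- entries[!is.na(entries$transcription) & nzchar(entries$transcription), , drop = FALSE]
  entries$doculect <- as.character(entries$doculect)
  entries$concept <- as.character(entries$concept)
  if (!all(entries$doculect %in% doculects$name))
    stop("entries refer to unknown doculect(s)")
  if (normalize)
    entries$transcription <- normalize_transcription(entries$transcription, inventory)
  rownames(doculects) <- NULL
  rownames(entries) <- NULL
  obj <- structure(list(doculects = doculects,
                        entries = entries[, c("doculect", "concept", "transcription")],
                        inventory = inventory),
                   class = "wordlist_collection")
  obj$cache <- .build_lang_cache(obj)
  obj
}

# Per-doculect view: words, concepts, integer encodings.
.build_lang_cache <- function(collection) {
  inv <- collection$inventory
  sp <- split(collection$entries[, c("concept", "transcription")],
              factor(collection$entries$doculect, levels = collection$doculects$name))
  lapply(sp, function(df) {
    list(concept = df$concept,
         word = df$transcription,
         enc = lapply(df$transcription, encode_word, inventory = inv))
  })
}

#' @export
print.wordlist_collection <- function(x, ...) {
  cat("Word-list collection:", nrow(x$doculects), "doculects,",
      length(unique(x$entries$concept)), "concepts,",
      nrow(x$entries), "entries\n")
  invisible(x)
}

#' @rdname wordlist_collection
#' @param collection a `wordlist_collection`.
#' @export
doculect_names <- function(collection) collection$doculects$name

#' @rdname wordlist_collection
#' @export
concept_names <- function(collection) sort(unique(collection$entries$concept))

# Words of one doculect (optionally one concept).
lang_words <- function(collection, doculect, concept = NULL) {
  lw <- collection$cache[[doculect]]
  if (is.null(lw)) stop("unknown doculect: ", doculect)
  if (is.null(concept)) return(lw)
  keep <- lw$concept == concept
  list(concept = lw$concept[keep], word = lw$word[keep], enc = lw$enc[keep])
}

#' Read a word-list collection from delimited text
#'
#' Expects UTF-8 delimited text (tab-separated by default; comma-separated
#' for `.csv` files) with header columns `doculect`, `family`, `genus`,
#' `latitude`, `longitude`, `concept`, `transcription`, one synonym per row.
#' Rows whose coordinates fail to parse keep the doculect but drop the
#' coordinates, with a warning.
#'
#' @param path file path.
#' @param sep field separator; guessed from the file extension by default.
#' @param inventory a [sound_inventory()].
#' @return a [wordlist_collection()].
#' @export
parse_wordlists <- function(path, sep = NULL, inventory = sound_inventory()) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", quote = "\"")
  need <- c("doculect", "family", "genus", "concept", "transcription")
  if (!all(need %in% names(raw)))
    stop("word-list file lacks column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  lat <- suppressWarnings(as.numeric(raw$latitude))
  lon <- suppressWarnings(as.numeric(raw$longitude))
  bad <- (!is.na(raw$latitude) & nzchar(raw$latitude) & is.na(lat)) |
    (!is.na(raw$longitude) & nzchar(raw$longitude) & is.na(lon))
  if (any(bad))
    warning(sum(bad), " row(s) with malformed coordinates; coordinates dropped")
  first <- !duplicated(raw$doculect)
  doculects <- data.frame(name = raw$doculect[first],
                          family = raw$family[first],
                          genus = raw$genus[first],
                          latitude = lat[first],
                          longitude = lon[first],
                          stringsAsFactors = FALSE)
  entries <- data.frame(doculect = raw$doculect, concept = raw$concept,
                        transcription = raw$transcription,
                        stringsAsFactors = FALSE)
  wordlist_collection(doculects, entries, inventory)
}

#' Write a word-list collection to delimited text
#'
#' @param collection a [wordlist_collection()].
#' @param path output file; tab-separated unless it ends in `.csv`.
#' @param extra optional data frame of extra per-entry columns (same row
#'   order as `collection$entries`), e.g. cognate-class labels.
#' @export
write_wordlists <- function(collection, path, extra = NULL) {
  d <- collection$doculects
  i <- match(collection$entries$doculect, d$name)
  out <- data.frame(doculect = collection$entries$doculect,
                    family = d$family[i], genus = d$genus[i],
                    latitude = d$latitude[i], longitude = d$longitude[i],
                    concept = collection$entries$concept,
                    transcription = collection$entries$transcription,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Estimate symbol occurrence probabilities
#'
#' Token relative frequencies of each sound class over all entries of the
#' collection.  Symbols never observed get probability 0.
#'
#' @param collection a [wordlist_collection()].
#' @return a [sound_inventory()] with the `q` slot filled.
#' @export
estimate_symbol_frequencies <- function(collection) {
  if (nrow(collection$entries) == 0) stop("empty collection")
  inv <- collection$inventory
  counts <- symbol_counts(collection)
  sound_inventory(q = counts / sum(counts), symbols = inv$symbols,
                  drop = inv$drop, join2 = inv$join2, join3 = inv$join3)
}

# Raw token counts per symbol.
symbol_counts <- function(collection) {
  inv <- collection$inventory
  tok <- unlist(lapply(collection$cache, `[[`, "enc"), use.names = FALSE)
  counts <- tabulate(tok, nbins = length(inv$symbols))
  names(counts) <- inv$symbols
  counts
}

#' Export-style taxon labels
#'
#' The `FAMILY.GENUS.DOCULECT` upper-case naming convention used in
#' distance and character exports.
#'
#' @param collection a [wordlist_collection()].
#' @return character vector, one label per doculect.
#' @export
taxon_labels <- function(collection) {
  d <- collection$doculects
  toupper(paste(d$family, d$genus, d$name, sep = "."))
}
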