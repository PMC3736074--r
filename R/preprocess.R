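#' Tokenize raw message text
#'
#' Tokens are maximal runs of letters, digits and apostrophes; everything
#' else (punctuation, whitespace, hyphens) is a separator.  Output is
#' lowercased.  The rule is deliberately frozen so feature counts are
#' reproducible across runs and platforms.
#'
#' @param text character vector of raw message texts.
#' @return For a single string, a character vector of tokens; for a vector,
#'   a list of token vectors.
#' @examples
#' tokenize("I had chemo, then surgery.")
#' tokenize("HER2-positive")
#' @export
tokenize <- function(text) {
  lower <- tolower(enc2utf8(as.character(text)))
  hits <- regmatches(lower, gregexpr("[\\p{L}\\p{N}']+", lower, perl = TRUE))
  hits <- lapply(hits, function(x) if (length(x) == 1 && is.na(x)) character() else x)
  if (length(text) == 1) hits[[1]] else hits
}

#' Load a stop-word list
#'
#' Plain-text format: one word per line, `#` starts a comment, blank lines
#' ignored.  Words are lowercased.  With no arguments, loads the list
#' shipped with the package (a standard small English function-word list).
#'
#' @param path path to a stop-word file, or `NULL` for the bundled default.
#' @return Character vector of lowercase stop words.
#' @export
load_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords.txt", package = "healthtopics")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(tolower(lines[nzchar(lines)]))
}

#' Remove stop words from a token vector
#'
#' Order-preserving filter; tokens found in `stoplist` are dropped.
#'
#' @param tokens character vector of lowercase tokens.
#' @param stoplist character vector of lowercase stop words.
#' @return Filtered token vector.
#' @export
remove_stopwords <- function(tokens, stoplist) {
  tokens[!(tokens %in% stoplist)]
}

#' Preprocess one message into raw and stemmed token streams
#'
#' `raw_tokens` are the lowercased word tokens of the text; they feed
#' lexicon matching (domain and sentiment terms are dictionary forms, so
#' they are matched unstemmed).  `stemmed_tokens` are the raw tokens after
#' stop-word removal and Porter stemming; they feed n-gram extraction.
#' Note the order: stop words are removed *before* stemming and before
#' n-gram formation, so bigrams may span a removed stop word.
#'
#' @param text one raw message text.
#' @param stoplist character vector of lowercase stop words.
#' @return A list with `raw_tokens` and `stemmed_tokens`.
#' @export
preprocess_message <- function(text, stoplist = load_stopwords()) {
  raw <- tokenize(text)
  list(raw_tokens = raw,
       stemmed_tokens = porter_stem(remove_stopwords(raw, stoplist)))
}

#' Preprocess every message of a corpus
#'
#' Runs [preprocess_message()] over the corpus once; the result can be
#' passed to the feature-extraction functions to avoid re-tokenizing inside
#' cross-validation folds (preprocessing is per-message and leakage-free).
#'
#' @param corp a `topic_corpus`.
#' @param stoplist character vector of lowercase stop words.
#' @return A list (one element per message, in corpus order) of
#'   `raw_tokens` / `stemmed_tokens` pairs, named by message id.
#' @export
preprocess_corpus <- function(corp, stoplist = load_stopwords()) {
  stopifnot(inherits(corp, "topic_corpus"))
  raws <- tokenize(corp$messages$text)
  if (nrow(corp$messages) == 1) raws <- list(raws)
  # stem the corpus vocabulary once, then map per message
  all_kept <- lapply(raws, remove_stopwords, stoplist = stoplist)
  vocab <- unique(unlist(all_kept, use.names = FALSE))
  stem_map <- porter_stem(vocab)
  names(stem_map) <- vocab
  out <- vector("list", length(raws))
  for (k in seq_along(raws)) {
    kept <- all_kept[[k]]
    out[[k]] <- list(raw_tokens = raws[[k]],
                     stemmed_tokens = unname(stem_map[kept]))
  }
  names(out) <- corp$messages$id
  out
}
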