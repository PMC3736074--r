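# Feature extraction: the three feature families (word n-grams, medical
# domain terms, sentiment terms) and the incremental feature sets FS1-FS4.
# Values are binary presence indicators throughout (bag-of-words).

#' Enumerate contiguous n-grams of a token vector
#'
#' All contiguous n-grams for n = 1..`n_max`, space-joined, *with
#' multiplicity* (a repeated n-gram appears repeatedly).  For a token list
#' of length L >= n_max = 3 this yields exactly 3L - 3 n-grams.
#'
#' @param tokens character vector (normally stemmed tokens).
#' @param n_max maximal n-gram order, between 1 and 3.
#' @return Character vector of n-grams with multiplicity.
#' @export
extract_ngrams <- function(tokens, n_max = 3) {
  stopifnot(n_max >= 1, n_max <= 3)
  L <- length(tokens)
  if (!L) return(character())
  out <- list(tokens)
  if (n_max >= 2 && L >= 2) {
    out[[2]] <- paste(tokens[-L], tokens[-1])
  }
  if (n_max >= 3 && L >= 3) {
    out[[3]] <- paste(tokens[1:(L - 2)], tokens[2:(L - 1)], tokens[3:L])
  }
  unlist(out, use.names = FALSE)
}

# internal: coerce corpus-or-token-cache into a token cache
.as_token_cache <- function(x, stoplist) {
  if (inherits(x, "topic_corpus")) preprocess_corpus(x, stoplist) else x
}

#' Build the frequency-thresholded n-gram vocabulary
#'
#' An n-gram enters the vocabulary iff its occurrence count over the whole
#' corpus reaches the frequency threshold (`>=` convention; count with
#' multiplicity by default, or per-document with `count = "document"`).
#' The default threshold of 20 is the value at which classification
#' accuracy peaks in frequency-threshold sweeps on forum-scale corpora.
#'
#' @param x a `topic_corpus`, or a token cache from [preprocess_corpus()].
#' @param freq_threshold minimum count, `>= 1`.
#' @param n_max maximal n-gram order (1-3).
#' @param count `"total"` (occurrences, with multiplicity) or `"document"`
#'   (number of messages containing the n-gram).
#' @param stoplist stop words, used only when `x` is a corpus.
#' @return Data frame of n-gram descriptors (`namespace = "ngram"`, `key`,
#'   `order`), sorted by key.
#' @export
build_ngram_vocabulary <- function(x, freq_threshold = 20, n_max = 3,
                                   count = c("total", "document"),
                                   stoplist = load_stopwords()) {
  count <- match.arg(count)
  stopifnot(freq_threshold >= 1)
  toks <- .as_token_cache(x, stoplist)
  grams <- lapply(toks, function(t) {
    g <- extract_ngrams(t$stemmed_tokens, n_max)
    if (count == "document") unique(g) else g
  })
  all <- unlist(grams, use.names = FALSE)
  if (!length(all)) {
    return(data.frame(namespace = character(), key = character(),
                      order = integer(), stringsAsFactors = FALSE))
  }
  tab <- table(all)
  keys <- names(tab)[tab >= freq_threshold]
  keys <- sort(keys, method = "radix")
  data.frame(namespace = rep("ngram", length(keys)),
             key = keys,
             order = lengths(strsplit(keys, " ", fixed = TRUE)),
             stringsAsFactors = FALSE)
}

#' Match medical domain terms in a token stream
#'
#' Greedy left-to-right longest-match of lexicon phrases (up to 3 words)
#' against the raw lowercased tokens.  Matched spans do not overlap: when
#' the lexicon holds both `"breast cancer"` and `"cancer"`, the phrase
#' consumes its tokens and only `"breast cancer"` is reported.
#'
#' @param raw_tokens lowercased, unstemmed tokens of one message.
#' @param lexicon a `domain_lexicon`.
#' @return Character vector of distinct matched terms (set semantics).
#' @export
extract_domain_features <- function(raw_tokens, lexicon) {
  stopifnot(inherits(lexicon, "domain_lexicon"))
  idx <- .lexicon_index(lexicon)
  n <- length(raw_tokens)
  maxw <- min(lexicon$max_words, 3L)
  found <- character(0)
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (L in seq.int(min(maxw, n - i + 1L), 1L)) {
      phrase <- paste(raw_tokens[i:(i + L - 1L)], collapse = " ")
      if (exists(phrase, envir = idx, inherits = FALSE)) {
        found <- c(found, phrase)
        hit <- L
        break
      }
    }
    i <- i + max(hit, 1L)
  }
  unique(found)
}

# hashed term index, built lazily and cached on the lexicon's environment
.lexicon_index <- function(lexicon) {
  cache <- attr(lexicon, "index")
  if (!is.null(cache)) return(cache)
  idx <- new.env(hash = TRUE, parent = emptyenv(), size = length(lexicon$entries))
  for (term in names(lexicon$entries)) assign(term, TRUE, envir = idx)
  idx
}

#' Match sentiment lemmas in a token stream
#'
#' @param raw_tokens lowercased, unstemmed tokens of one message.
#' @param sentiment_terms character vector of qualifying lemmas, normally
#'   from [sentiment_feature_terms()].
#' @return Character vector of distinct matched lemmas.
#' @export
extract_sentiment_features <- function(raw_tokens, sentiment_terms) {
  unique(raw_tokens[raw_tokens %in% sentiment_terms])
}

#' Assemble a feature space under one of the FS1-FS4 recipes
#'
#' The four incremental feature sets:
#' \describe{
#'   \item{FS1}{frequency-thresholded n-gram vocabulary (the baseline).}
#'   \item{FS2}{FS1 plus domain-term descriptors -- every lexicon term
#'     observed at least once in the corpus.}
#'   \item{FS3}{FS2 plus sentiment descriptors -- every lemma passing the
#'     subjectivity filter and observed at least once.}
#'   \item{FS4}{FS3 with the *n-gram* block reduced by information gain
#'     (gain strictly greater than `ig_threshold`); domain and sentiment
#'     descriptors are kept untouched.}
#' }
#' Domain and sentiment features are not frequency-thresholded.  FS4
#' requires labels on every message (information gain is supervised).
#'
#' @param x a `topic_corpus`, or a token cache from [preprocess_corpus()]
#'   (in which case `labels` must be given for FS4).
#' @param recipe `"FS1"`, `"FS2"`, `"FS3"` or `"FS4"`.
#' @param domain_lexicon a `domain_lexicon` (required for FS2-FS4).
#' @param sentiment_lexicon a `sentiment_lexicon` (required for FS3-FS4).
#' @param freq_threshold n-gram frequency threshold (default 20).
#' @param subjectivity_threshold sentiment subjectivity cut (default 0.5,
#'   strict).
#' @param ig_threshold information-gain cut in bits (default 0.0025,
#'   strict), applied to n-gram features only under FS4.
#' @param n_max maximal n-gram order.
#' @param count n-gram counting convention, see [build_ngram_vocabulary()].
#' @param stoplist stop words (used when `x` is a corpus).
#' @param labels class labels (needed for FS4 when `x` is a token cache).
#' @return An object of class `feature_space`: a data frame with columns
#'   `namespace`, `key`, `order`, rows ordered by (namespace, key), with a
#'   `provenance` attribute recording the recipe and all parameters.
#' @export
assemble_feature_space <- function(x, recipe = c("FS1", "FS2", "FS3", "FS4"),
                                   domain_lexicon = NULL,
                                   sentiment_lexicon = NULL,
                                   freq_threshold = 20,
                                   subjectivity_threshold = 0.5,
                                   ig_threshold = 0.0025,
                                   n_max = 3,
                                   count = "total",
                                   stoplist = load_stopwords(),
                                   labels = NULL) {
  recipe <- match.arg(recipe)
  if (inherits(x, "topic_corpus") && is.null(labels)) labels <- x$messages$label
  toks <- .as_token_cache(x, stoplist)

  desc <- build_ngram_vocabulary(toks, freq_threshold = freq_threshold,
                                 n_max = n_max, count = count)
  if (recipe %in% c("FS2", "FS3", "FS4")) {
    if (is.null(domain_lexicon)) {
      stop(sprintf("recipe %s requires a domain lexicon", recipe))
    }
    dom <- unique(unlist(lapply(toks, function(t)
      extract_domain_features(t$raw_tokens, domain_lexicon)), use.names = FALSE))
    dom <- sort(dom, method = "radix")
    if (length(dom)) {
      desc <- rbind(desc, data.frame(namespace = "domain", key = dom,
                                     order = 1L, stringsAsFactors = FALSE))
    }
  }
  if (recipe %in% c("FS3", "FS4")) {
    if (is.null(sentiment_lexicon)) {
      stop(sprintf("recipe %s requires a sentiment lexicon", recipe))
    }
    terms <- sentiment_feature_terms(sentiment_lexicon,
                                     threshold = subjectivity_threshold)
    sen <- unique(unlist(lapply(toks, function(t)
      extract_sentiment_features(t$raw_tokens, terms)), use.names = FALSE))
    sen <- sort(sen, method = "radix")
    if (length(sen)) {
      desc <- rbind(desc, data.frame(namespace = "sentiment", key = sen,
                                     order = 1L, stringsAsFactors = FALSE))
    }
  }
  desc <- desc[order(desc$namespace, desc$key, method = "radix"), , drop = FALSE]
  rownames(desc) <- NULL
  space <- structure(desc, class = c("feature_space", "data.frame"))
  attr(space, "provenance") <- list(
    recipe = recipe, freq_threshold = freq_threshold,
    subjectivity_threshold = subjectivity_threshold,
    ig_threshold = if (recipe == "FS4") ig_threshold else NA_real_,
    n_max = n_max, count = count)

  if (recipe == "FS4") {
    if (is.null(labels) || anyNA(labels)) {
      stop("FS4 requires labels on every message (information gain is supervised)")
    }
    is_ngram <- space$namespace == "ngram"
    if (any(is_ngram)) {
      ng_space <- space[is_ngram, , drop = FALSE]
      class(ng_space) <- class(space)
      attr(ng_space, "provenance") <- attr(space, "provenance")
      X <- vectorize(toks, ng_space, domain_lexicon = domain_lexicon,
                     sentiment_lexicon = sentiment_lexicon)
      scores <- score_all(X, labels)
      keep_keys <- sub("^ngram:", "", select_features(scores, ig_threshold))
      drop <- is_ngram & !(space$key %in% keep_keys)
      prov <- attr(space, "provenance")
      space <- space[!drop, , drop = FALSE]
      rownames(space) <- NULL
      class(space) <- c("feature_space", "data.frame")
      attr(space, "provenance") <- prov
    }
  }
  space
}

#' @export
print.feature_space <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("<feature_space> %s: %d descriptors (%s)\n",
              prov$recipe, nrow(x),
              paste(sprintf("%s=%d", names(table(x$namespace)),
                            as.integer(table(x$namespace))), collapse = ", ")))
  invisible(x)
}

#' Vectorize messages into a binary document-by-feature matrix
#'
#' Entry (d, f) is 1 iff message d contains descriptor f: n-gram
#' descriptors are matched over the stemmed token stream, domain and
#' sentiment descriptors over the raw lowercased tokens (lexicon lemmas
#' are dictionary forms).  Namespacing keeps a string that is both a
#' frequent n-gram and a lexicon term as two distinct columns.
#'
#' @param x a `topic_corpus` or a token cache from [preprocess_corpus()].
#' @param space a `feature_space`.
#' @param domain_lexicon needed when the space has domain descriptors.
#' @param sentiment_lexicon unused for matching (sentiment descriptors
#'   carry their lemmas), accepted for interface symmetry.
#' @param stoplist stop words (used when `x` is a corpus).
#' @param values `"binary"` (default, presence/absence per the BOW model)
#'   or `"count"` (within-message occurrence counts; n-grams with
#'   multiplicity, domain/sentiment matches per occurrence span).
#' @return A sparse `dgCMatrix`, rows named by message id, columns by
#'   `namespace:key`.
#' @export
vectorize <- function(x, space, domain_lexicon = NULL,
                      sentiment_lexicon = NULL, stoplist = load_stopwords(),
                      values = c("binary", "count")) {
  values <- match.arg(values)
  stopifnot(inherits(space, "feature_space"))
  toks <- .as_token_cache(x, stoplist)
  colkeys <- paste(space$namespace, space$key, sep = ":")
  n_max <- attr(space, "provenance")$n_max
  if (is.null(n_max)) n_max <- 3

  has_dom <- any(space$namespace == "domain")
  if (has_dom && is.null(domain_lexicon)) {
    stop("space contains domain descriptors: a domain lexicon is required")
  }
  sent_keys <- space$key[space$namespace == "sentiment"]

  col_env <- new.env(hash = TRUE, parent = emptyenv(), size = max(length(colkeys), 1))
  for (j in seq_along(colkeys)) assign(colkeys[j], j, envir = col_env)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (d in seq_along(toks)) {
    t <- toks[[d]]
    keys <- paste0("ngram:", extract_ngrams(t$stemmed_tokens, n_max))
    if (has_dom) {
      keys <- c(keys, paste0("domain:",
                             extract_domain_features(t$raw_tokens, domain_lexicon)))
    }
    if (length(sent_keys)) {
      sen <- t$raw_tokens[t$raw_tokens %in% sent_keys]
      keys <- c(keys, paste0("sentiment:", sen))
    }
    if (values == "binary") keys <- unique(keys)
    js <- unlist(mget(unique(keys), envir = col_env, ifnotfound = NA_integer_),
                 use.names = FALSE)
    if (values == "count") {
      cnt <- table(keys)[unique(keys)]
      keepk <- !is.na(js)
      js <- js[keepk]; cnt <- as.numeric(cnt)[keepk]
    } else {
      js <- js[!is.na(js)]
      cnt <- rep.int(1, length(js))
    }
    if (length(js)) {
      ii <- c(ii, rep.int(d, length(js)))
      jj <- c(jj, js)
      xx <- c(xx, cnt)
    }
  }
  Matrix::sparseMatrix(
    i = ii, j = jj, x = xx,
    dims = c(length(toks), nrow(space)),
    dimnames = list(names(toks), colkeys))
}

#' Export a feature matrix as MatrixMarket plus sidecar files
#'
#' Writes `<base>.mtx` (sparse MatrixMarket), `<base>.features` (one
#' `namespace:key` per line, column order) and `<base>.rows` (one message
#' id per line, row order).  [read_feature_matrix()] re-imports the triple.
#'
#' @param mat a sparse feature matrix from [vectorize()].
#' @param base path prefix (without extension).
#' @return `base`, invisibly.
#' @export
write_feature_matrix <- function(mat, base) {
  Matrix::writeMM(methods::as(mat, "generalMatrix"), paste0(base, ".mtx"))
  writeLines(colnames(mat), paste0(base, ".features"), useBytes = TRUE)
  writeLines(rownames(mat), paste0(base, ".rows"), useBytes = TRUE)
  invisible(base)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(base) {
  mat <- Matrix::readMM(paste0(base, ".mtx")) * 1  # pattern -> numeric
  mat <- methods::as(mat, "CsparseMatrix")
  dimnames(mat) <- list(readLines(paste0(base, ".rows"), warn = FALSE),
                        readLines(paste0(base, ".features"), warn = FALSE))
  mat
}
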