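#' Construct a labeled message corpus
#'
#' A `topic_corpus` holds an ordered set of messages, each with a unique
#' `id`, verbatim `text`, and an optional topic `label` (`NA` = unlabeled).
#' The label set is recorded in first-appearance order; that order is fixed
#' and defines the class index used by every downstream stage (information
#' gain, classifiers, confusion matrices, tie-breaking).
#'
#' @param messages data frame with character columns `id`, `text` and
#'   optionally `label` (`NA` for unlabeled messages).
#' @return An object of class `topic_corpus`: a list with elements
#'   `messages` (the data frame) and `label_set` (character vector of
#'   distinct labels in first-appearance order).
#' @examples
#' corp <- corpus(data.frame(
#'   id = c("m1", "m2"),
#'   text = c("chemo went fine", "sending hugs"),
#'   label = c("treatment", "emotional")
#' ))
#' corp$label_set
#' @export
corpus <- function(messages) {
  stopifnot(is.data.frame(messages))
  if (!all(c("id", "text") %in% names(messages))) {
    stop("corpus requires 'id' and 'text' columns")
  }
  if (!"label" %in% names(messages)) {
    messages$label <- rep(NA_character_, nrow(messages))
  }
  messages <- data.frame(
    id = as.character(messages$id),
    text = as.character(messages$text),
    label = as.character(messages$label),
    stringsAsFactors = FALSE
  )
  if (any(is.na(messages$id) | !nzchar(messages$id))) {
    stop("message ids must be non-empty")
  }
  dup <- messages$id[duplicated(messages$id)]
  if (length(dup)) {
    stop(sprintf("duplicate message id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  lab <- messages$label[!is.na(messages$label)]
  label_set <- unique(lab)
  structure(list(messages = messages, label_set = label_set),
            class = "topic_corpus")
}

#' @export
print.topic_corpus <- function(x, ...) {
  n <- nrow(x$messages)
  cat(sprintf("<topic_corpus> %d message%s, %d label%s\n",
              n, if (n == 1) "" else "s",
              length(x$label_set), if (length(x$label_set) == 1) "" else "s"))
  if (length(x$label_set)) {
    cat("labels:", paste(x$label_set, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.topic_corpus <- function(x) nrow(x$messages)

#' Subset a corpus by message position
#'
#' Keeps the selected messages in the given order. The label set is rebuilt
#' in first-appearance order of the subset, so class indices remain
#' deterministic for the new corpus.
#'
#' @param x a `topic_corpus`.
#' @param i integer or logical index into the messages.
#' @param ... unused.
#' @return A `topic_corpus`.
#' @export
`[.topic_corpus` <- function(x, i, ...) {
  corpus(x$messages[i, , drop = FALSE])
}

#' Read a labeled corpus from JSONL or CSV
#'
#' The canonical on-disk format is JSON Lines (UTF-8, one object per line,
#' fields `id`, `text`, optional `label`); CSV with header `id,text,label`
#' and RFC-4180 quoting is accepted for convenience.  Text is stored
#' verbatim -- no normalization happens at I/O time.  In CSV an empty label
#' field denotes an unlabeled message.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return A [corpus()] preserving record order, with the label set built in
#'   first-appearance order.
#' @export
read_corpus <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(corpus(data.frame(id = character(), text = character())))
    recs <- vector("list", length(lines))
    for (k in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[k]]),
                      error = function(e) NULL)
      if (is.null(rec) || is.null(rec$id) || is.null(rec$text)) {
        stop(sprintf("malformed JSONL record at line %d of %s", k, path))
      }
      recs[[k]] <- data.frame(
        id = as.character(rec$id),
        text = as.character(rec$text),
        label = if (is.null(rec$label)) NA_character_ else as.character(rec$label),
        stringsAsFactors = FALSE
      )
    }
    corpus(do.call(rbind, recs))
  } else {
    df <- tryCatch(
      utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8"),
      error = function(e) stop(sprintf("malformed CSV in %s: %s", path, conditionMessage(e)))
    )
    if (!all(c("id", "text") %in% names(df))) {
      stop("CSV header must contain columns 'id' and 'text'")
    }
    if (!nrow(df)) return(corpus(data.frame(id = character(), text = character())))
    if ("label" %in% names(df)) df$label[!nzchar(df$label)] <- NA_character_
    corpus(df)
  }
}

#' Write a corpus to JSONL or CSV
#'
#' Round-trip safe: `read_corpus(write_corpus(corp, path), format)`
#' reproduces `corp` exactly, including absent labels and non-ASCII text
#' (UTF-8 throughout).
#'
#' @param corp a `topic_corpus`.
#' @param path output file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corp, path, format = c("jsonl", "csv")) {
  stopifnot(inherits(corp, "topic_corpus"))
  format <- match.arg(format)
  msg <- corp$messages
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(msg)), function(k) {
      rec <- list(id = msg$id[k], text = msg$text[k])
      if (!is.na(msg$label[k])) rec$label <- msg$label[k]
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
  } else {
    out <- msg
    out$label[is.na(out$label)] <- ""
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.csv(out, con, row.names = FALSE)
  }
  invisible(path)
}

#' Summarize per-label message counts
#'
#' @param corp a `topic_corpus`.
#' @return A list with `counts` (named integer vector in label-set order),
#'   `n_unlabeled`, and `total`.  Counts sum to the number of labeled
#'   messages.
#' @export
corpus_summary <- function(corp) {
  stopifnot(inherits(corp, "topic_corpus"))
  lab <- corp$messages$label
  counts <- vapply(corp$label_set, function(l) sum(!is.na(lab) & lab == l),
                   integer(1))
  names(counts) <- corp$label_set
  list(counts = counts,
       n_unlabeled = sum(is.na(lab)),
       total = nrow(corp$messages))
}

# internal: run code under a temporary RNG state, restoring the caller's
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
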