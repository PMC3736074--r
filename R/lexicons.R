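#' Health-related UMLS-style semantic types
#'
#' The 20 semantic-type abbreviations used to filter the medical domain
#' lexicon, with their full names.  These cover the health-related subset
#' of UMLS semantic types relevant to patient-forum text (diseases,
#' symptoms, drugs, procedures, anatomy, ...).
#'
#' @return Named character vector: names are the abbreviation codes, values
#'   the full semantic-type names.
#' @export
umls_semantic_types <- function() {
  c(Aapp = "Amino acid, peptide, or protein",
    Acab = "Acquired abnormality",
    Anab = "Anatomical abnormality",
    Bdsy = "Body system",
    Blor = "Body location or region",
    Bmod = "Biomedical occupation or discipline",
    Bpoc = "Body part, organ, or organ component",
    Diap = "Diagnostic procedure",
    Dsyn = "Disease or syndrome",
    Horm = "Hormone",
    Imft = "Immunologic factor",
    Inpo = "Injury or poisoning",
    lbpr = "Laboratory procedure",
    Mobd = "Mental or behavioral dysfunction",
    Neop = "Neoplastic process",
    Orch = "Organic chemical",
    Patf = "Pathologic function",
    Phsu = "Pharmacologic substance",
    Sosy = "Sign or symptom",
    Topp = "Therapeutic or preventive procedure")
}

#' Load a medical domain lexicon
#'
#' Format: tab-separated, two columns `term<TAB>semantic-type code`, `#`
#' comment lines and blank lines ignored.  Terms are 1-3 word phrases,
#' lowercased on load and stored space-separated.  Rows whose code is not
#' in `allowed_types` are an error in strict mode, silently dropped
#' otherwise.  The same term under several codes becomes one entry carrying
#' all its codes.  Loading is order-independent: permuting rows yields the
#' same lexicon.
#'
#' @param path TSV file path.
#' @param allowed_types character vector of admissible semantic-type codes;
#'   defaults to the 20 codes of [umls_semantic_types()].
#' @param strict if `TRUE` (default), an unknown code is an error naming
#'   the offending row.
#' @return An object of class `domain_lexicon`: list with `entries` (named
#'   list, lowercased term -> character vector of codes, terms sorted) and
#'   `max_words` (longest phrase length).
#' @export
load_domain_lexicon <- function(path,
                                allowed_types = names(umls_semantic_types()),
                                strict = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  terms <- character(0); codes <- character(0)
  for (k in rows) {
    parts <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    if (length(parts) != 2 || !nzchar(parts[1]) || !nzchar(parts[2])) {
      stop(sprintf("malformed domain-lexicon row at line %d: %s", k, lines[[k]]))
    }
    term <- tolower(gsub("\\s+", " ", parts[1]))
    code <- parts[2]
    if (!(code %in% allowed_types)) {
      if (strict) {
        stop(sprintf("unknown semantic-type code '%s' at line %d (term '%s')",
                     code, k, term))
      }
      next
    }
    terms <- c(terms, term); codes <- c(codes, code)
  }
  entries <- lapply(split(codes, terms), function(x) sort(unique(x)))
  entries <- entries[order(names(entries), method = "radix")]
  max_words <- if (length(entries)) {
    max(lengths(strsplit(names(entries), " ", fixed = TRUE)))
  } else 1L
  structure(list(entries = entries, max_words = as.integer(max_words)),
            class = "domain_lexicon")
}

#' @export
print.domain_lexicon <- function(x, ...) {
  cat(sprintf("<domain_lexicon> %d terms (phrases up to %d words)\n",
              length(x$entries), x$max_words))
  invisible(x)
}

#' Load a sentiment lexicon in SentiWordNet 3.0 format
#'
#' Format: tab-separated columns `POS`, `ID`, `PosScore`, `NegScore`,
#' `SynsetTerms` (and optionally a trailing gloss column); `SynsetTerms`
#' holds space-separated `lemma#rank` entries.  Lines starting with `#` are
#' ignored.  Each `lemma#rank` contributes one sense record
#' `(pos, neg, rank)` to that lemma.  Scores must lie in `[0, 1]` with
#' `pos + neg <= 1` (objectivity = 1 - pos - neg is non-negative).
#' Part of speech is pooled: the pipeline does not POS-tag tokens, so all
#' senses of a lemma are aggregated regardless of POS.
#'
#' @param path file path.
#' @return An object of class `sentiment_lexicon`: list with `senses`, a
#'   data frame with columns `lemma`, `pos`, `neg`, `rank`.
#' @export
load_sentiment_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lemma <- character(0); pos <- numeric(0); neg <- numeric(0); rank <- integer(0)
  for (k in seq_along(lines)) {
    ln <- lines[[k]]
    if (grepl("^\\s*(#|$)", ln)) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 5) {
      stop(sprintf("malformed sentiment-lexicon line %d: expected >= 5 tab-separated columns", k))
    }
    p <- suppressWarnings(as.numeric(parts[3]))
    n <- suppressWarnings(as.numeric(parts[4]))
    if (is.na(p) || is.na(n) || p < 0 || p > 1 || n < 0 || n > 1) {
      stop(sprintf("scores outside [0,1] at line %d", k))
    }
    if (p + n > 1 + 1e-12) {
      stop(sprintf("pos + neg > 1 at line %d (pos=%g, neg=%g)", k, p, n))
    }
    terms <- strsplit(trimws(parts[5]), "\\s+")[[1]]
    for (t in terms) {
      hash <- regexpr("#[0-9]+$", t)
      if (hash < 0) {
        stop(sprintf("synset term '%s' at line %d lacks a #rank suffix", t, k))
      }
      r <- as.integer(substring(t, hash + 1))
      if (is.na(r) || r < 1) {
        stop(sprintf("bad sense rank in '%s' at line %d", t, k))
      }
      lemma <- c(lemma, tolower(substring(t, 1, hash - 1)))
      pos <- c(pos, p); neg <- c(neg, n); rank <- c(rank, r)
    }
  }
  senses <- data.frame(lemma = lemma, pos = pos, neg = neg, rank = rank,
                       stringsAsFactors = FALSE)
  structure(list(senses = senses), class = "sentiment_lexicon")
}

#' @export
print.sentiment_lexicon <- function(x, ...) {
  cat(sprintf("<sentiment_lexicon> %d senses, %d lemmas\n",
              nrow(x$senses), length(unique(x$senses$lemma))))
  invisible(x)
}

#' Subjectivity score of a lemma
#'
#' Subjectivity of one word sense is `pos + neg` (equivalently
#' `1 - objectivity`).  A multi-sense lemma is aggregated as the unweighted
#' arithmetic mean over its senses by default; `rank_weighted = TRUE`
#' weights sense s by `1/rank_s` (normalized), emphasizing common senses.
#'
#' @param lexicon a `sentiment_lexicon`.
#' @param lemma character vector of lowercase lemmas.
#' @param rank_weighted use `1/rank` sense weights instead of the plain mean.
#' @return Numeric vector in `[0, 1]`; `NA` for lemmas absent from the
#'   lexicon.
#' @export
subjectivity <- function(lexicon, lemma, rank_weighted = FALSE) {
  stopifnot(inherits(lexicon, "sentiment_lexicon"))
  s <- lexicon$senses
  vapply(tolower(lemma), function(l) {
    rows <- s$lemma == l
    if (!any(rows)) return(NA_real_)
    subj <- s$pos[rows] + s$neg[rows]
    if (rank_weighted) {
      w <- 1 / s$rank[rows]
      sum(w * subj) / sum(w)
    } else {
      mean(subj)
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Lemmas qualifying as sentiment features
#'
#' Returns the lemmas whose subjectivity is strictly greater than the
#' threshold (default 0.5; the boundary value itself is excluded).
#'
#' @param lexicon a `sentiment_lexicon`.
#' @param threshold subjectivity cut in `[0, 1]`.
#' @param rank_weighted passed to [subjectivity()].
#' @return Character vector of qualifying lemmas, sorted.
#' @export
sentiment_feature_terms <- function(lexicon, threshold = 0.5,
                                    rank_weighted = FALSE) {
  stopifnot(inherits(lexicon, "sentiment_lexicon"),
            threshold >= 0, threshold <= 1)
  lemmas <- unique(lexicon$senses$lemma)
  subj <- subjectivity(lexicon, lemmas, rank_weighted = rank_weighted)
  sort(lemmas[subj > threshold], method = "radix")
}
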