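# Porter (1980) suffix-stripping stemmer, implemented from the published
# algorithm description.  Operates on single lowercase words; words of one
# or two letters are returned unchanged.  Exposed per-step internals make
# each rule group testable against the algorithm's worked examples.

# consonant/vowel pattern: TRUE = consonant.  'y' is a consonant at word
# start or after a vowel, otherwise a vowel.
.pt_pattern <- function(ch) {
  n <- length(ch)
  pat <- logical(n)
  for (i in seq_len(n)) {
    c <- ch[i]
    if (c %in% c("a", "e", "i", "o", "u")) {
      pat[i] <- FALSE
    } else if (c == "y") {
      pat[i] <- if (i == 1) TRUE else !pat[i - 1]
    } else {
      pat[i] <- TRUE
    }
  }
  pat
}

# m: number of vowel->consonant transitions, i.e. [C](VC){m}[V]
.pt_measure <- function(word) {
  if (!nchar(word)) return(0L)
  pat <- .pt_pattern(strsplit(word, "", fixed = TRUE)[[1]])
  runs <- rle(pat)$values
  if (length(runs) < 2) return(0L)
  sum(!runs[-length(runs)] & runs[-1])
}

.pt_has_vowel <- function(word) {
  if (!nchar(word)) return(FALSE)
  any(!.pt_pattern(strsplit(word, "", fixed = TRUE)[[1]]))
}

.pt_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2) return(FALSE)
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  ch[n] == ch[n - 1] && .pt_pattern(ch)[n]
}

# *o condition: stem ends consonant-vowel-consonant, final consonant
# not w, x or y
.pt_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3) return(FALSE)
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  pat <- .pt_pattern(ch)
  pat[n - 2] && !pat[n - 1] && pat[n] && !(ch[n] %in% c("w", "x", "y"))
}

.pt_ends <- function(word, suf) {
  ns <- nchar(suf)
  nw <- nchar(word)
  nw >= ns && substring(word, nw - ns + 1, nw) == suf
}

.pt_chop <- function(word, suf) substring(word, 1, nchar(word) - nchar(suf))

.pt_step1a <- function(w) {
  if (.pt_ends(w, "sses")) return(paste0(.pt_chop(w, "sses"), "ss"))
  if (.pt_ends(w, "ies"))  return(paste0(.pt_chop(w, "ies"), "i"))
  if (.pt_ends(w, "ss"))   return(w)
  if (.pt_ends(w, "s"))    return(.pt_chop(w, "s"))
  w
}

.pt_step1b <- function(w) {
  if (.pt_ends(w, "eed")) {
    stem <- .pt_chop(w, "eed")
    if (.pt_measure(stem) > 0) return(paste0(stem, "ee"))
    return(w)
  }
  cleanup <- FALSE
  if (.pt_ends(w, "ed") && .pt_has_vowel(.pt_chop(w, "ed"))) {
    w <- .pt_chop(w, "ed"); cleanup <- TRUE
  } else if (.pt_ends(w, "ing") && .pt_has_vowel(.pt_chop(w, "ing"))) {
    w <- .pt_chop(w, "ing"); cleanup <- TRUE
  }
  if (cleanup) {
    if (.pt_ends(w, "at") || .pt_ends(w, "bl") || .pt_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.pt_double_cons(w) &&
               !(substring(w, nchar(w)) %in% c("l", "s", "z"))) {
      w <- substring(w, 1, nchar(w) - 1)
    } else if (.pt_measure(w) == 1 && .pt_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

.pt_step1c <- function(w) {
  if (.pt_ends(w, "y") && .pt_has_vowel(.pt_chop(w, "y"))) {
    return(paste0(.pt_chop(w, "y"), "i"))
  }
  w
}

# rule tables for steps 2-4, ordered longest suffix first so that at most
# the single applicable rule fires (per the algorithm, once a suffix
# matches the step ends whether or not its condition holds)
.pt_rules2 <- list(
  c("ational", "ate"), c("ization", "ize"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"),
  c("tional", "tion"), c("biliti", "ble"),
  c("entli", "ent"), c("ousli", "ous"), c("ation", "ate"),
  c("alism", "al"), c("aliti", "al"), c("iviti", "ive"),
  c("enci", "ence"), c("anci", "ance"), c("izer", "ize"),
  c("abli", "able"), c("alli", "al"), c("ator", "ate"),
  c("eli", "e")
)

.pt_rules3 <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"),
  c("iciti", "ic"), c("ical", "ic"), c("ful", ""), c("ness", "")
)

.pt_rules4 <- c("ement", "ance", "ence", "able", "ible", "ment",
                "ant", "ent", "ion", "ism", "ate", "iti", "ous",
                "ive", "ize", "al", "er", "ic", "ou")

.pt_step23 <- function(w, rules) {
  for (r in rules) {
    if (.pt_ends(w, r[1])) {
      stem <- .pt_chop(w, r[1])
      if (.pt_measure(stem) > 0) return(paste0(stem, r[2]))
      return(w)
    }
  }
  w
}

.pt_step4 <- function(w) {
  for (suf in .pt_rules4) {
    if (.pt_ends(w, suf)) {
      stem <- .pt_chop(w, suf)
      if (suf == "ion" &&
          !(nchar(stem) && substring(stem, nchar(stem)) %in% c("s", "t"))) {
        return(w)
      }
      if (.pt_measure(stem) > 1) return(stem)
      return(w)
    }
  }
  w
}

.pt_step5a <- function(w) {
  if (.pt_ends(w, "e")) {
    stem <- .pt_chop(w, "e")
    m <- .pt_measure(stem)
    if (m > 1 || (m == 1 && !.pt_cvc(stem))) return(stem)
  }
  w
}

.pt_step5b <- function(w) {
  if (.pt_measure(w) > 1 && .pt_double_cons(w) && .pt_ends(w, "l")) {
    return(substring(w, 1, nchar(w) - 1))
  }
  w
}

.pt_stem_word <- function(w) {
  if (nchar(w) <= 2) return(w)
  w <- .pt_step1a(w)
  w <- .pt_step1b(w)
  w <- .pt_step1c(w)
  w <- .pt_step23(w, .pt_rules2)
  w <- .pt_step23(w, .pt_rules3)
  w <- .pt_step4(w)
  w <- .pt_step5a(w)
  .pt_step5b(w)
}

#' Porter-stem a vector of lowercase tokens
#'
#' Applies the classic Porter suffix-stripping algorithm.  Tokens that
#' contain characters outside `a-z` (digits, apostrophes) are passed through
#' the same rules; in practice the rules only fire on alphabetic tails, so
#' tokens such as `"her2"` come back unchanged.  Length of the input is
#' preserved.
#'
#' @param tokens character vector of lowercase tokens.
#' @return Character vector of stems, same length and order.
#' @examples
#' porter_stem(c("treatments", "caring", "happy"))
#' @export
porter_stem <- function(tokens) {
  if (!length(tokens)) return(character())
  uniq <- unique(tokens)
  stems <- vapply(uniq, .pt_stem_word, character(1), USE.NAMES = FALSE)
  stems[match(tokens, uniq)]
}
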