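# Small in-code fixtures shared across test files.

tiny_corpus <- function() {
  corpus(data.frame(
    id = c("m1", "m2", "m3"),
    text = c("I had chemo, then surgery.",
             "Sending hugs and prayers to everyone.",
             "Five years out and feeling strong!"),
    label = c("treatment", "emotional", "survivorship"),
    stringsAsFactors = FALSE))
}

write_domain_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("# test lexicon", rows), path)
  path
}

write_swn_fixture <- function(rows, path = tempfile(fileext = ".txt")) {
  writeLines(c("# test sentiment lexicon", rows), path)
  path
}

swn_line <- function(pos, id, p, n, terms) {
  sprintf("%s\t%08d\t%s\t%s\t%s\tgloss", pos, id, format(p), format(n), terms)
}

# deterministic mini stoplist used where the bundled list would obscure
# the arithmetic
tiny_stoplist <- c("i", "and", "to", "the", "a", "had", "then", "out")
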