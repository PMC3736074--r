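test_that("n-gram enumeration yields all contiguous n-grams with multiplicity", {
  expect_setequal(extract_ngrams(c("breast", "cancer", "treatment")),
                  c("breast", "cancer", "treatment",
                    "breast cancer", "cancer treatment",
                    "breast cancer treatment"))
  expect_equal(extract_ngrams(character()), character())
  expect_equal(extract_ngrams("solo"), "solo")
  # 3L - 3 identity for L >= 3, multiplicity preserved
  for (L in 3:7) {
    toks <- sample(letters[1:3], L, replace = TRUE)
    expect_length(extract_ngrams(toks), 3 * L - 3)
  }
  expect_equal(sum(extract_ngrams(c("a", "a", "a")) == "a"), 3)
})

test_that("n-gram vocabulary applies the >= frequency threshold", {
  texts <- c(rep("chemo works", 10), rep("chemo", 15), "rare gram here")
  corp <- corpus(data.frame(id = paste0("m", seq_along(texts)), text = texts))
  voc <- build_ngram_vocabulary(corp, freq_threshold = 20,
                                stoplist = character())
  expect_equal(voc$key, "chemo")    # 25 occurrences; "works" has 10
  voc1 <- build_ngram_vocabulary(corp, freq_threshold = 1,
                                 stoplist = character())
  expect_true(all(c("chemo", "work", "chemo work", "rare") %in% voc1$key))
  # boundary: exactly at threshold is retained
  voc10 <- build_ngram_vocabulary(corp, freq_threshold = 10,
                                  stoplist = character())
  expect_true(all(c("chemo work", "work") %in% voc10$key))
  # monotone: raising the threshold never adds descriptors
  for (th in c(2, 5, 11, 16)) {
    v_lo <- build_ngram_vocabulary(corp, freq_threshold = th,
                                   stoplist = character())
    expect_true(all(v_lo$key %in% voc1$key))
    expect_lte(nrow(v_lo), nrow(voc1))
  }
})

test_that("document-frequency counting is available as an option", {
  texts <- c("echo echo echo", "echo", "other words")
  corp <- corpus(data.frame(id = paste0("m", 1:3), text = texts))
  v_tot <- build_ngram_vocabulary(corp, freq_threshold = 3, n_max = 1,
                                  count = "total", stoplist = character())
  v_doc <- build_ngram_vocabulary(corp, freq_threshold = 3, n_max = 1,
                                  count = "document", stoplist = character())
  expect_true("echo" %in% v_tot$key)    # 4 occurrences
  expect_false("echo" %in% v_doc$key)   # 2 documents
})

test_that("domain matching is greedy longest-match without overlap", {
  lex <- load_domain_lexicon(write_domain_fixture(
    c("breast cancer\tDsyn", "cancer\tNeop", "fatigue\tSosy",
      "radiation therapy\tTopp")))
  expect_equal(extract_domain_features(
    c("had", "breast", "cancer", "surgery"), lex), "breast cancer")
  expect_equal(extract_domain_features(c("no", "match", "here"), lex),
               character())
  expect_equal(extract_domain_features(c("fatigue", "and", "fatigue"), lex),
               "fatigue")
  # consumed spans do not re-match, but a later standalone term does
  expect_equal(sort(extract_domain_features(
    c("breast", "cancer", "then", "cancer"), lex)),
    c("breast cancer", "cancer"))
})

test_that("sentiment matching is raw-token set membership", {
  expect_equal(extract_sentiment_features(c("so", "happy", "today"),
                                          c("happy", "sad")), "happy")
  expect_equal(extract_sentiment_features(c("plain", "words"),
                                          c("happy")), character())
  expect_equal(extract_sentiment_features(c("happy", "happy"),
                                          c("happy")), "happy")
})

test_that("FS recipes nest and namespaces prevent collisions", {
  cfg <- synth_config(n_messages = 120, seed = 7)
  gen <- generate_corpus(cfg)
  lex <- generate_lexicons(cfg)
  spaces <- lapply(c("FS1", "FS2", "FS3"), function(r) {
    assemble_feature_space(gen$corpus, r, domain_lexicon = lex$domain,
                           sentiment_lexicon = lex$sentiment,
                           freq_threshold = 2)
  })
  n1 <- nrow(spaces[[1]]); n2 <- nrow(spaces[[2]]); n3 <- nrow(spaces[[3]])
  expect_lte(n1, n2); expect_lte(n2, n3)
  expect_true(all(spaces[[1]]$namespace == "ngram"))
  # a sentiment lemma that is also a frequent unigram appears twice,
  # under two namespaces
  keys3 <- paste(spaces[[3]]$namespace, spaces[[3]]$key)
  dup <- intersect(spaces[[3]]$key[spaces[[3]]$namespace == "sentiment"],
                   spaces[[3]]$key[spaces[[3]]$namespace == "ngram"])
  expect_gt(length(dup), 0)
  expect_equal(anyDuplicated(keys3), 0)
})

test_that("FS4 reduces only the n-gram block and requires labels", {
  cfg <- synth_config(n_messages = 150, seed = 11)
  gen <- generate_corpus(cfg)
  lex <- generate_lexicons(cfg)
  fs3 <- assemble_feature_space(gen$corpus, "FS3", domain_lexicon = lex$domain,
                                sentiment_lexicon = lex$sentiment,
                                freq_threshold = 5)
  fs4 <- assemble_feature_space(gen$corpus, "FS4", domain_lexicon = lex$domain,
                                sentiment_lexicon = lex$sentiment,
                                freq_threshold = 5, ig_threshold = 0.0025)
  count_ns <- function(sp, ns) sum(sp$namespace == ns)
  expect_lte(count_ns(fs4, "ngram"), count_ns(fs3, "ngram"))
  expect_equal(count_ns(fs4, "domain"), count_ns(fs3, "domain"))
  expect_equal(count_ns(fs4, "sentiment"), count_ns(fs3, "sentiment"))
  unlabeled <- corpus(data.frame(id = gen$corpus$messages$id,
                                 text = gen$corpus$messages$text))
  expect_error(assemble_feature_space(unlabeled, "FS4",
                                      domain_lexicon = lex$domain,
                                      sentiment_lexicon = lex$sentiment,
                                      freq_threshold = 5),
               "label")
})

test_that("feature spaces are invariant to message order (FS1-FS3)", {
  cfg <- synth_config(n_messages = 80, seed = 3)
  gen <- generate_corpus(cfg)
  lex <- generate_lexicons(cfg)
  perm <- rev(seq_len(length(gen$corpus)))
  for (r in c("FS1", "FS2", "FS3")) {
    s1 <- assemble_feature_space(gen$corpus, r, domain_lexicon = lex$domain,
                                 sentiment_lexicon = lex$sentiment,
                                 freq_threshold = 4)
    s2 <- assemble_feature_space(gen$corpus[perm], r,
                                 domain_lexicon = lex$domain,
                                 sentiment_lexicon = lex$sentiment,
                                 freq_threshold = 4)
    expect_equal(as.data.frame(s1), as.data.frame(s2), label = r)
  }
})

test_that("vectorize marks presence over the right token stream", {
  corp <- corpus(data.frame(
    id = c("d1", "d2"),
    text = c("breast cancer treatments helped", "nothing relevant"),
    label = c("a", "b")))
  lex <- load_domain_lexicon(write_domain_fixture("breast cancer\tDsyn"))
  space <- assemble_feature_space(corp, "FS2", domain_lexicon = lex,
                                  freq_threshold = 1,
                                  stoplist = character())
  X <- vectorize(corp, space, domain_lexicon = lex, stoplist = character())
  expect_equal(X["d1", "ngram:breast cancer"], 1)   # stemmed bigram
  expect_equal(X["d1", "domain:breast cancer"], 1)  # lexicon match
  expect_equal(X["d2", "ngram:breast cancer"], 0)
  expect_true(all(X@x %in% c(0, 1)))
  # every FS1 column built from this corpus has at least one nonzero row
  expect_true(all(Matrix::colSums(X) >= 1))
  # all-zero rows are legal
  empty_corp <- corpus(data.frame(id = "e1", text = "zzz qqq"))
  Xe <- vectorize(empty_corp, space, domain_lexicon = lex,
                  stoplist = character())
  expect_equal(sum(Xe), 0)
})

test_that("feature matrices round-trip through MatrixMarket export", {
  cfg <- synth_config(n_messages = 40, seed = 5)
  gen <- generate_corpus(cfg)
  space <- assemble_feature_space(gen$corpus, "FS1", freq_threshold = 3)
  X <- vectorize(gen$corpus, space)
  base <- tempfile()
  write_feature_matrix(X, base)
  Y <- read_feature_matrix(base)
  expect_equal(as.matrix(X), as.matrix(Y))
  expect_identical(dimnames(X), dimnames(Y))
})
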