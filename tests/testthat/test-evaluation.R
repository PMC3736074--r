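test_that("confusion matrix tallies true-by-predicted counts", {
  classes <- c("t", "e", "s")
  truth <- c("t", "t", "e", "s", "s", "s")
  pred <- c("t", "e", "e", "s", "t", "s")
  cm <- confusion_matrix(truth, pred, classes)
  expect_equal(sum(cm), 6)
  expect_equal(cm["t", "t"], 1L); expect_equal(cm["t", "e"], 1L)
  expect_equal(cm["s", "t"], 1L); expect_equal(cm["s", "s"], 2L)
  # perfect predictions -> diagonal
  cmd <- confusion_matrix(truth, truth, classes)
  expect_equal(sum(cmd) - sum(diag(cmd)), 0)
  # empty input -> all-zero matrix
  cm0 <- confusion_matrix(character(), character(), classes)
  expect_equal(sum(cm0), 0)
  expect_error(confusion_matrix("x", "t", classes), "x")
  expect_error(confusion_matrix(c("t", "e"), "t", classes), "length")
})

test_that("metrics match a hand-computed three-class example", {
  cm <- structure(matrix(as.integer(c(5, 1, 0,
                                      1, 3, 2,
                                      0, 1, 7)), 3, 3, byrow = TRUE,
                         dimnames = list(true = c("c1", "c2", "c3"),
                                         predicted = c("c1", "c2", "c3"))),
                  class = c("confusion_matrix", "matrix"))
  met <- compute_metrics(cm)
  expect_equal(met$accuracy, 15 / 20)
  expect_equal(met$per_class$precision, c(5 / 6, 3 / 5, 7 / 9))
  expect_equal(met$per_class$recall, c(5 / 6, 3 / 6, 7 / 8))
  f <- function(p, r) 2 * p * r / (p + r)
  expect_equal(met$per_class$f1,
               c(f(5 / 6, 5 / 6), f(3 / 5, 3 / 6), f(7 / 9, 7 / 8)))
  expect_equal(met$macro_precision, mean(c(5 / 6, 3 / 5, 7 / 9)))
  # diagonal matrix: everything 1
  met1 <- compute_metrics(confusion_matrix(c("a", "b"), c("a", "b"),
                                           c("a", "b")))
  expect_equal(met1$accuracy, 1)
  expect_equal(met1$macro_f1, 1)
  expect_error(compute_metrics(confusion_matrix(character(), character(),
                                                c("a", "b"))), "empty")
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(31)
  for (rep in 1:25) {
    m <- sample(2:4, 1)
    cm <- matrix(rpois(m * m, 4), m, m,
                 dimnames = list(true = paste0("c", 1:m),
                                 predicted = paste0("c", 1:m)))
    if (sum(cm) == 0) cm[1, 1] <- 1
    met <- compute_metrics(structure(cm, class = c("confusion_matrix", "matrix")))
    # micro identity: accuracy = class-size-weighted mean recall
    w <- rowSums(cm) / sum(cm)
    expect_equal(met$accuracy, sum(w * met$per_class$recall), tolerance = 1e-12)
    # per-class F is the harmonic mean of its P and R
    with(met$per_class, expect_true(all(abs(
      f1 - ifelse(precision + recall > 0,
                  2 * precision * recall / (precision + recall), 0)) < 1e-12)))
  }
  # a class absent from truth and predictions gets P = R = 0 by convention
  met0 <- compute_metrics(confusion_matrix(c("a", "a"), c("a", "a"),
                                           c("a", "ghost")))
  expect_equal(met0$per_class$precision[2], 0)
  expect_equal(met0$per_class$recall[2], 0)
})

test_that("stratified folds partition the corpus with balanced classes", {
  labels <- rep(c("t", "e", "s"), c(40, 25, 55))
  fold <- make_folds(labels, k = 10, seed = 4)
  expect_length(fold, 120)
  expect_true(all(fold %in% 1:10))
  # partition: each document in exactly one fold; fold sizes balanced
  expect_equal(sum(table(fold)), 120)
  for (cl in unique(labels)) {
    per_fold <- table(factor(fold[labels == cl], levels = 1:10))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  # determinism and seed sensitivity
  expect_identical(make_folds(labels, 10, seed = 4), fold)
  expect_false(identical(make_folds(labels, 10, seed = 5), fold))
  expect_error(make_folds(rep(c("a", "b"), c(30, 5)), k = 10), "b")
})

test_that("cross-validation pools folds and is reproducible", {
  cfg <- synth_config(preset = "strong", n_messages = 160, seed = 12)
  gen <- generate_corpus(cfg)
  rep1 <- cross_validate(gen$corpus, recipe = "FS1", classifier = "nb",
                         k = 5, seed = 9, freq_threshold = 3)
  rep2 <- cross_validate(gen$corpus, recipe = "FS1", classifier = "nb",
                         k = 5, seed = 9, freq_threshold = 3)
  expect_identical(rep1$confusion, rep2$confusion)
  expect_equal(sum(rep1$confusion), length(gen$corpus))
  expect_equal(nrow(rep1$per_fold), 5)
  expect_gt(rep1$metrics$accuracy, 0.8)
  # micro identity holds on the pooled report
  w <- rowSums(rep1$confusion) / sum(rep1$confusion)
  expect_equal(rep1$metrics$accuracy,
               sum(w * rep1$metrics$per_class$recall), tolerance = 1e-12)
  expect_error(cross_validate(gen$corpus, recipe = "FS2", classifier = "nb",
                              k = 5, seed = 9), "domain lexicon")
})

test_that("repeated CV pairs repetitions across configs via shared seeds", {
  cfg <- synth_config(preset = "strong", n_messages = 120, seed = 21)
  gen <- generate_corpus(cfg)
  base <- list(recipe = "FS1", classifier = "nb", freq_threshold = 3)
  res <- repeated_cv(gen$corpus, list(one = base, two = base),
                     repetitions = 3, k = 4, seed = 100)
  # identical configs give identical paired vectors
  expect_equal(res$accuracy[, "one"], res$accuracy[, "two"])
  expect_equal(res$macro_f1[, "one"], res$macro_f1[, "two"])
  expect_equal(nrow(res$accuracy), 3)
  expect_equal(res$seeds, 100:102)
  tests <- pairwise_tests(res)
  expect_equal(nrow(tests), 2)      # one pair x two metrics
  expect_equal(tests$p_value, c(0.5, 0.5))
})

test_that("paired t-test matches the closed form and reference oracle", {
  # hand example: d = (.04, .03, .05), t = .04 / (.01 / sqrt(3)) = 4 sqrt(3)
  a <- c(0.80, 0.82, 0.81); b <- c(0.84, 0.85, 0.86)
  tt <- paired_t_test(a, b)
  expect_equal(tt$t, 4 * sqrt(3), tolerance = 1e-12)
  expect_equal(tt$p_value, oracle_t2_upper(4 * sqrt(3)), tolerance = 1e-12)
  # antisymmetry
  rev_tt <- paired_t_test(b, a)
  expect_equal(rev_tt$t, -tt$t, tolerance = 1e-12)
  expect_equal(rev_tt$p_value, 1 - tt$p_value, tolerance = 1e-12)
  # degenerate conventions
  expect_equal(paired_t_test(a, a)[c("t", "p_value")], list(t = 0, p_value = 0.5))
  up <- paired_t_test(a, a + 0.01)
  expect_equal(up$t, Inf); expect_equal(up$p_value, 0)
  dn <- paired_t_test(a + 0.01, a)
  expect_equal(dn$t, -Inf); expect_equal(dn$p_value, 1)
  expect_error(paired_t_test(a, b[1:2]), "length")
  expect_error(paired_t_test(1, 2), "at least 2")
})

test_that("paired t-test agrees with stats::t.test on random pairs", {
  set.seed(55)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    a <- runif(n); b <- a + rnorm(n, 0.02, 0.05)
    mine <- paired_t_test(a, b)
    ref <- t.test(b, a, paired = TRUE, alternative = "greater")
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("frequency-threshold sweep tabulates one row per threshold", {
  cfg <- synth_config(preset = "strong", n_messages = 120, seed = 8)
  gen <- generate_corpus(cfg)
  res <- sweep_frequency_threshold(gen$corpus, c(2, 1e9), classifier = "nb",
                                   k = 4, seed = 3)
  expect_equal(res$threshold, c(2, 1e9))
  expect_equal(nrow(res), 2)
  # an absurd threshold empties FS1: majority-class behavior
  prop <- max(table(gen$corpus$messages$label)) / length(gen$corpus)
  expect_equal(res$accuracy[2], prop, tolerance = 0.02)
  # informative features help over no features
  expect_gt(res$accuracy[1], res$accuracy[2])
})

test_that("evaluation reports serialize to JSON and per-class TSV", {
  cfg <- synth_config(preset = "strong", n_messages = 100, seed = 14)
  gen <- generate_corpus(cfg)
  report <- cross_validate(gen$corpus, recipe = "FS1", classifier = "nb",
                           k = 4, seed = 2, freq_threshold = 3)
  base <- tempfile()
  write_report(report, base)
  js <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(js$accuracy, report$metrics$accuracy)
  tsv <- read.delim(paste0(base, ".tsv"))
  expect_equal(nrow(tsv), 4)      # 3 classes + average row
  expect_equal(tsv$class[4], "average")
})
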