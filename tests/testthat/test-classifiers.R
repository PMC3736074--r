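test_that("naive Bayes posteriors match the hand-computed Bernoulli model", {
  # class A: docs (1,0), (1,1); class B: doc (0,1); alpha = 1
  X <- matrix(c(1, 0, 1, 1, 0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(NULL, c("t1", "t2")))
  labels <- c("A", "A", "B")
  m <- train_naive_bayes(X, labels, alpha = 1)
  sc <- predict(m, matrix(c(1, 0), 1, 2), type = "score")
  # log-odds A vs B at query (1,0):
  # log(2/3 / 1/3) + log(3/4 / 1/3) + log(1/2 / 1/3) = log(6.75)
  expect_equal(sc$scores[1, 1] - sc$scores[1, 2], log(6.75),
               tolerance = 1e-12)
  expect_equal(sc$labels, "A")
  # all-zero query: log-odds = log(2) + log((1/4)/(2/3)) + log((1/2)/(1/3))
  sc0 <- predict(m, matrix(0, 1, 2), type = "score")
  expect_equal(sc0$scores[1, 1] - sc0$scores[1, 2],
               log(2) + log((1 / 4) / (2 / 3)) + log((1 / 2) / (1 / 3)),
               tolerance = 1e-12)
})

test_that("symmetric training data breaks ties toward the first class", {
  X <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("t1", "t2")))
  m <- train_naive_bayes(X, c("A", "B"))
  expect_equal(predict(m, matrix(c(1, 1), 1, 2)), "A")
  expect_equal(predict(m, matrix(c(0, 0), 1, 2)), "A")
  # and the simple separable case recovers each class
  expect_equal(predict(m, X), c("A", "B"))
})

test_that("prediction rejects dimension mismatches and unlabeled training", {
  X <- matrix(rbinom(20, 1, 0.5), 5, 4)
  labels <- c("a", "a", "b", "b", "a")
  for (fit in list(train_naive_bayes(X, labels),
                   train_decision_tree(X, labels),
                   train_svm(X, labels))) {
    expect_error(predict(fit, matrix(0, 2, 3)), "mismatch")
  }
  expect_error(train_naive_bayes(X[0, , drop = FALSE], character()), "empty")
  expect_error(train_naive_bayes(X, c("a", NA, "b", "b", "a")), "label")
})

test_that("a perfectly predictive feature yields a depth-1 tree", {
  X <- cbind(sig = c(1, 1, 1, 0, 0, 0), noise = c(1, 0, 1, 1, 0, 1))
  labels <- rep(c("pos", "neg"), each = 3)
  tr <- train_decision_tree(X, labels)
  expect_false(tr$root$leaf)
  expect_equal(tr$root$feature_name, "sig")
  expect_true(tr$root$present$leaf && tr$root$absent$leaf)
  expect_equal(predict(tr, X), labels)
})

test_that("a pure corpus trains to a single leaf", {
  X <- matrix(rbinom(12, 1, 0.5), 4, 3)
  tr <- train_decision_tree(X, rep("only", 4))
  expect_true(tr$root$leaf)
  expect_equal(predict(tr, X), rep("only", 4))
})

test_that("tree splits agree with the brute-force gain-ratio oracle", {
  for (s in 1:25) {
    fx <- random_labeled_matrix(n_docs = 8, n_feat = 3,
                                n_classes = 2, seed = 3000 + s)
    tr <- train_decision_tree(fx$X, fx$labels, min_leaf = 1)
    ratios <- oracle_gain_ratio(fx$X, fx$labels)
    # features with no positive gain are not split candidates
    gains <- vapply(seq_len(ncol(fx$X)), function(j)
      oracle_information_gain(fx$X[, j], fx$labels), numeric(1))
    ratios[gains <= 1e-12] <- NA_real_
    if (tr$root$leaf) {
      expect_true(all(is.na(ratios)) || length(unique(fx$labels)) == 1)
    } else {
      expect_equal(tr$root$feature,
                   which.max(replace(ratios, is.na(ratios), -Inf)))
    }
  }
})

test_that("SVM separates linearly separable and XOR-patterned data", {
  # separable, degree 1
  set.seed(1)
  X <- rbind(matrix(rnorm(20, 2), 10, 2), matrix(rnorm(20, -2), 10, 2))
  labels <- rep(c("hi", "lo"), each = 10)
  fit <- train_svm(X, labels, degree = 1, C = 10)
  expect_equal(predict(fit, X), labels)
  # XOR needs the quadratic kernel
  Xx <- matrix(c(0, 0, 1, 1, 1, 0, 0, 1), 4, 2, byrow = TRUE)
  yx <- c("same", "same", "diff", "diff")
  fit2 <- train_svm(Xx, yx, degree = 2, C = 100, gamma = 1, coef0 = 1)
  expect_equal(predict(fit2, Xx), yx)
  # duplicating the training set leaves the decision function unchanged
  fit_dup <- train_svm(rbind(X, X), rep(labels, 2), degree = 1, C = 10)
  probe <- matrix(rnorm(40), 20, 2)
  expect_equal(predict(fit_dup, probe), predict(fit, probe))
})

test_that("multiclass SVM predictions are deterministic and in class order", {
  cfg <- synth_config(preset = "strong", n_messages = 90, seed = 2)
  gen <- generate_corpus(cfg)
  space <- assemble_feature_space(gen$corpus, "FS1", freq_threshold = 3)
  X <- vectorize(gen$corpus, space)
  labels <- gen$corpus$messages$label
  fit <- train_svm(X, labels, classes = gen$corpus$label_set)
  p1 <- predict(fit, X)
  p2 <- predict(train_svm(X, labels, classes = gen$corpus$label_set), X)
  expect_identical(p1, p2)
  expect_true(all(p1 %in% gen$corpus$label_set))
  expect_gt(mean(p1 == labels), 0.9)
})

test_that("NB and tree models round-trip through the JSON schema", {
  fx <- random_labeled_matrix(20, 6, 3, seed = 77)
  probe <- random_labeled_matrix(10, 6, 3, seed = 78)$X
  nb <- train_naive_bayes(fx$X, fx$labels)
  path <- tempfile(fileext = ".json")
  save_model(nb, path)
  nb2 <- load_model(path)
  expect_equal(predict(nb, probe, type = "score")$scores,
               predict(nb2, probe, type = "score")$scores,
               ignore_attr = TRUE)
  tr <- train_decision_tree(fx$X, fx$labels)
  save_model(tr, path)
  tr2 <- load_model(path)
  expect_identical(predict(tr, probe), predict(tr2, probe))
  sv <- train_svm(fx$X, fx$labels)
  rds <- tempfile(fileext = ".rds")
  save_model(sv, rds)
  expect_identical(predict(load_model(rds), probe), predict(sv, probe))
})
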