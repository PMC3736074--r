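# Evaluation protocol: confusion-matrix metrics, stratified tenfold
# cross-validation with leakage-free per-fold feature construction,
# repeated runs with shared fold seeds, one-sided paired t-tests, and
# frequency-threshold sweeps.

#' Build a confusion matrix
#'
#' Rows are true classes, columns predicted classes, both in the fixed
#' class order.
#'
#' @param true_labels,predicted_labels character vectors of equal length;
#'   every value must belong to `class_order`.
#' @param class_order character vector fixing row/column order.
#' @return An m x m integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, class_order) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("true and predicted label vectors must have equal length")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_order)
  if (length(bad)) {
    stop(sprintf("label(s) outside the class order: %s",
                 paste(bad, collapse = ", ")))
  }
  tf <- factor(true_labels, levels = class_order)
  pf <- factor(predicted_labels, levels = class_order)
  cm <- table(true = tf, predicted = pf)
  cm <- matrix(as.integer(cm), nrow = length(class_order),
               dimnames = list(true = class_order, predicted = class_order))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Compute accuracy, precision, recall and F-measure from a confusion matrix
#'
#' Accuracy is trace/total.  Per-class precision = TP/(TP+FP) and recall =
#' TP/(TP+FN), each 0 when its denominator is 0; F is the harmonic mean
#' 2PR/(P+R), 0 when P+R = 0.  The "average" row is the macro
#' (unweighted) mean over classes.
#'
#' @param cm a `confusion_matrix` with at least one entry.
#' @return A list with `accuracy`, `per_class` (data frame: class,
#'   precision, recall, f1, support), and `macro_precision`,
#'   `macro_recall`, `macro_f1`.
#' @export
compute_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = sum(tp) / total,
       per_class = data.frame(class = classes, precision = unname(prec),
                              recall = unname(rec), f1 = unname(f1),
                              support = unname(rowSums(cm)),
                              stringsAsFactors = FALSE),
       macro_precision = mean(prec),
       macro_recall = mean(rec),
       macro_f1 = mean(f1))
}

#' Stratified fold assignment
#'
#' Shuffles each class independently and deals its members round-robin
#' over the k folds (class start offsets rotate so overall fold sizes
#' balance); per-class fold counts differ by at most one.
#'
#' @param labels class label per document (no `NA`).
#' @param k number of folds.
#' @param seed RNG seed for the shuffle (the caller's RNG state is left
#'   untouched).
#' @param stratified if `FALSE`, plain shuffled deal ignoring classes.
#' @return Integer vector of fold ids in `1..k`, one per document.
#' @export
make_folds <- function(labels, k = 10, seed = 1, stratified = TRUE) {
  n <- length(labels)
  if (anyNA(labels)) stop("fold assignment requires labeled documents")
  fold <- integer(n)
  local_seed(seed, {
    if (!stratified) {
      fold <- ((sample.int(n) - 1L) %% k) + 1L
    } else {
      classes <- unique(labels)
      small <- classes[vapply(classes, function(cl) sum(labels == cl), 0L) < k]
      if (length(small)) {
        stop(sprintf("class(es) smaller than k = %d folds: %s", k,
                     paste(small, collapse = ", ")))
      }
      offset <- 0L
      for (cl in classes) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
        offset <- (offset + length(idx)) %% k
      }
    }
  })
  fold
}

# one fold's work: build space on training part, vectorize, fit, predict
.fit_predict_fold <- function(toks, labels, train, test, classes, recipe,
                              classifier, params, paper_mode, space_full) {
  space <- if (paper_mode) space_full else {
    assemble_feature_space(toks[train],
                           recipe = recipe$recipe,
                           domain_lexicon = recipe$domain_lexicon,
                           sentiment_lexicon = recipe$sentiment_lexicon,
                           freq_threshold = recipe$freq_threshold,
                           subjectivity_threshold = recipe$subjectivity_threshold,
                           ig_threshold = recipe$ig_threshold,
                           n_max = recipe$n_max, count = recipe$count,
                           labels = labels[train])
  }
  Xtr <- vectorize(toks[train], space, domain_lexicon = recipe$domain_lexicon)
  Xte <- vectorize(toks[test], space, domain_lexicon = recipe$domain_lexicon)
  model <- switch(classifier,
    nb = do.call(train_naive_bayes,
                 c(list(Xtr, labels[train], classes = classes), params)),
    tree = do.call(train_decision_tree,
                   c(list(Xtr, labels[train], classes = classes), params)),
    svm = do.call(train_svm,
                  c(list(Xtr, labels[train], classes = classes), params)),
    stop(sprintf("unknown classifier '%s'", classifier)))
  stats::predict(model, Xte)
}

.recipe_params <- function(recipe, domain_lexicon, sentiment_lexicon,
                           freq_threshold, subjectivity_threshold,
                           ig_threshold, n_max, count) {
  list(recipe = recipe, domain_lexicon = domain_lexicon,
       sentiment_lexicon = sentiment_lexicon, freq_threshold = freq_threshold,
       subjectivity_threshold = subjectivity_threshold,
       ig_threshold = ig_threshold, n_max = n_max, count = count)
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Partitions the labeled corpus into k stratified folds (default tenfold,
#' i.e. 90% train / 10% test per fold).  Within each fold the n-gram
#' vocabulary, domain/sentiment descriptor sets and (for FS4) information
#' gain are computed on the training portion only, so no test information
#' leaks into feature construction; `paper_mode = TRUE` instead builds one
#' feature space on the full corpus before splitting, mirroring protocols
#' that vectorize once up front.  Folds are aggregated by pooling all test
#' predictions into a single confusion matrix; per-fold accuracy and
#' macro-F are also reported.
#'
#' @param corp a fully labeled `topic_corpus`.
#' @param recipe `"FS1"`..`"FS4"`.
#' @param classifier `"nb"`, `"tree"` or `"svm"`.
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param domain_lexicon,sentiment_lexicon lexicons as required by the
#'   recipe.
#' @param freq_threshold,subjectivity_threshold,ig_threshold,n_max,count
#'   feature parameters, see [assemble_feature_space()].
#' @param classifier_params named list of extra arguments for the trainer
#'   (e.g. `list(alpha = 1)`, `list(degree = 2, C = 10)`).
#' @param stoplist stop words.
#' @param paper_mode build the feature space on the full corpus instead of
#'   per-fold training data.
#' @param stratified stratify folds by class (default `TRUE`).
#' @return An object of class `evaluation_report`: list with `confusion`,
#'   `metrics`, `per_fold` (data frame fold/accuracy/macro_f1), `config`.
#' @export
cross_validate <- function(corp, recipe = "FS1",
                           classifier = c("nb", "tree", "svm"),
                           k = 10, seed = 1,
                           domain_lexicon = NULL, sentiment_lexicon = NULL,
                           freq_threshold = 20, subjectivity_threshold = 0.5,
                           ig_threshold = 0.0025, n_max = 3, count = "total",
                           classifier_params = list(),
                           stoplist = load_stopwords(),
                           paper_mode = FALSE, stratified = TRUE) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(corp, "topic_corpus"))
  labels <- corp$messages$label
  if (anyNA(labels)) stop("cross-validation requires a fully labeled corpus")
  classes <- corp$label_set
  rec <- .recipe_params(recipe, domain_lexicon, sentiment_lexicon,
                        freq_threshold, subjectivity_threshold, ig_threshold,
                        n_max, count)
  if (recipe %in% c("FS2", "FS3", "FS4") && is.null(domain_lexicon)) {
    stop(sprintf("recipe %s requires a domain lexicon", recipe))
  }
  if (recipe %in% c("FS3", "FS4") && is.null(sentiment_lexicon)) {
    stop(sprintf("recipe %s requires a sentiment lexicon", recipe))
  }
  toks <- preprocess_corpus(corp, stoplist)
  fold <- make_folds(labels, k = k, seed = seed, stratified = stratified)
  space_full <- if (paper_mode) {
    assemble_feature_space(toks, recipe = recipe,
                           domain_lexicon = domain_lexicon,
                           sentiment_lexicon = sentiment_lexicon,
                           freq_threshold = freq_threshold,
                           subjectivity_threshold = subjectivity_threshold,
                           ig_threshold = ig_threshold, n_max = n_max,
                           count = count, labels = labels)
  } else NULL
  pred <- character(length(labels))
  per_fold <- data.frame(fold = seq_len(k), accuracy = NA_real_,
                         macro_f1 = NA_real_)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    pf <- .fit_predict_fold(toks, labels, train, test, classes, rec,
                            classifier, classifier_params, paper_mode,
                            space_full)
    pred[test] <- pf
    mets <- compute_metrics(confusion_matrix(labels[test], pf, classes))
    per_fold$accuracy[f] <- mets$accuracy
    per_fold$macro_f1[f] <- mets$macro_f1
  }
  cm <- confusion_matrix(labels, pred, classes)
  structure(list(confusion = cm,
                 metrics = compute_metrics(cm),
                 per_fold = per_fold,
                 config = list(recipe = recipe, classifier = classifier,
                               k = k, seed = seed,
                               freq_threshold = freq_threshold,
                               subjectivity_threshold = subjectivity_threshold,
                               ig_threshold = ig_threshold, n_max = n_max,
                               count = count, paper_mode = paper_mode,
                               stratified = stratified,
                               classifier_params = classifier_params)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s + %s, %d-fold CV (seed %s)\n",
              x$config$recipe, x$config$classifier, x$config$k,
              format(x$config$seed)))
  cat(sprintf("pooled accuracy %.4f, macro-F %.4f\n",
              x$metrics$accuracy, x$metrics$macro_f1))
  print(x$metrics$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Repeated cross-validation with shared fold seeds
#'
#' Runs each configuration through k-fold CV `repetitions` times.
#' Repetition r of *every* configuration uses the same fold seed
#' (`seed + r - 1`), so the per-repetition accuracy and macro-F vectors
#' are paired across configurations, as required by [paired_t_test()].
#'
#' @param corp a fully labeled `topic_corpus`.
#' @param configs named list; each element is a list of arguments for
#'   [cross_validate()] (everything except `corp`, `k` and `seed`).
#' @param repetitions number of repetitions (default 10, must be >= 2).
#' @param k folds per repetition.
#' @param seed base fold seed.
#' @return An object of class `repeated_cv`: list with `accuracy` and
#'   `macro_f1` (matrices, repetitions x configs), `seeds`, `configs`.
#' @export
repeated_cv <- function(corp, configs, repetitions = 10, k = 10, seed = 1) {
  stopifnot(repetitions >= 2, length(configs) >= 1)
  if (is.null(names(configs)) || any(!nzchar(names(configs)))) {
    names(configs) <- paste0("config", seq_along(configs))
  }
  seeds <- seed + seq_len(repetitions) - 1
  acc <- matrix(NA_real_, repetitions, length(configs),
                dimnames = list(NULL, names(configs)))
  mf1 <- acc
  for (r in seq_len(repetitions)) {
    for (j in seq_along(configs)) {
      rep_args <- c(list(corp = corp, k = k, seed = seeds[r]), configs[[j]])
      report <- do.call(cross_validate, rep_args)
      acc[r, j] <- report$metrics$accuracy
      mf1[r, j] <- report$metrics$macro_f1
    }
  }
  structure(list(accuracy = acc, macro_f1 = mf1, seeds = seeds,
                 configs = configs),
            class = "repeated_cv")
}

#' One-sided paired t-test for metric improvement
#'
#' Tests whether metric `b` exceeds metric `a` on paired runs: with
#' d = b - a, `t = mean(d) / (sd(d) / sqrt(n))` (sample sd, n - 1), and
#' the p-value is the one-sided upper tail of Student's t with n - 1
#' degrees of freedom for the alternative `mean(b - a) > 0`.  Degenerate
#' conventions: all differences zero gives `(t = 0, p = 0.5)`; zero sd
#' with a nonzero mean gives `t = +/-Inf` and `p = 0` or `1` by sign.
#'
#' @param a,b equal-length (n >= 2) numeric vectors, paired by position.
#' @return A list with `t`, `p_value`, `df`, `mean_diff`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2) stop("paired t-test needs at least 2 pairs")
  d <- b - a
  md <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (md == 0) {
      return(list(t = 0, p_value = 0.5, df = n - 1, mean_diff = 0))
    }
    return(list(t = sign(md) * Inf, p_value = if (md > 0) 0 else 1,
                df = n - 1, mean_diff = md))
  }
  t_stat <- md / (sd_d / sqrt(n))
  list(t = t_stat,
       p_value = stats::pt(t_stat, df = n - 1, lower.tail = FALSE),
       df = n - 1, mean_diff = md)
}

#' Pairwise t-test table over a repeated-CV run
#'
#' For every ordered configuration pair (i < j in the configs order) and
#' both metrics (accuracy, macro-F), tests `config_i < config_j`.
#'
#' @param rep_cv a `repeated_cv` object.
#' @return Data frame with columns `comparison`, `metric`, `t`, `p_value`,
#'   `mean_diff`.
#' @export
pairwise_tests <- function(rep_cv) {
  stopifnot(inherits(rep_cv, "repeated_cv"))
  cfgs <- colnames(rep_cv$accuracy)
  out <- list()
  for (i in seq_along(cfgs)) {
    for (j in seq_along(cfgs)) {
      if (j <= i) next
      for (metric in c("accuracy", "macro_f1")) {
        mat <- rep_cv[[metric]]
        tt <- paired_t_test(mat[, i], mat[, j])
        out[[length(out) + 1]] <- data.frame(
          comparison = sprintf("%s<%s", cfgs[i], cfgs[j]),
          metric = metric, t = tt$t, p_value = tt$p_value,
          mean_diff = tt$mean_diff, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Frequency-threshold sweep for the n-gram feature set
#'
#' Cross-validates the FS1 (n-gram only) recipe at each frequency
#' threshold and tabulates pooled accuracy, reproducing the
#' threshold-versus-accuracy curve used to pick the default of 20.
#'
#' @param corp a fully labeled `topic_corpus`.
#' @param thresholds non-empty numeric vector of thresholds.
#' @param classifier `"nb"`, `"tree"` or `"svm"`.
#' @param k folds.
#' @param seed fold seed (shared across thresholds).
#' @param ... further arguments passed to [cross_validate()].
#' @return Data frame with columns `threshold`, `accuracy`, `macro_f1`.
#' @export
sweep_frequency_threshold <- function(corp, thresholds, classifier = "nb",
                                      k = 10, seed = 1, ...) {
  stopifnot(length(thresholds) >= 1)
  rows <- lapply(thresholds, function(th) {
    rep <- cross_validate(corp, recipe = "FS1", classifier = classifier,
                          k = k, seed = seed, freq_threshold = th, ...)
    data.frame(threshold = th, accuracy = rep$metrics$accuracy,
               macro_f1 = rep$metrics$macro_f1)
  })
  do.call(rbind, rows)
}

#' Write an evaluation report to disk
#'
#' `<base>.json` holds the full report (confusion matrix, metrics,
#' per-fold traces, configuration); `<base>.tsv` holds the per-class table
#' (class, precision, recall, F, support) plus a macro-average row.
#'
#' @param report an `evaluation_report`.
#' @param base output path prefix.
#' @return `base`, invisibly.
#' @export
write_report <- function(report, base) {
  stopifnot(inherits(report, "evaluation_report"))
  obj <- list(config = report$config,
              confusion = list(classes = rownames(report$confusion),
                               counts = unclass(report$confusion)),
              accuracy = report$metrics$accuracy,
              macro_precision = report$metrics$macro_precision,
              macro_recall = report$metrics$macro_recall,
              macro_f1 = report$metrics$macro_f1,
              per_class = report$metrics$per_class,
              per_fold = report$per_fold)
  jsonlite::write_json(obj, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  pc <- report$metrics$per_class
  avg <- data.frame(class = "average",
                    precision = report$metrics$macro_precision,
                    recall = report$metrics$macro_recall,
                    f1 = report$metrics$macro_f1,
                    support = sum(pc$support), stringsAsFactors = FALSE)
  utils::write.table(rbind(pc, avg), paste0(base, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(base)
}
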