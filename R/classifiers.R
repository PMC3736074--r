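# The three classifiers behind one training/prediction contract:
# Bernoulli naive Bayes, a C4.5-style gain-ratio decision tree, and a
# polynomial-kernel SVM (libsvm via e1071, wrapped one-vs-rest).
# Class order is always the corpus label-set order; every tie anywhere is
# broken toward the earliest class in that order.

.check_labels <- function(labels, classes) {
  if (!length(labels)) stop("empty training set")
  if (anyNA(labels)) stop("training requires a label on every message")
  missing <- setdiff(classes, labels)
  if (length(missing)) {
    stop(sprintf("class(es) with no training documents: %s",
                 paste(missing, collapse = ", ")))
  }
}

.as_dense01 <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}

#' Train a Bernoulli naive Bayes classifier
#'
#' Event model matched to binary presence features: class priors are
#' count ratios, and the per-class presence probability of feature j is
#' Laplace-smoothed, `(n_present + alpha) / (n_class + 2 * alpha)`.
#' Prediction scores a vector x by
#' `log P(c) + sum_j [x_j log p_cj + (1 - x_j) log (1 - p_cj)]`.
#'
#' @param matrix binary document-by-feature matrix.
#' @param labels class label per row.
#' @param classes class order; defaults to first-appearance order of
#'   `labels`.
#' @param alpha smoothing pseudo-count (default 1).
#' @return An object of class `topic_nb` with `log_prior`, `log_p` /
#'   `log_q` (log presence / absence probabilities, classes x features),
#'   `classes`, and `features`.
#' @export
train_naive_bayes <- function(matrix, labels, classes = unique(labels),
                              alpha = 1) {
  .check_labels(labels, classes)
  if (nrow(matrix) != length(labels)) stop("row/label length mismatch")
  X <- .as_dense01(matrix)
  m <- length(classes)
  p <- ncol(X)
  n_c <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  present <- matrix(0, m, p)
  for (j in seq_len(m)) {
    rows <- labels == classes[j]
    present[j, ] <- if (any(rows)) colSums(X[rows, , drop = FALSE]) else 0
  }
  prob <- (present + alpha) / (n_c + 2 * alpha)
  structure(list(log_prior = log(n_c / sum(n_c)),
                 log_p = log(prob), log_q = log1p(-prob),
                 classes = classes,
                 features = colnames(matrix), p = ncol(matrix),
                 alpha = alpha),
            class = "topic_nb")
}

#' @export
print.topic_nb <- function(x, ...) {
  cat(sprintf("<topic_nb> %d classes x %d features (alpha = %g)\n",
              length(x$classes), length(x$features), x$alpha))
  invisible(x)
}

#' Predict topic labels
#'
#' Shared contract for the three model kinds: input rows must match the
#' training feature space dimension; predictions are deterministic, ties
#' broken toward the earliest class in class order.
#'
#' @param object a fitted `topic_nb`, `topic_tree` or `topic_svm`.
#' @param matrix document-by-feature matrix over the training space.
#' @param type `"class"` for labels, `"score"` to also return the
#'   per-class score matrix (log-posterior up to a constant for NB, leaf
#'   class proportions for the tree, decision values for the SVM).
#' @param ... unused.
#' @return Character vector of labels, or a list `(labels, scores)`.
#' @name predict-topics
NULL

.check_dim <- function(p_model, matrix) {
  if (ncol(matrix) != p_model) {
    stop(sprintf("dimension mismatch: model has %d features, input has %d",
                 p_model, ncol(matrix)))
  }
}

.pick_class <- function(scores, classes) {
  # ties toward the earliest class (columns are in class order)
  classes[max.col(scores, ties.method = "first")]
}

#' @rdname predict-topics
#' @export
predict.topic_nb <- function(object, matrix, type = c("class", "score"), ...) {
  type <- match.arg(type)
  .check_dim(object$p, matrix)
  X <- .as_dense01(matrix)
  # x %*% (log p - log q) + sum log q, per class
  delta <- t(object$log_p - object$log_q)            # features x classes
  base <- rowSums(object$log_q)                      # per class
  scores <- X %*% delta
  scores <- sweep(scores, 2, base + object$log_prior, "+")
  labels <- .pick_class(scores, object$classes)
  if (type == "class") labels else list(labels = labels, scores = scores)
}

# ---------------------------------------------------------------------------
# gain-ratio decision tree (C4.5-style pre-pruned binary tree over presence
# features; no post-pruning or missing-value handling -- features here are
# binary and complete)

.entropy <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# per-feature gain and gain ratio at one node; counts: class x {absent,present}
.node_split_stats <- function(X, labels, classes) {
  n <- length(labels)
  n_c <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  h_node <- .entropy(n_c)
  ind <- matrix(0, n, length(classes))
  for (j in seq_along(classes)) ind[labels == classes[j], j] <- 1
  pres_c <- t(X) %*% ind                    # p x m
  n1 <- rowSums(pres_c)
  n0 <- n - n1
  h1 <- apply(pres_c, 1, .entropy)
  h0 <- apply(sweep(-pres_c, 2, n_c, "+"), 1, .entropy)
  gain <- h_node - (n1 / n) * h1 - (n0 / n) * h0
  split_info <- vapply(seq_along(n1), function(k) .entropy(c(n1[k], n0[k])),
                       numeric(1))
  list(gain = gain, split_info = split_info, n1 = n1, n0 = n0)
}

.majority <- function(labels, classes) {
  counts <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  classes[which.max(counts)]   # ties -> earliest class
}

.grow_tree <- function(X, labels, classes, min_leaf, depth) {
  leaf <- function() {
    counts <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
    list(leaf = TRUE, class = .majority(labels, classes), counts = counts)
  }
  if (length(unique(labels)) <= 1 || ncol(X) == 0) return(leaf())
  st <- .node_split_stats(X, labels, classes)
  ok <- st$gain > 1e-12 & st$split_info > 0 &
        st$n1 >= min_leaf & st$n0 >= min_leaf
  if (!any(ok)) return(leaf())
  ratio <- unname(ifelse(ok, st$gain / st$split_info, -Inf))
  j <- which.max(ratio)                      # ties -> lowest column index
  present <- X[, j] > 0
  list(leaf = FALSE, feature = j, feature_name = colnames(X)[j],
       present = .grow_tree(X[present, , drop = FALSE], labels[present],
                            classes, min_leaf, depth + 1),
       absent = .grow_tree(X[!present, , drop = FALSE], labels[!present],
                           classes, min_leaf, depth + 1))
}

#' Train a gain-ratio decision tree
#'
#' Binary splits on feature presence, chosen by gain ratio (information
#' gain divided by split information) among splits with positive gain and
#' both children of size at least `min_leaf`.  Recursion stops at class
#' purity, at the size floor, or when no positive-gain split exists;
#' leaves predict their majority class (ties toward class order).  This is
#' the C4.5 splitting rule with pre-pruning; error-based post-pruning and
#' missing-value handling are out of scope for complete binary features.
#'
#' @inheritParams train_naive_bayes
#' @param min_leaf minimum documents in each child of a split (default 2).
#' @return An object of class `topic_tree`.
#' @export
train_decision_tree <- function(matrix, labels, classes = unique(labels),
                                min_leaf = 2) {
  .check_labels(labels, classes)
  if (nrow(matrix) != length(labels)) stop("row/label length mismatch")
  X <- .as_dense01(matrix)
  root <- .grow_tree(X, labels, classes, min_leaf, 0)
  structure(list(root = root, classes = classes,
                 features = colnames(matrix), p = ncol(matrix),
                 min_leaf = min_leaf),
            class = "topic_tree")
}

.tree_depth <- function(node) {
  if (node$leaf) return(0L)
  1L + max(.tree_depth(node$present), .tree_depth(node$absent))
}

#' @export
print.topic_tree <- function(x, ...) {
  cat(sprintf("<topic_tree> %d classes x %d features, depth %d\n",
              length(x$classes), length(x$features), .tree_depth(x$root)))
  invisible(x)
}

.tree_scores_row <- function(node, xrow) {
  while (!node$leaf) {
    node <- if (xrow[node$feature] > 0) node$present else node$absent
  }
  node$counts / sum(node$counts)
}

#' @rdname predict-topics
#' @export
predict.topic_tree <- function(object, matrix, type = c("class", "score"), ...) {
  type <- match.arg(type)
  .check_dim(object$p, matrix)
  X <- .as_dense01(matrix)
  m <- length(object$classes)
  scores <- vapply(seq_len(nrow(X)), function(i)
    .tree_scores_row(object$root, X[i, ]), numeric(m))
  scores <- if (m == 1) matrix(scores, ncol = 1) else t(scores)
  labels <- .pick_class(scores, object$classes)
  if (type == "class") labels else list(labels = labels, scores = scores)
}

# ---------------------------------------------------------------------------
# polynomial-kernel SVM: libsvm (e1071) binary machines in a hand-rolled
# one-vs-rest scheme; prediction picks the class with the largest decision
# value, ties toward class order.

#' Train a polynomial-kernel SVM (one-vs-rest)
#'
#' One binary soft-margin machine per class (class vs. rest), polynomial
#' kernel `(gamma * <u, v> + coef0)^degree`; a new vector gets the class
#' whose machine yields the largest decision value.  The quadratic programs
#' are solved by libsvm; given fixed inputs and settings the fitted model
#' and all predictions are deterministic.
#'
#' @inheritParams train_naive_bayes
#' @param degree polynomial degree (default 1, i.e. linear).
#' @param C soft-margin cost (default 1).
#' @param gamma kernel scale; default `1 / ncol(matrix)`.
#' @param coef0 kernel offset (default 0).
#' @return An object of class `topic_svm`.
#' @export
train_svm <- function(matrix, labels, classes = unique(labels),
                      degree = 1, C = 1, gamma = NULL, coef0 = 0) {
  .check_labels(labels, classes)
  if (nrow(matrix) != length(labels)) stop("row/label length mismatch")
  stopifnot(degree >= 1, C > 0)
  X <- .as_dense01(matrix)
  if (ncol(X) == 0) stop("SVM requires at least one feature")
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  machines <- lapply(classes, function(cl) {
    y <- factor(ifelse(labels == cl, "yes", "no"), levels = c("yes", "no"))
    e1071::svm(X, y, scale = FALSE, type = "C-classification",
               kernel = "polynomial", degree = degree, cost = C,
               gamma = gamma, coef0 = coef0)
  })
  structure(list(machines = machines, classes = classes,
                 features = colnames(matrix), p = ncol(matrix),
                 degree = degree, C = C, gamma = gamma, coef0 = coef0),
            class = "topic_svm")
}

#' @export
print.topic_svm <- function(x, ...) {
  cat(sprintf("<topic_svm> %d one-vs-rest machines, degree %d, C = %g\n",
              length(x$machines), x$degree, x$C))
  invisible(x)
}

#' @rdname predict-topics
#' @export
predict.topic_svm <- function(object, matrix, type = c("class", "score"), ...) {
  type <- match.arg(type)
  .check_dim(object$p, matrix)
  X <- .as_dense01(matrix)
  scores <- vapply(object$machines, function(mod) {
    dv <- attr(stats::predict(mod, X, decision.values = TRUE),
               "decision.values")
    # orient so positive = the "yes" (target) class
    if (colnames(dv)[1] == "yes/no") dv[, 1] else -dv[, 1]
  }, numeric(nrow(X)))
  if (nrow(X) == 1) scores <- matrix(scores, nrow = 1)
  labels <- .pick_class(scores, object$classes)
  if (type == "class") labels else list(labels = labels, scores = scores)
}

# ---------------------------------------------------------------------------
# model persistence

#' Save or load a fitted model
#'
#' NB and tree models serialize to a documented JSON schema; the SVM
#' delegates to R serialization (RDS) since its support vectors live in
#' the fitted libsvm structures.  `load_model()` dispatches on the file
#' content.
#'
#' @param model a fitted `topic_nb`, `topic_tree` or `topic_svm`.
#' @param path output path (`.json` for nb/tree, `.rds` for svm).
#' @return `path` invisibly for `save_model()`; the model for
#'   `load_model()`.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "topic_svm")) {
    saveRDS(model, path)
    return(invisible(path))
  }
  if (inherits(model, "topic_nb")) {
    obj <- list(kind = "naive_bayes", classes = model$classes,
                features = model$features, p = model$p, alpha = model$alpha,
                log_prior = model$log_prior,
                log_p = model$log_p, log_q = model$log_q)
  } else if (inherits(model, "topic_tree")) {
    obj <- list(kind = "decision_tree", classes = model$classes,
                features = model$features, p = model$p, min_leaf = model$min_leaf,
                root = model$root)
  } else {
    stop("unknown model type")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.relist_tree <- function(node) {
  if (isTRUE(node$leaf)) {
    return(list(leaf = TRUE, class = node$class,
                counts = as.numeric(node$counts)))
  }
  list(leaf = FALSE, feature = as.integer(node$feature),
       feature_name = node$feature_name,
       present = .relist_tree(node$present),
       absent = .relist_tree(node$absent))
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  first <- readBin(path, "raw", n = 1)
  if (!length(first) || first != charToRaw("{")) {
    return(readRDS(path))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$kind == "naive_bayes") {
    structure(list(log_prior = as.numeric(obj$log_prior),
                   log_p = as.matrix(obj$log_p), log_q = as.matrix(obj$log_q),
                   classes = obj$classes, features = obj$features,
                   p = as.integer(obj$p), alpha = obj$alpha),
              class = "topic_nb")
  } else if (obj$kind == "decision_tree") {
    obj2 <- jsonlite::read_json(path, simplifyVector = FALSE)
    structure(list(root = .relist_tree(obj2$root), classes = obj$classes,
                   features = obj$features, p = as.integer(obj$p),
                   min_leaf = obj$min_leaf),
              class = "topic_tree")
  } else {
    stop(sprintf("unknown model kind '%s' in %s", obj$kind, path))
  }
}
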