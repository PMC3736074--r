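# Information-gain feature scoring and threshold-based reduction.
#
# For feature t with binary presence over N labeled documents and classes
# c_1..c_m, the gain is
#
#   G(t) = - sum_i P(c_i) log P(c_i)
#          + P(t)    sum_i P(c_i | t)    log P(c_i | t)
#          + P(tbar) sum_i P(c_i | tbar) log P(c_i | tbar)
#
# with maximum-likelihood (count-ratio) probabilities, the convention
# 0 * log 0 = 0, and base-2 logarithms (scores in bits), so
# 0 <= G(t) <= log2(m).

.xlogx <- function(p, base = 2) ifelse(p > 0, p * log(p, base = base), 0)

#' Information gain of one binary feature
#'
#' @param presence binary (0/1 or logical) vector: feature present in each
#'   document.
#' @param labels class label per document, same length.
#' @param base logarithm base; 2 (bits, the default) or `exp(1)` (nats).
#'   Threshold semantics downstream are base-dependent.
#' @return The gain G(t), a non-negative scalar bounded by
#'   `log(m, base)` for m classes.
#' @export
information_gain <- function(presence, labels, base = 2) {
  presence <- as.numeric(presence)
  if (length(presence) != length(labels)) {
    stop("presence and labels must have equal length")
  }
  n <- length(labels)
  stopifnot(n >= 1)
  classes <- unique(labels)
  n_c <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  n_t <- sum(presence > 0)
  n_ct <- vapply(classes, function(cl) sum(labels == cl & presence > 0), numeric(1))

  p_c <- n_c / n
  prior <- -sum(.xlogx(p_c, base))
  p_t <- n_t / n
  term_t <- if (n_t > 0) p_t * sum(.xlogx(n_ct / n_t, base)) else 0
  n_bar <- n - n_t
  term_bar <- if (n_bar > 0) {
    (n_bar / n) * sum(.xlogx((n_c - n_ct) / n_bar, base))
  } else 0
  g <- prior + term_t + term_bar
  max(g, 0)  # clamp tiny negative rounding residue
}

#' Information gain of every feature in a matrix
#'
#' Vectorized over columns; equivalent to [information_gain()] per column.
#'
#' @param matrix binary document-by-feature matrix (dense or sparse),
#'   labeled rows only.
#' @param labels class label per row; must contain no `NA`.
#' @param base logarithm base (default 2).
#' @return An object of class `ig_scores`: named numeric vector of gains
#'   (names = column names), with attributes `n_classes`, `n_documents`
#'   and `base`.
#' @export
score_all <- function(matrix, labels, base = 2) {
  if (anyNA(labels)) stop("score_all requires labels on every row")
  if (nrow(matrix) != length(labels)) stop("row/label length mismatch")
  classes <- unique(labels)
  m <- length(classes)
  n <- length(labels)
  ind <- matrix(0, n, m)                         # class indicators, n x m
  for (j in seq_len(m)) ind[labels == classes[j], j] <- 1
  n_c <- colSums(ind)
  X <- if (inherits(matrix, "Matrix")) matrix else Matrix::Matrix(matrix, sparse = TRUE)
  X <- Matrix::Matrix((X > 0) * 1, sparse = TRUE)  # presence, not counts
  n_ct <- as.matrix(Matrix::crossprod(X, ind))   # p x m, present counts
  n_t <- Matrix::colSums(X)                      # per feature

  prior <- -sum(.xlogx(n_c / n, base))
  pt <- n_t / n
  cond_t <- n_ct / ifelse(n_t > 0, n_t, 1)
  term_t <- pt * rowSums(.xlogx(cond_t, base))
  n_bar <- n - n_t
  cond_bar <- sweep(-n_ct, 2, n_c, "+") / ifelse(n_bar > 0, n_bar, 1)
  term_bar <- (n_bar / n) * rowSums(.xlogx(cond_bar, base))
  g <- pmax(prior + term_t + term_bar, 0)
  names(g) <- colnames(matrix)
  structure(g, class = "ig_scores",
            n_classes = m, n_documents = n, base = base)
}

#' @export
print.ig_scores <- function(x, ...) {
  cat(sprintf("<ig_scores> %d features, %d classes, %d documents (log base %g)\n",
              length(x), attr(x, "n_classes"), attr(x, "n_documents"),
              attr(x, "base")))
  invisible(x)
}

#' Select features above an information-gain threshold
#'
#' Retains descriptors whose gain is *strictly* greater than the threshold
#' (default 0.0025 bits; the boundary value itself is excluded).
#'
#' @param scores an `ig_scores` vector from [score_all()].
#' @param threshold non-negative gain cut.
#' @return Character vector of retained descriptor names, in the scores'
#'   original order.
#' @export
select_features <- function(scores, threshold = 0.0025) {
  stopifnot(threshold >= 0)
  names(scores)[as.numeric(scores) > threshold]
}

#' Write information-gain scores as TSV
#'
#' Two columns (`feature`, `gain`), sorted by descending gain (ties by
#' feature name for determinism).
#'
#' @param scores an `ig_scores` vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ig_scores <- function(scores, path) {
  ord <- order(-as.numeric(scores), names(scores), method = "radix")
  df <- data.frame(feature = names(scores)[ord],
                   gain = as.numeric(scores)[ord])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
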