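# Independent brute-force oracles, kept deliberately separate from the
# package implementations they check.

# entropy-based information gain evaluated term by term, straight from the
# defining expression (priors, P(t), conditionals given presence/absence)
oracle_information_gain <- function(presence, labels) {
  n <- length(labels)
  classes <- unique(labels)
  lg <- function(p) if (p > 0) log2(p) else 0
  g <- 0
  for (cl in classes) {
    p_c <- sum(labels == cl) / n
    g <- g - p_c * lg(p_c)
  }
  p_t <- sum(presence > 0) / n
  if (p_t > 0) {
    acc <- 0
    for (cl in classes) {
      p_ct <- sum(labels == cl & presence > 0) / sum(presence > 0)
      acc <- acc + p_ct * lg(p_ct)
    }
    g <- g + p_t * acc
  }
  p_tbar <- 1 - p_t
  if (p_tbar > 0) {
    acc <- 0
    for (cl in classes) {
      p_cbar <- sum(labels == cl & presence == 0) / sum(presence == 0)
      acc <- acc + p_cbar * lg(p_cbar)
    }
    g <- g + p_tbar * acc
  }
  g
}

# brute-force gain ratio of every feature at a tree root
oracle_gain_ratio <- function(X, labels) {
  n <- length(labels)
  ent <- function(v) {
    tb <- table(v)
    p <- tb[tb > 0] / sum(tb)
    -sum(p * log2(p))
  }
  h0 <- ent(labels)
  vapply(seq_len(ncol(X)), function(j) {
    pres <- X[, j] > 0
    n1 <- sum(pres); n0 <- n - n1
    gain <- h0 -
      (n1 / n) * (if (n1) ent(labels[pres]) else 0) -
      (n0 / n) * (if (n0) ent(labels[!pres]) else 0)
    si <- ent(ifelse(pres, "p", "a"))
    if (si > 0) gain / si else NA_real_
  }, numeric(1))
}

# closed-form upper-tail Student-t probability for 2 degrees of freedom
oracle_t2_upper <- function(t) 0.5 - t / (2 * sqrt(t^2 + 2))

# random binary matrix with labels, for property loops
random_labeled_matrix <- function(n_docs, n_feat, n_classes, seed) {
  set.seed(seed)
  X <- matrix(rbinom(n_docs * n_feat, 1, runif(1, 0.2, 0.8)), n_docs, n_feat)
  colnames(X) <- paste0("f", seq_len(n_feat))
  labels <- sample(paste0("c", seq_len(n_classes)), n_docs, replace = TRUE)
  # ensure every class appears
  labels[seq_len(n_classes)] <- paste0("c", seq_len(n_classes))
  list(X = X, labels = labels)
}
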