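# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# implementation) so they can act as ground truth.

random_bipartite <- function(n_mirnas, n_genes, p, prefix = "") {
  m <- outer(seq_len(n_mirnas), seq_len(n_genes),
             function(i, j) stats::runif(n_mirnas * n_genes)) < p
  hits <- which(m, arr.ind = TRUE)
  if (nrow(hits) == 0) hits <- cbind(1, 1)
  regulatory_network(sprintf("%sm%02d", prefix, hits[, 1]),
                     sprintf("%sg%02d", prefix, hits[, 2]))
}

nod_oracle <- function(net, mirna) {
  targets <- net$edges$gene[net$edges$mirna == mirna]
  n <- 0L
  for (g in targets) {
    regulators <- unique(net$edges$mirna[net$edges$gene == g])
    if (length(regulators) == 1 && regulators == mirna) n <- n + 1L
  }
  n
}

tfp_oracle <- function(net, mirna, tf_set) {
  targets <- net$edges$gene[net$edges$mirna == mirna]
  hit <- 0L
  for (g in targets) if (g %in% tf_set) hit <- hit + 1L
  hit / length(targets)
}

auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# MOST oracle: explicit per-k loop over top-k subsets; shares only the
# memoized Gaussian order-statistic constants with the implementation.
most_oracle <- function(disease, control) {
  sc <- stats::sd(control)
  d <- sort((disease - mean(control)) / sc, decreasing = TRUE)
  const <- mirnetscreen:::.most_constants(length(d))
  best <- -Inf
  for (k in seq_along(d)) {
    s <- 0
    for (i in seq_len(k)) s <- s + d[i]
    z <- (s - const$mu[k]) / const$sigma[k]
    if (z > best) best <- z
  }
  best
}

lsoss_oracle <- function(disease, control) {
  d <- sort(disease, decreasing = TRUE)
  nd <- length(d); nc <- length(control)
  sumsq <- function(v) {
    m <- sum(v) / length(v)
    s <- 0
    for (x in v) s <- s + (x - m)^2
    s
  }
  best_ss <- Inf; best_k <- 1L
  for (k in 1:(nd - 1)) {
    s2 <- sumsq(d[1:k]) + sumsq(d[(k + 1):nd])
    if (s2 < best_ss) { best_ss <- s2; best_k <- k }
  }
  pv <- (best_ss + sumsq(control)) / (nd + nc - 3)
  (mean(d[1:best_k]) - mean(control)) / sqrt(pv)
}

# exhaustive nearest-neighbour imputation: mean squared difference over
# co-observed samples, neighbours restricted to features observed at the
# target sample
knn_oracle <- function(values, k) {
  out <- values
  for (f in seq_len(nrow(values))) {
    for (s in seq_len(ncol(values))) {
      if (!is.na(values[f, s])) next
      d <- rep(Inf, nrow(values))
      for (f2 in seq_len(nrow(values))) {
        if (f2 == f || is.na(values[f2, s])) next
        shared <- !is.na(values[f, ]) & !is.na(values[f2, ])
        if (!any(shared)) next
        d[f2] <- mean((values[f, shared] - values[f2, shared])^2)
      }
      ord <- order(d, rownames(values))
      ord <- ord[is.finite(d[ord])]
      nn <- ord[seq_len(min(k, length(ord)))]
      out[f, s] <- mean(values[nn, s])
    }
  }
  out
}

# all 0/1 bipartite adjacency matrices with the given margins
enumerate_margin_matrices <- function(row_sums, col_sums) {
  nr <- length(row_sums); nc <- length(col_sums)
  out <- list()
  for (code in 0:(2^(nr * nc) - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(nr * nc)]
    m <- matrix(bits, nrow = nr)
    if (all(rowSums(m) == row_sums) && all(colSums(m) == col_sums)) {
      out[[length(out) + 1]] <- m
    }
  }
  out
}

make_study <- function(n_features = 20, n_per_group = 6, seed = 1,
                       shift_features = character(), shift = 0,
                       subgroup = NULL) {
  set.seed(seed)
  ids <- sprintf("f%03d", seq_len(n_features))
  vals <- matrix(stats::rnorm(n_features * 2 * n_per_group, 7, 1),
                 nrow = n_features, dimnames = list(ids, NULL))
  colnames(vals) <- sprintf("s%02d", seq_len(2 * n_per_group))
  groups <- rep(c("disease", "control"), each = n_per_group)
  for (f in shift_features) {
    cols <- if (is.null(subgroup)) seq_len(n_per_group)
            else sample(seq_len(n_per_group), subgroup)
    vals[f, cols] <- vals[f, cols] + shift
  }
  expression_study(vals, groups)
}
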