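# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations.

oracle_dist <- function(a, b, metric) {
  d2 <- sum((a - b)^2)
  if (metric == "euclidean") sqrt(d2) else d2
}

# k-distance of row i within X excluding row i.
oracle_kdist <- function(i, X, k, metric) {
  d <- numeric(0)
  for (j in seq_len(nrow(X))) {
    if (j != i) d <- c(d, oracle_dist(X[i, ], X[j, ], metric))
  }
  sort(d)[k]
}

# Neighborhood row indices of point p among rows of X, excluding `excl`.
oracle_nbrs <- function(p, X, k, metric, excl = integer(0)) {
  cand <- setdiff(seq_len(nrow(X)), excl)
  d <- vapply(cand, function(j) oracle_dist(p, X[j, ], metric), numeric(1))
  kd <- sort(d)[k]
  cand[d <= kd]
}

oracle_lrd <- function(p, X, k, metric, variant, excl = integer(0)) {
  nb <- oracle_nbrs(p, X, k, metric, excl)
  reach <- vapply(nb, function(j) {
    d <- oracle_dist(p, X[j, ], metric)
    if (variant == "reachability") max(oracle_kdist(j, X, k, metric), d) else d
  }, numeric(1))
  m <- mean(reach)
  if (m == 0) Inf else 1 / m
}

oracle_lof <- function(p, X, k, metric, variant) {
  excl <- integer(0)
  for (j in seq_len(nrow(X))) {
    if (all(X[j, ] == p)) { excl <- j; break }
  }
  lp <- oracle_lrd(p, X, k, metric, variant, excl)
  if (!is.finite(lp)) return(1)
  nb <- oracle_nbrs(p, X, k, metric, excl)
  ratios <- vapply(nb, function(j) {
    oracle_lrd(X[j, ], X, k, metric, variant, j) / lp
  }, numeric(1))
  mean(ratios)
}

# Pair-counting AUC by explicit double loop.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (x in pos) for (y in neg) {
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Maximum Youden J over every candidate threshold, by direct counting.
oracle_max_j <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  best <- -Inf
  for (t in cand) {
    sens <- sum(scores > t & labels == 1) / sum(labels == 1)
    spec <- sum(scores <= t & labels == 0) / sum(labels == 0)
    best <- max(best, sens + spec - 1)
  }
  best
}

# DeLong structural components by explicit loops.
oracle_delong_var <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  n1 <- length(pos)
  n0 <- length(neg)
  v10 <- numeric(n1)
  for (i in seq_len(n1)) {
    acc <- 0
    for (j in seq_len(n0)) {
      acc <- acc + if (pos[i] > neg[j]) 1 else if (pos[i] == neg[j]) 0.5 else 0
    }
    v10[i] <- acc / n0
  }
  v01 <- numeric(n0)
  for (j in seq_len(n0)) {
    acc <- 0
    for (i in seq_len(n1)) {
      acc <- acc + if (pos[i] > neg[j]) 1 else if (pos[i] == neg[j]) 0.5 else 0
    }
    v01[j] <- acc / n1
  }
  stats::var(v10) / n1 + stats::var(v01) / n0
}
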