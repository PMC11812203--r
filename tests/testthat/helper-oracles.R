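# Independent brute-force oracles used to cross-check the implementation on
# small instances. Each is written from the defining formula, not from the
# code path it checks.

# Spearman rho from the rank-difference formula (tie-free inputs only).
oracle_spearman <- function(x, y) {
  stopifnot(!anyDuplicated(x), !anyDuplicated(y))
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Benjamini-Hochberg step-up from the definition: p_(i) * n / i, cumulative
# minimum from the largest p down, capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Two-sided Wilcoxon rank-sum p by exhaustive enumeration of all C(m+n, m)
# group assignments of the pooled ranks (tie-free inputs).
oracle_wilcoxon <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  m <- length(x)
  w_obs <- sum(r[seq_len(m)])
  all_w <- apply(combn(length(pooled), m), 2L, function(idx) sum(r[idx]))
  mu <- m * (length(pooled) + 1) / 2
  mean(abs(all_w - mu) >= abs(w_obs - mu) - 1e-9)
}

# Hypergeometric over-representation p by direct enumeration of the tail.
oracle_hyper <- function(overlap, pathway_size, universe_size, selected_size) {
  ks <- overlap:min(pathway_size, selected_size)
  sum(choose(pathway_size, ks) *
        choose(universe_size - pathway_size, selected_size - ks)) /
    choose(universe_size, selected_size)
}

# Breadth-first-search shortest paths on an undirected edge list.
oracle_bfs <- function(nodes, edges, from) {
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  frontier <- from
  while (length(frontier) > 0L) {
    nxt <- character(0)
    for (v in frontier) {
      nb <- c(edges$to[edges$from == v], edges$from[edges$to == v])
      new <- nb[dist[nb] == Inf]
      dist[new] <- dist[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  dist
}

# ROC AUC as the normalized Mann-Whitney U: fraction of (pos, neg) pairs
# where pos wins, ties counted half.
oracle_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Sample standard deviation z-score.
oracle_zscore <- function(x) (x - mean(x)) / sd(x)
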