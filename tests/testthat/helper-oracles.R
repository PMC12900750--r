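# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths they verify.

# Truncated power-series subgraph centrality: sum_{k<=kmax} (A^k)_ii / k!
oracle_sc_series <- function(adj, kmax = 30) {
  n <- nrow(adj)
  acc <- diag(n)
  term <- diag(n)
  for (k in seq_len(kmax)) {
    term <- term %*% adj / k
    acc <- acc + term
  }
  stats::setNames(diag(acc), rownames(adj))
}

# Exact two-sided binomial split p-value by direct enumeration with the
# log-factorial pmf (phi = 0 case of the conditional test).
oracle_binom_split_p <- function(y1, t, n1, n2) {
  if (t == 0) return(1)
  pr <- n1 / (n1 + n2)
  ys <- 0:t
  logp <- lgamma(t + 1) - lgamma(ys + 1) - lgamma(t - ys + 1) +
    ys * log(pr) + (t - ys) * log(1 - pr)
  p <- exp(logp)
  sum(p[logp <= logp[y1 + 1] + 1e-12]) / sum(p)
}

# AUC by explicit pair counting over all case-control pairs.
oracle_auc_pairs <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cs) * length(ct))
}

# First-order partial correlation from the recursive closed form, applied to
# Spearman correlations of the three variables.
oracle_partial_spearman_1cov <- function(x, y, z) {
  rxy <- stats::cor(x, y, method = "spearman")
  rxz <- stats::cor(x, z, method = "spearman")
  ryz <- stats::cor(y, z, method = "spearman")
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Random simple undirected graph on n nodes with edge probability p.
random_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(graph = g, adj = adj, nodes = nodes)
}
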