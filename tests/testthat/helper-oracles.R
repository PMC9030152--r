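# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the code paths they check.

# Mann-Whitney by exhaustive enumeration: U for every way of labeling the
# pooled values, two-sided p as the doubled smaller tail.
oracle_mann_whitney <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  u_of <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(n, n1), 2L, u_of)
  p <- min(1, 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs)))
  list(u = u_obs, p = p)
}

# MCODE vertex weight by iterative peeling on an adjacency matrix: for each
# k, strip vertices of degree < k until stable; the highest non-empty core
# gives k and its density.
oracle_mcode_weight <- function(adj, v) {
  nb <- c(v, which(adj[v, ] == 1))
  B <- adj[nb, nb, drop = FALSE]
  if (sum(B) == 0) return(0)
  best_k <- 0L
  best <- seq_len(nrow(B))
  for (k in seq_len(nrow(B))) {
    keep <- seq_len(nrow(B))
    repeat {
      deg <- rowSums(B[keep, keep, drop = FALSE])
      bad <- keep[deg < k]
      if (!length(bad) || !length(keep)) break
      keep <- setdiff(keep, bad)
    }
    if (length(keep)) {
      best_k <- k
      best <- keep
    } else break
  }
  nv <- length(best)
  m <- sum(B[best, best]) / 2
  best_k * 2 * m / (nv * (nv - 1))
}

# Random simple undirected graph on n nodes as (igraph, adjacency) pair.
random_graph_pair <- function(n, p = 0.4) {
  adj <- matrix(0L, n, n)
  on <- stats::runif(n * (n - 1) / 2) < p
  adj[upper.tri(adj)][on] <- 1L
  adj <- adj + t(adj)
  dimnames(adj) <- list(letters[seq_len(n)], letters[seq_len(n)])
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(g = g, adj = adj)
}

# Small alteration-call fixture.
make_calls <- function(...) {
  rows <- list(...)
  data.frame(sample_id = vapply(rows, `[[`, character(1), 1L),
             gene = vapply(rows, `[[`, character(1), 2L),
             category = vapply(rows, `[[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

# Edge-table fixture.
make_edges <- function(a, b, channel, score) {
  data.frame(gene_a = a, gene_b = b, channel = channel, score = score,
             stringsAsFactors = FALSE)
}

# Dependency matrix with constant per-gene scores.
const_dep_matrix <- function(gene_scores, n_lines = 4L, prefix = "CL") {
  m <- matrix(rep(gene_scores, each = n_lines), nrow = n_lines,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(n_lines)),
                              names(gene_scores)))
  m
}
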