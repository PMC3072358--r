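# Independent oracles and tiny fixture builders shared across test files.

# Brute-force betweenness by explicit shortest-path counting: run BFS from
# every source to get distances and path counts, then for every unordered
# pair (s, t) and interior vertex v add
#   sigma_s(v) * sigma_t(v) / sigma_s(t)   when  d_s(v) + d_t(v) = d_s(t).
# Edge list is a two-column matrix of 1-based vertex indices; n vertices.
brute_betweenness <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(dist[s, w])) {
          dist[s, w] <- dist[s, v] + 1
          queue <- c(queue, w)
        }
        if (dist[s, w] == dist[s, v] + 1)
          sigma[s, w] <- sigma[s, w] + sigma[s, v]
      }
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (is.infinite(dist[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (dist[s, v] + dist[t, v] == dist[s, t])
          bc[v] <- bc[v] + sigma[s, v] * sigma[t, v] / sigma[s, t]
      }
    }
  }
  bc
}

# Closed-form Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- rev(q_sorted)
  q
}

# Exact two-sided rank-sum p by full enumeration of label assignments,
# written independently of the package (operates on the pooled values, uses
# the 2*min(tails) convention).
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  sets <- combn(length(r), n1)
  w_all <- apply(sets, 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
}

# Fisher p for a 2x2 table by exhaustive enumeration over all tables with
# the same margins, summing probabilities <= that of the observed table.
oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  prob <- function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }
  p_obs <- prob(a)
  sum(vapply(lo:hi, function(x) {
    px <- prob(x)
    if (px <= p_obs * (1 + 1e-7)) px else 0
  }, numeric(1)))
}

# seven-node ladder for a human-like focal species
toy_ladder <- function(focal = "human") {
  sp <- data.frame(
    species_id = c("ecoli", "bsub", "yeast", "spombe", "fungus1",
                   "fly", "worm", "zebrafish", "chicken",
                   "mouse", "rat", "chimp", focal),
    node_label = c("LUCA", "LUCA", "eukaryotes", "eukaryotes", "opisthokonts",
                   "metazoans", "metazoans", "vertebrates", "vertebrates",
                   "mammals", "mammals", "group_specific", "group_specific"),
    stringsAsFactors = FALSE)
  build_ladder(sp, focal)
}

# cluster table builder: members is a list of c(species, gene) pairs
toy_clusters <- function(...) {
  rows <- list(...)
  ortholog_clusters(do.call(rbind, lapply(rows, function(r)
    data.frame(cluster_id = r[[1]], level = r[[2]], species_id = r[[3]],
               gene_id = r[[4]], stringsAsFactors = FALSE))))
}

# random simple graph as an interactome-compatible evidence table
random_graph_evidence <- function(n, p_edge, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  list(
    n = n,
    edges = pairs,
    evidence = if (nrow(pairs)) data.frame(
      gene_a = sprintf("v%03d", pairs[, 1]),
      gene_b = sprintf("v%03d", pairs[, 2]),
      source_db = "test", experiment_id = "E1",
      provenance_class = "direct", stringsAsFactors = FALSE)
    else NULL)
}
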