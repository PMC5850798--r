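# Independent brute-force oracles used to check the implementation. These
# deliberately avoid the package's own graph/statistics code paths.

# upward reachability (child -> parent) by plain breadth-first search over
# the edge data.frame
bfs_ancestors <- function(edges, start, relations = c("is_a", "part_of")) {
  edges <- edges[edges$relation %in% relations, , drop = FALSE]
  seen <- character()
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(edges$parent[edges$child %in% frontier])
    nxt <- setdiff(nxt, c(seen, start))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

bfs_descendants <- function(edges, start, relations = c("is_a", "part_of")) {
  edges <- edges[edges$relation %in% relations, , drop = FALSE]
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(edges$child[edges$parent %in% frontier])
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# upper-tail hypergeometric p-value by direct summation of the density
hyper_tail_oracle <- function(a, K, n_fg, n_ref) {
  ks <- a:min(K, n_fg)
  sum(choose(K, ks) * choose(n_ref - K, n_fg - ks) / choose(n_ref, n_fg))
}

# Benjamini-Hochberg step-up by explicit sort and cumulative minimum
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# two-sided Fisher exact p by enumerating all tables with fixed margins
fisher_two_sided_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  ks <- max(0, k - n):min(k, m)
  dens <- choose(m, ks) * choose(n, k - ks) / choose(m + n, k)
  obs <- dens[ks == a]
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# Mantel-Haenszel odds ratio computed directly from a stratum data.frame
mh_oracle <- function(strata) {
  n <- strata$a + strata$b + strata$c + strata$d
  sum(strata$a * strata$d / n) / sum(strata$b * strata$c / n)
}

# small fixed ontology: root R, children M1 M2, leaves under both
toy_ontology <- function() {
  edges <- data.frame(
    child = c("M1", "M2", "L1", "L2", "L3"),
    parent = c("R", "R", "M1", "M1", "M2"),
    relation = c("is_a", "is_a", "is_a", "part_of", "is_a"),
    stringsAsFactors = FALSE)
  ontology_graph(c("R", "M1", "M2", "L1", "L2", "L3"), edges = edges)
}

# random DAG over n terms (same scheme as the generator but built here)
random_dag <- function(n, seed) {
  set.seed(seed)
  terms <- sprintf("T%03d", seq_len(n))
  ec <- ep <- er <- character()
  for (i in 2:n) {
    k <- if (i > 2 && runif(1) < 0.4) 2 else 1
    for (p in sample(i - 1, min(k, i - 1))) {
      ec <- c(ec, terms[i]); ep <- c(ep, terms[p])
      er <- c(er, sample(c("is_a", "part_of"), 1))
    }
  }
  list(terms = terms,
       edges = data.frame(child = ec, parent = ep, relation = er,
                          stringsAsFactors = FALSE))
}

# recursively reverse child order of a gene tree (topology-invariance checks)
reverse_children <- function(node) {
  if (isTRUE(node$leaf)) return(node)
  node$children <- rev(lapply(node$children, reverse_children))
  node
}
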