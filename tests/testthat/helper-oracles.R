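# Independent brute-force oracles used to validate the package's graph
# algorithms on small cases. These deliberately share no code with the
# implementation: reachability is done by boolean matrix powers, maximum
# matching by exhaustive assignment enumeration, and propagation by
# explicit walk enumeration.

# Boolean-matrix-power m-reach: adj[i, j] = 1 iff link i -> j.
oracle_reach <- function(adj, m) {
  n <- nrow(adj)
  a <- (adj > 0) * 1
  step <- a
  within_m <- a
  if (m > 1) for (l in 2:m) {
    step <- (step %*% a > 0) * 1
    within_m <- ((within_m + step) > 0) * 1
  }
  diag(within_m) <- 0
  rowSums(within_m) / (n - 1)
}

oracle_grc <- function(adj, m) {
  r <- oracle_reach(adj, m)
  sum(max(r) - r) / (nrow(adj) - 1)
}

# Maximum bipartite matching size by exhaustive enumeration of injective
# left -> right assignments (feasible for <= 8 left nodes).
oracle_matching <- function(n_left, left, right) {
  best <- 0L
  rec <- function(idx, used_r, count) {
    remaining <- n_left - idx + 1L
    if (count + remaining <= best) return()
    if (idx > n_left) {
      if (count > best) best <<- count
      return()
    }
    rec(idx + 1L, used_r, count)
    for (r in right[left == idx]) {
      if (r %in% used_r) next
      rec(idx + 1L, c(used_r, r), count + 1L)
    }
  }
  rec(1L, integer(0), 0L)
  best
}

# Control centrality by the oracle: transitive-closure reachable set via
# matrix powers, then exhaustive matching on the bipartite representation
# with the external source attached to node i.
oracle_control <- function(adj, i) {
  n <- nrow(adj)
  closure <- (adj > 0) * 1
  step <- closure
  for (l in seq_len(n)) {
    step <- (step %*% closure > 0) * 1
    closure <- ((closure + step) > 0) * 1
  }
  reach <- sort(unique(c(i, which(closure[i, ] > 0))))
  sub <- adj[reach, reach, drop = FALSE]
  k <- length(reach)
  el <- which(sub > 0, arr.ind = TRUE)
  left <- c(el[, 1L], k + 1L)               # source s is left node k + 1
  right <- c(el[, 2L], match(i, reach))
  oracle_matching(k + 1L, left, right)
}

# Effective propagation coefficients by explicit walk enumeration:
# every directed walk from i of length 1..l_max contributes the product
# of the signed coefficients along it to its endpoint.
oracle_effective_beta <- function(bmat, i, l_max) {
  p <- nrow(bmat)
  acc <- numeric(p)
  rec <- function(at, prod, len) {
    if (len == l_max) return()
    for (j in which(bmat[, at] != 0)) {
      acc[j] <<- acc[j] + prod * bmat[j, at]
      rec(j, prod * bmat[j, at], len + 1L)
    }
  }
  rec(i, 1, 0L)
  acc
}

# Random simple digraph as an adjacency matrix (no self-loops).
random_adjacency <- function(n, p_edge) {
  adj <- matrix(as.numeric(stats::runif(n * n) < p_edge), n, n)
  diag(adj) <- 0
  adj
}

adj_to_igraph <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "directed")
  igraph::set_vertex_attr(g, "name",
                          value = sprintf("n%02d", seq_len(nrow(adj))))
}

# signed_network from a dense signed coefficient matrix b[j, i].
net_from_beta <- function(bmat, threshold = NULL) {
  nm <- sprintf("n%02d", seq_len(nrow(bmat)))
  dimnames(bmat) <- list(nm, nm)
  signed_network(bmat, threshold = threshold)
}

# Layered feed-forward graph: `layers` layers of `width` nodes, each
# possible link from layer l to layer l+1 present with prob p_edge.
layered_graph <- function(layers, width, p_edge, seed) {
  n <- layers * width
  adj <- matrix(0, n, n)
  withr::with_seed(seed, {
    for (l in seq_len(layers - 1L)) {
      src <- ((l - 1L) * width + 1L):(l * width)
      dst <- (l * width + 1L):((l + 1L) * width)
      for (i in src) for (j in dst)
        if (stats::runif(1) < p_edge) adj[i, j] <- 1
    }
  })
  adj
}

derive_seed_for_test <- function(seed, stream)
  methylnet:::derive_seed(seed, stream)

# Small deterministic fixture matrix with ages.
toy_matrix <- function(n_cpgs = 4, n_samples = 6) {
  vals <- matrix(seq(0.1, 0.9, length.out = n_cpgs * n_samples),
                 n_cpgs, n_samples,
                 dimnames = list(sprintf("cg%d", seq_len(n_cpgs)),
                                 sprintf("s%d", seq_len(n_samples))))
  methyl_matrix(vals, ages = seq(30, 80, length.out = n_samples))
}
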