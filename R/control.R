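#' Subgraph reachable from a node
#'
#' Induced subgraph on the node itself plus every node reachable from it
#' along directed paths, keeping all links among them.
#'
#' @param graph A [signed_network] or igraph directed graph.
#' @param node Node name or index.
#' @return An igraph directed graph.
#' @export
reachable_subgraph <- function(graph, node) {
  g <- as_igraph(graph)
  if (is.character(node) && !node %in% igraph::V(g)$name)
    stop("node '", node, "' not in graph")
  reach <- igraph::subcomponent(g, node, mode = "out")
  igraph::induced_subgraph(g, reach)
}

#' Control centrality of a node
#'
#' The maximum number of nodes that a single external signal injected at
#' node i can drive, computed combinatorially via structural
#' controllability: take the subgraph reachable from i, attach an
#' auxiliary external source s with the single link s -> i, build the
#' bipartite representation (each link u -> v becomes an edge between
#' u's out-copy and v's in-copy), and count the links of a maximum
#' bipartite matching. Link weights play no role; only the unweighted
#' structure matters for structural controllability.
#'
#' The external link s -> i participates in the matching, so C(i) >= 1
#' (a node always drives at least itself) and the head of a directed
#' chain has C equal to the full chain length. The exclusive convention
#' (counting only nodes other than i, i.e. C(i) - 1) is available with
#' `include_self = FALSE`.
#'
#' @inheritParams reachable_subgraph
#' @param include_self Count node i itself among the controlled nodes
#'   (default `TRUE`).
#' @return Integer count.
#' @export
control_centrality <- function(graph, node, include_self = TRUE) {
  g <- as_igraph(graph)
  if (is.character(node) && !node %in% igraph::V(g)$name)
    stop("node '", node, "' not in graph")
  vid <- as.integer(igraph::V(g)[node])
  reach <- sort(as.integer(igraph::subcomponent(g, vid, mode = "out")))
  sub <- igraph::induced_subgraph(g, reach)
  el <- igraph::as_edgelist(sub, names = FALSE)
  n_sub <- igraph::vcount(sub)
  i_idx <- match(vid, reach)
  # bipartite graph: out-copies 1..n_sub+1 (node n_sub+1 = external source
  # s), in-copies of the subgraph nodes; s -> i plus every subgraph link
  left_n <- n_sub + 1L
  edges_l <- c(el[, 1L], left_n)
  edges_r <- c(el[, 2L], i_idx)
  size <- max_bipartite_matching_size(left_n, n_sub, edges_l, edges_r)
  as.integer(size) - if (include_self) 0L else 1L
}

# Maximum matching size of a bipartite graph given as parallel edge
# vectors (left index, right index), via igraph's bipartite matching.
max_bipartite_matching_size <- function(n_left, n_right, left, right) {
  if (!length(left)) return(0L)
  g <- igraph::make_empty_graph(n = n_left + n_right, directed = FALSE)
  g <- igraph::add_edges(g, rbind(left, n_left + right))
  types <- c(rep(FALSE, n_left), rep(TRUE, n_right))
  igraph::max_bipartite_match(g, types = types)$matching_size
}

#' Relative control centrality of every node
#'
#' c(i) = C(i) / N with N the node count of the *full* network, so values
#' are comparable across nodes and thresholds.
#'
#' @inheritParams control_centrality
#' @return Named numeric vector of fractions in (0, 1\].
#' @export
relative_control_centrality <- function(graph, include_self = TRUE) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  c_abs <- vapply(seq_len(n), function(i)
    control_centrality(g, i, include_self = include_self), integer(1))
  stats::setNames(c_abs / n, nodes)
}

#' Threshold-sweep-averaged control centrality
#'
#' A single thresholded network gives a coarse, near-binary distribution
#' of control centralities. Averaging c(i) over an ensemble of networks
#' obtained at `n_thresholds` evenly spaced weight thresholds in
#' \[`w_lo`, `w_hi`\] yields a finer ranking of the nodes' driving
#' ability. Nodes isolated by a threshold control only themselves and
#' contribute c = 1/N at that threshold.
#'
#' @param network An unthresholded [signed_network].
#' @param w_lo,w_hi Sweep bounds on the weight threshold (defaults 0.04
#'   and 0.1).
#' @param n_thresholds Number of thresholds (default 60).
#' @param include_self Passed to [control_centrality()].
#' @return List of class `control_sweep`: `averaged` (named vector of
#'   mean c(i)), `per_threshold` (matrix, nodes x thresholds),
#'   `thresholds`.
#' @export
sweep_averaged_control <- function(network, w_lo = 0.04, w_hi = 0.1,
                                   n_thresholds = 60,
                                   include_self = TRUE) {
  stopifnot(inherits(network, "signed_network"))
  if (w_lo >= w_hi) stop("w_lo must be < w_hi")
  if (n_thresholds < 1L) stop("n_thresholds must be >= 1")
  thresholds <- if (n_thresholds == 1L) w_lo else
    seq(w_lo, w_hi, length.out = n_thresholds)
  n <- length(network$nodes)
  per <- vapply(thresholds, function(ws) {
    net <- threshold_network(network, ws)
    if (n_links(net) == 0L)
      return(rep(NA_real_, n))   # emptied; flagged below
    relative_control_centrality(as_igraph(net),
                                include_self = include_self)
  }, numeric(n))
  per <- matrix(per, nrow = n,
                dimnames = list(network$nodes, NULL))
  if (all(is.na(per))) stop("every threshold empties the network")
  # thresholds emptying the whole network are dropped; isolated nodes in
  # surviving networks already got c = 1/N from the matching (C = 1)
  keep <- colSums(is.na(per)) == 0L
  list(averaged = rowMeans(per[, keep, drop = FALSE]),
       per_threshold = per[, keep, drop = FALSE],
       thresholds = thresholds[keep]) |>
    structure(class = "control_sweep")
}

#' @export
print.control_sweep <- function(x, ...) {
  if (!length(x$thresholds)) {
    cat(sprintf("control_sweep: degenerate (no usable thresholds), c = 1/N\n"))
  } else {
    cat(sprintf(
      "control_sweep: %d thresholds in [%g, %g], mean <c> = %.3f\n",
      length(x$thresholds), min(x$thresholds), max(x$thresholds),
      mean(x$averaged)))
  }
  invisible(x)
}
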