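#' m-reach of nodes in a directed graph
#'
#' The m-reach of a node is the fraction of the other N - 1 nodes that can
#' be reached from it along directed paths of length at most `m`. Nodes
#' with a large m-reach can influence most of the network within a few
#' steps and sit near the top of its hierarchy.
#'
#' @param graph A [signed_network] or igraph directed graph.
#' @param node Node name or index; if `NULL` (default for
#'   [m_reach_all()]), all nodes.
#' @param m Step horizon (>= 1).
#' @return `m_reach()`: a single fraction in \[0, 1\]. `m_reach_all()`: a
#'   named vector over all nodes.
#' @export
m_reach <- function(graph, node, m = 3) {
  g <- as_igraph(graph)
  if (is.character(node) && !node %in% igraph::V(g)$name)
    stop("node '", node, "' not in graph")
  if (m < 1L) stop("m must be >= 1")
  n <- igraph::vcount(g)
  reached <- igraph::ego_size(g, order = m, nodes = node, mode = "out")
  (reached - 1L) / (n - 1L)    # ego includes the node itself
}

#' @rdname m_reach
#' @export
m_reach_all <- function(graph, m = 3) {
  g <- as_igraph(graph)
  if (m < 1L) stop("m must be >= 1")
  n <- igraph::vcount(g)
  r <- (igraph::ego_size(g, order = m, mode = "out") - 1L) / (n - 1L)
  stats::setNames(r, igraph::V(g)$name)
}

#' Global Reaching Centrality
#'
#' \deqn{\mathrm{GRC}(m) = \frac{1}{N-1}\sum_i \big[r_{m,\max} - r_m(i)\big],}
#' the average gap between the maximal m-reach in the graph and each
#' node's m-reach. GRC is 0 when every node has the same reach (e.g. a
#' directed cycle) and 1 for the out-star, the most heterogeneous case.
#'
#' @inheritParams m_reach
#' @return GRC in \[0, 1\].
#' @export
grc <- function(graph, m = 3) {
  g <- as_igraph(graph)
  if (igraph::vcount(g) < 2L) stop("GRC needs at least 2 nodes")
  r <- m_reach_all(g, m)
  sum(max(r) - r) / (length(r) - 1L)
}

#' Degree-preserving link randomization
#'
#' Draws a sample from the configuration-model ensemble of the graph by
#' repeated double-link end swaps: two links are chosen at random and
#' their target ends exchanged. Swaps that would create a self-loop or a
#' duplicate link are rejected and retried, so every node's in- and
#' out-degree is preserved exactly and the result is always a simple
#' digraph. The number of *accepted* swaps is `swaps_per_link` times the
#' link count.
#'
#' @inheritParams m_reach
#' @param swaps_per_link Accepted swaps per link (default 10).
#' @param seed Integer seed.
#' @param max_tries Retry cap as a multiple of the requested swaps; if
#'   exceeded, the graph is too rigid to randomize and an error reports
#'   the acceptance rate.
#' @return An igraph directed graph with identical degree sequences.
#' @export
randomize_links <- function(graph, swaps_per_link = 10, seed = 1,
                            max_tries = 200) {
  g <- as_igraph(graph)
  el <- igraph::as_edgelist(g, names = FALSE)
  L <- nrow(el)
  if (L < 2L) stop("need at least 2 links to randomize")
  n <- igraph::vcount(g)
  from <- el[, 1L]
  to <- el[, 2L]
  # membership of directed pairs, indexed by (from - 1) * n + to; a flat
  # logical vector keeps the hot loop allocation-free for realistic sizes
  if (as.double(n) * n > 2^26)
    stop("randomize_links supports up to ", floor(2^13), " nodes")
  present <- logical(n * n)
  present[(from - 1L) * n + to] <- TRUE
  target_swaps <- swaps_per_link * L
  out <- with_local_seed(seed, {
    done <- 0L
    tries <- 0L
    cap <- max_tries * target_swaps
    while (done < target_swaps) {
      tries <- tries + 1L
      if (tries > cap)
        stop(structure(class = c("methylnet_rigid_graph", "error",
                                 "condition"),
                       list(message = sprintf(
          "graph too rigid to randomize: %d/%d swaps accepted (%.2g%% acceptance)",
          done, target_swaps, 100 * done / tries),
                            call = sys.call(-1))))
      e <- sample.int(L, 2L)
      a <- e[1L]; b <- e[2L]
      # swap the target ends of the two links
      na1 <- to[b]; nb1 <- to[a]
      if (from[a] == na1 || from[b] == nb1) next            # self-loop
      if (na1 == to[a]) next                                 # no-op swap
      k1 <- (from[a] - 1L) * n + na1
      k2 <- (from[b] - 1L) * n + nb1
      if (present[k1] || present[k2]) next                   # duplicate
      present[(from[a] - 1L) * n + to[a]] <- FALSE
      present[(from[b] - 1L) * n + to[b]] <- FALSE
      present[k1] <- TRUE
      present[k2] <- TRUE
      to[a] <- na1; to[b] <- nb1
      done <- done + 1L
    }
    cbind(from, to)
  })
  g2 <- igraph::make_empty_graph(n = n, directed = TRUE)
  g2 <- igraph::set_vertex_attr(g2, "name", value = igraph::V(g)$name)
  g2 <- igraph::add_edges(g2, t(out))
  stopifnot(identical(igraph::degree(g2, mode = "in"),
                      igraph::degree(g, mode = "in")),
            identical(igraph::degree(g2, mode = "out"),
                      igraph::degree(g, mode = "out")))
  g2
}

#' GRC null distribution from a link-randomized ensemble
#'
#' Compares the observed GRC(m) to the configuration-model baseline:
#' `n_samples` independent degree-preserving randomizations are drawn and
#' GRC(m) is computed on each, yielding a z-score and an upper-tail
#' empirical p-value (with the +1 correction) for the observed value.
#'
#' When the null distribution is degenerate (zero spread, e.g. an
#' out-star that no swap can alter), the z-score is reported as `NA` and
#' `degenerate = TRUE`.
#'
#' @inheritParams randomize_links
#' @param m Step horizon.
#' @param n_samples Ensemble size (>= 2; 20,000 reproduces a
#'   publication-scale ensemble, 1,000 is a desk-scale default).
#' @return List of class `grc_null` with `observed`, `null_samples`,
#'   `null_mean`, `null_sd`, `z`, `p`, `degenerate`.
#' @export
grc_null <- function(graph, m = 3, n_samples = 1000, swaps_per_link = 10,
                     seed = 1) {
  if (n_samples < 2L) stop("n_samples must be >= 2")
  g <- as_igraph(graph)
  observed <- grc(g, m)
  if (igraph::ecount(g) < 2L) {
    # fewer than two links: the degree sequence fixes the graph, so the
    # null ensemble is degenerate by construction
    samples <- rep(observed, n_samples)
    return(structure(list(
      observed = observed, null_samples = samples, null_mean = observed,
      null_sd = 0, z = NA_real_, p = 1, degenerate = TRUE, m = m),
      class = "grc_null"))
  }
  samples <- tryCatch(
    vapply(seq_len(n_samples), function(k) {
      grc(randomize_links(g, swaps_per_link = swaps_per_link,
                          seed = derive_seed(seed, k)), m)
    }, numeric(1)),
    methylnet_rigid_graph = function(e) {
      # the degree sequence admits (essentially) only the observed graph:
      # the null collapses onto it
      rep(observed, n_samples)
    })
  mu <- mean(samples)
  sdv <- stats::sd(samples)
  degenerate <- sdv == 0
  structure(list(
    observed = observed, null_samples = samples, null_mean = mu,
    null_sd = sdv,
    z = if (degenerate) NA_real_ else (observed - mu) / sdv,
    p = (sum(samples >= observed) + 1) / (n_samples + 1),
    degenerate = degenerate, m = m), class = "grc_null")
}

#' @export
print.grc_null <- function(x, ...) {
  cat(sprintf(
    "grc_null (m = %d): observed %.4f vs null %.4f +/- %.4f (%s, p = %.3g)\n",
    x$m, x$observed, x$null_mean, x$null_sd,
    if (x$degenerate) "degenerate null" else sprintf("z = %.2f", x$z),
    x$p))
  invisible(x)
}

#' GRC null comparison across several step horizons
#'
#' Draws one link-randomized ensemble and evaluates GRC(m) on every
#' sample at each requested horizon, so the null comparison across
#' m-values shares a single ensemble.
#'
#' @inheritParams grc_null
#' @param ms Integer vector of step horizons (default 2:5).
#' @return A `data.table` with one row per horizon: `m`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `p`, `degenerate`.
#' @export
grc_null_profile <- function(graph, ms = 2:5, n_samples = 1000,
                             swaps_per_link = 10, seed = 1) {
  if (n_samples < 2L) stop("n_samples must be >= 2")
  g <- as_igraph(graph)
  observed <- vapply(ms, function(m) grc(g, m), numeric(1))
  rigid <- igraph::ecount(g) < 2L
  samples <- if (rigid) {
    matrix(rep(observed, each = n_samples), n_samples, length(ms))
  } else tryCatch({
    t(vapply(seq_len(n_samples), function(k) {
      r <- randomize_links(g, swaps_per_link = swaps_per_link,
                           seed = derive_seed(seed, k))
      vapply(ms, function(m) grc(r, m), numeric(1))
    }, numeric(length(ms))))
  }, methylnet_rigid_graph = function(e) {
    matrix(rep(observed, each = n_samples), n_samples, length(ms))
  })
  mu <- colMeans(samples)
  sdv <- apply(samples, 2L, stats::sd)
  data.table::data.table(
    m = as.integer(ms), observed = observed, null_mean = mu,
    null_sd = sdv,
    z = ifelse(sdv == 0, NA_real_, (observed - mu) / sdv),
    p = (colSums(samples >= rep(observed, each = n_samples)) + 1) /
      (n_samples + 1),
    degenerate = sdv == 0)
}

#' Assign hierarchical levels from m-reach values
#'
#' Nodes are sorted by decreasing reach and grouped greedily: a node joins
#' the current level while the gap between its reach and the level's
#' maximal reach stays below one tenth of the standard deviation of all
#' reach values; otherwise a new level starts. Level 0 is the top.
#'
#' @param reach Named numeric vector of m-reach values.
#' @param gap_fraction Fraction of sd(reach) used as the within-level gap
#'   threshold (default 0.1).
#' @return Named integer vector of level indices (0 = top), in the input
#'   order.
#' @export
assign_levels <- function(reach, gap_fraction = 0.1) {
  if (!length(reach)) stop("no nodes")
  gap <- gap_fraction * stats::sd(reach)
  if (length(reach) == 1L || is.na(gap)) gap <- 0
  ord <- order(reach, decreasing = TRUE)
  lev <- integer(length(reach))
  current <- 0L
  level_top <- reach[ord[1L]]
  for (k in seq_along(ord)) {
    gap_k <- level_top - reach[ord[k]]
    # a node joins the current level while its gap to the level top stays
    # below the threshold; exactly equal reaches always share a level
    if (k > 1L && gap_k > 0 && gap_k >= gap) {
      current <- current + 1L
      level_top <- reach[ord[k]]
    }
    lev[ord[k]] <- current
  }
  stats::setNames(lev, names(reach))
}

#' Full hierarchy characterisation of a network
#'
#' Convenience wrapper returning per-node m-reach, level assignment, GRC
#' and (optionally) its null-ensemble comparison in one object.
#'
#' @inheritParams grc_null
#' @param null_samples Ensemble size for the null; 0 skips the null.
#' @return List of class `hierarchy_result` with `m`, `reach`, `levels`,
#'   `grc` and `null` (a [grc_null()] result or `NULL`).
#' @export
hierarchy_analysis <- function(graph, m = 3, null_samples = 1000,
                               swaps_per_link = 10, seed = 1) {
  g <- as_igraph(graph)
  reach <- m_reach_all(g, m)
  res <- list(m = m, reach = reach, levels = assign_levels(reach),
              grc = grc(g, m),
              null = if (null_samples > 0)
                grc_null(g, m, n_samples = null_samples,
                         swaps_per_link = swaps_per_link, seed = seed))
  class(res) <- "hierarchy_result"
  res
}

#' @export
print.hierarchy_result <- function(x, ...) {
  cat(sprintf(
    "hierarchy_result: m = %d, GRC = %.4f, %d levels over %d nodes\n",
    x$m, x$grc, max(x$levels) + 1L, length(x$reach)))
  if (!is.null(x$null)) print(x$null)
  invisible(x)
}
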