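#' Per-node cross-validated Lasso regression
#'
#' Models the methylation level of one CpG as a sparse linear combination
#' of all other CpGs,
#' \deqn{m_j = \sum_{i \ne j} \beta_{ji} m_i + \beta_0,}
#' with the L1 penalty strength chosen by k-fold cross-validation. The
#' fold assignment is drawn from `seed`, so results are reproducible and
#' invariant to sample order given fixed folds.
#'
#' Predictors are not standardised by default: beta values already share
#' the \[0,1\] scale and the link weights |beta_ji| are compared across
#' node pairs downstream, which per-predictor rescaling would distort.
#'
#' @param response CpG id of the response.
#' @param x A [methyl_matrix].
#' @param n_folds Number of CV folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param standardize Standardise predictors inside the Lasso
#'   (sensitivity-analysis flag; default `FALSE`).
#' @param lambda_choice `"lambda.min"` (CV-optimal, default) or
#'   `"lambda.1se"`.
#' @param foldid Optional explicit fold assignment overriding `seed`.
#' @return List with `coefficients` (named vector over the other CpGs,
#'   many exactly zero) and `intercept`.
#' @export
fit_node_lasso <- function(response, x, n_folds = 10, seed = 1,
                           standardize = FALSE,
                           lambda_choice = c("lambda.min", "lambda.1se"),
                           foldid = NULL) {
  lambda_choice <- match.arg(lambda_choice)
  if (!response %in% rownames(x))
    stop("response CpG '", response, "' not in matrix")
  if (n_folds < 2L) stop("need at least 2 CV folds")
  if (ncol(x) < n_folds) stop("fewer samples than CV folds")
  vals <- unclass_matrix(x)
  y <- vals[response, ]
  xm <- t(vals[setdiff(rownames(vals), response), , drop = FALSE])
  if (stats::sd(y) == 0) {
    warning("response '", response, "' is constant; returning zero model")
    return(list(coefficients = stats::setNames(numeric(ncol(xm)),
                                               colnames(xm)),
                intercept = y[1]))
  }
  if (is.null(foldid)) foldid <- cv_fold_assignment(ncol(x), n_folds, seed)
  fit <- glmnet::cv.glmnet(xm, y, alpha = 1, foldid = foldid,
                           standardize = standardize,
                           nlambda = 100, lambda.min.ratio = 1e-3)
  co <- stats::coef(fit, s = lambda_choice)
  list(coefficients = stats::setNames(as.numeric(co[-1L]), colnames(xm)),
       intercept = as.numeric(co[1L]))
}

#' Deterministic CV fold assignment
#'
#' Balanced fold labels for `n` samples drawn with `seed`; keyed to the
#' sample index, so it is unaffected by how samples are ordered elsewhere.
#'
#' @param n Number of samples.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1:n_folds`.
#' @export
cv_fold_assignment <- function(n, n_folds, seed) {
  stopifnot(n >= n_folds)
  with_local_seed(seed, sample(rep_len(seq_len(n_folds), n)))
}

#' Build the full methylation network by neighbourhood Lasso
#'
#' Runs [fit_node_lasso()] with every CpG in turn as the response and
#' assembles the signed coefficients into a directed network: link i -> j
#' is stored iff beta_ji is non-zero. The result is unthresholded; see
#' [scan_thresholds()] and [threshold_network()] for sparsification.
#'
#' The same fold assignment (derived from `seed`) is shared by all
#' per-node fits.
#'
#' @inheritParams fit_node_lasso
#' @return An unthresholded [signed_network].
#' @export
build_network <- function(x, n_folds = 10, seed = 1, standardize = FALSE,
                          lambda_choice = "lambda.min") {
  nodes <- rownames(x)
  p <- length(nodes)
  if (p < 3L) stop("need at least 3 CpGs to build a network")
  foldid <- cv_fold_assignment(ncol(x), n_folds, seed)
  rows <- vector("list", p)
  intercepts <- numeric(p)
  for (j in seq_len(p)) {
    fit <- fit_node_lasso(nodes[j], x, n_folds = n_folds, seed = seed,
                          standardize = standardize,
                          lambda_choice = lambda_choice, foldid = foldid)
    nz <- which(fit$coefficients != 0)
    rows[[j]] <- data.table::data.table(
      j = j, i = match(names(fit$coefficients)[nz], nodes),
      beta = unname(fit$coefficients[nz]))
    intercepts[j] <- fit$intercept
  }
  ed <- data.table::rbindlist(rows)
  b <- Matrix::sparseMatrix(i = ed$j, j = ed$i, x = ed$beta,
                            dims = c(p, p), dimnames = list(nodes, nodes))
  signed_network(b, intercepts = stats::setNames(intercepts, nodes))
}

#' Global efficiency of a directed graph
#'
#' \deqn{E_g = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d_{ij},}
#' where d_ij is the unweighted directed shortest-path length and
#' unreachable pairs contribute 0. Equals 1 exactly on the complete
#' digraph and 0 on the empty graph.
#'
#' @param graph A [signed_network] or igraph directed graph.
#' @return Efficiency in \[0, 1\].
#' @export
global_efficiency <- function(graph) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  if (n < 2L) stop("global efficiency needs at least 2 nodes")
  d <- igraph::distances(g, mode = "out", weights = NA)
  diag(d) <- Inf
  sum(1 / d) / (n * (n - 1))
}

#' Local efficiency of a directed graph
#'
#' Mean over nodes of the global efficiency of the subgraph induced on
#' each node's neighbours (union of in- and out-neighbours, the node
#' itself removed, directed links kept). Neighbour subgraphs with fewer
#' than 2 nodes contribute 0.
#'
#' @inheritParams global_efficiency
#' @param mode Neighbour set: `"all"` (union of in- and out-neighbours,
#'   default) or `"out"` (out-neighbours only).
#' @return Efficiency in \[0, 1\]; 0 for an empty graph.
#' @export
local_efficiency <- function(graph, mode = c("all", "out")) {
  mode <- match.arg(mode)
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  if (n == 0L) return(0)
  eff <- vapply(seq_len(n), function(i) {
    nb <- igraph::neighbors(g, i, mode = mode)
    nb <- setdiff(as.integer(nb), i)
    if (length(nb) < 2L) return(0)
    global_efficiency(igraph::induced_subgraph(g, nb))
  }, numeric(1))
  mean(eff)
}

#' Efficiency-based quality of a thresholded network
#'
#' \deqn{J = (E_g + E_l) / \rho_L,} the sum of global and local efficiency
#' over the link density rho_L = L / \[N (N-1)\]. Maximising J over the
#' weight threshold trades connectedness against sparsity.
#'
#' @inheritParams global_efficiency
#' @return The quality J.
#' @export
quality_J <- function(graph) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  if (n < 2L) stop("quality needs at least 2 nodes")
  rho <- igraph::ecount(g) / (n * (n - 1))
  if (rho == 0) stop("threshold removed all links")
  (global_efficiency(g) + local_efficiency(g)) / rho
}

#' Scan weight thresholds by the efficiency criterion
#'
#' For each candidate w*, keeps links with |beta_ji| >= w* and evaluates
#' the quality [quality_J()]; the optimum is the candidate maximising J.
#' Candidates that empty the graph are kept in the table (with `NA`
#' quality) but excluded from the argmax. Ties are broken toward the
#' smaller threshold (denser network).
#'
#' @param network An unthresholded [signed_network].
#' @param grid Ascending numeric vector of candidate thresholds; by
#'   default `grid_points` values evenly spaced between the smallest and
#'   largest observed link weight.
#' @param grid_points Number of default grid points (default 200).
#' @return List of class `threshold_scan` with elements `scan` (a
#'   `data.table` of w_star, E_g, E_l, rho_L, J), `w_star` (the argmax)
#'   and `J_max`.
#' @export
scan_thresholds <- function(network, grid = NULL, grid_points = 200) {
  stopifnot(inherits(network, "signed_network"))
  w <- abs(network$beta@x)
  if (!length(w)) stop("network has no links to threshold")
  if (is.null(grid)) grid <- seq(min(w), max(w), length.out = grid_points)
  if (is.unsorted(grid)) stop("`grid` must be sorted ascending")
  n <- length(network$nodes)
  res <- lapply(grid, function(ws) {
    g <- as_igraph(threshold_network(network, ws))
    L <- igraph::ecount(g)
    if (L == 0L)
      return(data.table::data.table(w_star = ws, E_g = NA_real_,
                                    E_l = NA_real_, rho_L = 0,
                                    J = NA_real_))
    eg <- global_efficiency(g)
    el <- local_efficiency(g)
    rho <- L / (n * (n - 1))
    data.table::data.table(w_star = ws, E_g = eg, E_l = el,
                           rho_L = rho, J = (eg + el) / rho)
  })
  scan <- data.table::rbindlist(res)
  ok <- which(!is.na(scan$J))
  if (!length(ok)) stop("every candidate threshold empties the graph")
  best <- ok[which.max(scan$J[ok])]   # which.max takes the first maximum
  structure(list(scan = scan, w_star = scan$w_star[best],
                 J_max = scan$J[best]),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("threshold_scan: %d candidates, optimum w* = %g (J = %.4g)\n",
              nrow(x$scan), x$w_star, x$J_max))
  invisible(x)
}
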