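#' Directed signed coefficient network
#'
#' Stores the per-node regression model of a methylation network: for each
#' response CpG j, a sparse row of signed coefficients beta_ji over
#' predictor CpGs i, plus the intercepts. A directed link i -> j exists
#' where beta_ji is non-zero; its weight is w_ij = |beta_ji|.
#'
#' @param beta Square sparse (or dense) matrix with `beta[j, i]` the
#'   coefficient of predictor i in the model for response j; zero diagonal.
#'   Dimnames give the node (CpG) ids.
#' @param intercepts Numeric vector of per-response intercepts (optional).
#' @param threshold Weight threshold already applied to `beta`, or `NULL`
#'   for an unthresholded network.
#' @return An object of class `signed_network`.
#' @export
signed_network <- function(beta, intercepts = NULL, threshold = NULL) {
  beta <- methods::as(methods::as(Matrix::Matrix(beta, sparse = TRUE),
                                  "generalMatrix"), "CsparseMatrix")
  if (nrow(beta) != ncol(beta)) stop("`beta` must be square")
  if (is.null(rownames(beta)) || !identical(rownames(beta), colnames(beta)))
    stop("`beta` must have identical row and column names (node ids)")
  if (any(Matrix::diag(beta) != 0)) stop("self-links are not allowed")
  beta <- Matrix::drop0(beta)
  if (!is.null(threshold)) {
    w <- abs(beta@x)
    if (length(w) && min(w) < threshold)
      stop("stored link weights below the declared threshold")
  }
  if (is.null(intercepts)) intercepts <- stats::setNames(
    rep(0, nrow(beta)), rownames(beta))
  structure(list(nodes = rownames(beta), beta = beta,
                 intercepts = intercepts, threshold = threshold),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf(
    "signed_network: %d nodes, %d links%s, mean total degree %.2f\n",
    length(x$nodes), n_links(x),
    if (is.null(x$threshold)) " (unthresholded)"
    else sprintf(" (threshold w* = %g)", x$threshold),
    mean_degree(x)))
  invisible(x)
}

#' @rdname signed_network
#' @param x A `signed_network`.
#' @export
n_links <- function(x) length(x$beta@x)

#' Mean total degree (in + out) of a signed network
#' @param x A [signed_network].
#' @export
mean_degree <- function(x) 2 * n_links(x) / length(x$nodes)

#' Edge table of a signed network
#'
#' @param x A [signed_network].
#' @return A `data.table` with columns `source` (predictor i), `target`
#'   (response j), `beta` (signed coefficient beta_ji) and `weight`
#'   (|beta_ji|), ordered by target then source.
#' @export
network_edges <- function(x) {
  tm <- methods::as(x$beta, "TsparseMatrix")
  dt <- data.table::data.table(
    source = x$nodes[tm@j + 1L],   # predictor index = column
    target = x$nodes[tm@i + 1L],   # response index = row
    beta = tm@x,
    weight = abs(tm@x))
  data.table::setorder(dt, target, source)[]
}

#' Convert a network to an igraph object
#'
#' Directed graph on all nodes (isolated nodes kept), one edge per
#' non-zero coefficient, with `beta` and `weight` edge attributes.
#'
#' @param x A [signed_network] or an igraph graph (returned unchanged).
#' @return An `igraph` directed graph.
#' @export
as_igraph <- function(x) {
  if (igraph::is_igraph(x)) return(x)
  stopifnot(inherits(x, "signed_network"))
  ed <- network_edges(x)
  g <- igraph::make_empty_graph(n = length(x$nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = x$nodes)
  if (nrow(ed))
    g <- igraph::add_edges(g, rbind(ed$source, ed$target),
                           beta = ed$beta, weight = ed$weight)
  g
}

#' Apply a weight threshold to a network
#'
#' Keeps links with `|beta_ji| >= w_star` (signs retained) and records the
#' threshold on the result.
#'
#' @param x A [signed_network].
#' @param w_star Weight threshold.
#' @return A thresholded [signed_network].
#' @export
threshold_network <- function(x, w_star) {
  b <- x$beta
  b@x[abs(b@x) < w_star] <- 0
  signed_network(Matrix::drop0(b), intercepts = x$intercepts,
                 threshold = w_star)
}

#' Write / read a network edge list
#'
#' TSV with columns `source`, `target`, `beta`, `weight`; a JSON sidecar
#' (same path with extension `.json`) records the node set and threshold so
#' isolated nodes round-trip.
#'
#' @param x A [signed_network].
#' @param path Output TSV path.
#' @return `path` (write) or a [signed_network] (read).
#' @export
write_network <- function(x, path) {
  ed <- network_edges(x)
  ed$beta <- format_full(ed$beta)
  ed$weight <- format_full(ed$weight)
  data.table::fwrite(ed, path, sep = "\t", quote = FALSE)
  jsonlite::write_json(
    list(nodes = x$nodes, threshold = x$threshold,
         intercepts = as.list(x$intercepts)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_network
#' @param nodes Node ids; when `NULL`, taken from the JSON sidecar if
#'   present, else from the ids appearing in the edge list.
#' @export
read_network <- function(path, nodes = NULL) {
  ed <- data.table::fread(path, header = TRUE)
  threshold <- NULL
  intercepts <- NULL
  sidecar <- paste0(path, ".json")
  if (is.null(nodes) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    nodes <- meta$nodes
    threshold <- meta$threshold
    if (!is.null(meta$intercepts))
      intercepts <- unlist(meta$intercepts)
  }
  if (is.null(nodes)) nodes <- sort(unique(c(ed$source, ed$target)))
  n <- length(nodes)
  b <- Matrix::sparseMatrix(
    i = match(ed$target, nodes), j = match(ed$source, nodes),
    x = ed$beta, dims = c(n, n), dimnames = list(nodes, nodes))
  signed_network(b, intercepts = intercepts, threshold = threshold)
}
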