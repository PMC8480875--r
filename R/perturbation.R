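#' Effective propagation coefficients from a perturbed node
#'
#' When the methylation level of CpG i is perturbed, the change propagates
#' along chains of network links: node j receives, through every walk of
#' length at most `l_max` from i to j, the product of the signed
#' coefficients along the walk. The effective coefficient is the walk sum
#' \deqn{\beta^{\mathrm{eff}}_{ji} = \sum_{\ell = 1}^{\ell_{\max}}
#'   (B^\ell)_{ji},}
#' with B the signed coefficient matrix of the (thresholded) network.
#' Walks may revisit nodes (the nested sums carry no distinctness
#' constraint); a simple-path variant, which counts each node at most
#' once per path, is available for sensitivity analysis with
#' `paths = "simple"`. The sum is accumulated by repeated sparse
#' matrix-vector products, never dense matrix powers.
#'
#' @param network A thresholded [signed_network] (signed coefficients on
#'   the surviving links).
#' @param node Perturbed CpG id.
#' @param l_max Maximal chain length (>= 1; for the unpropagated case use
#'   [age_derivative()] with `l_max = 0`).
#' @param paths `"walks"` (default, unrestricted walk sums) or
#'   `"simple"` (simple paths only).
#' @return Named numeric vector of effective coefficients over all nodes
#'   (zero at unaffected nodes and at i itself).
#' @export
effective_beta <- function(network, node, l_max = 4,
                           paths = c("walks", "simple")) {
  paths <- match.arg(paths)
  stopifnot(inherits(network, "signed_network"))
  if (l_max < 1L) stop("l_max must be >= 1; l_max = 0 has no propagation")
  i <- match(node, network$nodes)
  if (is.na(i)) stop("node '", node, "' not in network")
  p <- length(network$nodes)
  if (paths == "walks") {
    b <- network$beta
    v <- numeric(p); v[i] <- 1
    acc <- numeric(p)
    for (l in seq_len(l_max)) {
      v <- as.numeric(b %*% v)
      acc <- acc + v
      if (all(v == 0)) break
    }
  } else {
    acc <- simple_path_beta(as.matrix(network$beta), i, l_max)
  }
  # the diagonal term (walks returning to i itself) is kept: the nested
  # sums are unrestricted, so cycles through i feed back into its own
  # coordinate
  stats::setNames(acc, network$nodes)
}

# Sum of coefficient products over simple paths (no node revisited) from
# node i, up to length l_max; depth-first enumeration.
simple_path_beta <- function(bmat, i, l_max) {
  p <- nrow(bmat)
  acc <- numeric(p)
  recurse <- function(at, prod, depth, visited) {
    if (depth == l_max) return()
    nxt <- which(bmat[, at] != 0)
    for (j in nxt) {
      if (visited[j]) next
      w <- prod * bmat[j, at]
      acc[j] <<- acc[j] + w
      visited[j] <- TRUE
      recurse(j, w, depth + 1L, visited)
      visited[j] <- FALSE
    }
  }
  visited <- logical(p)
  visited[i] <- TRUE
  recurse(i, 1, 0L, visited)
  acc
}

#' Sensitivity of clock-estimated age to one methylation level
#'
#' Derivative of the estimated age with respect to the methylation level
#' of CpG i, in the linear (adult) branch of the clock, with the
#' perturbation propagated over the network up to chains of length
#' `l_max`:
#' \deqn{\frac{da}{dm_i} = (a_t + 1)\Big[H_i + \sum_j H_j\,
#'   \beta^{\mathrm{eff}}_{ji}\Big].}
#' At `l_max = 0` this reduces to the isolated-CpG sensitivity
#' \eqn{(a_t + 1) H_i}.
#'
#' @inheritParams effective_beta
#' @param clock A [clock_model] covering every network node.
#' @return Derivative in years per unit methylation.
#' @export
age_derivative <- function(network, clock, node, l_max = 4,
                           paths = "walks") {
  h <- clock$coefficients
  absent <- setdiff(network$nodes, names(h))
  if (length(absent))
    stop("clock missing network nodes: ", paste(absent, collapse = ", "))
  if (!node %in% network$nodes) stop("node '", node, "' not in network")
  hi <- h[[node]]
  at <- clock$adult_threshold
  if (l_max == 0L) return((at + 1) * hi)
  eff <- effective_beta(network, node, l_max = l_max, paths = paths)
  (at + 1) * (hi + sum(h[network$nodes] * eff))
}

#' Predicted age change from perturbing one CpG
#'
#' Applies a methylation perturbation of size `delta_m` (by default twice
#' the cohort's mean per-CpG standard deviation, see [mean_cpg_std()]) at
#' one CpG, propagates it over the network, and reports the induced
#' change in clock-estimated age, \eqn{\Delta a = (da/dm_i)\,\Delta m_i}.
#' The magnitude |Delta a| is the attainable virtual age shift; applying
#' the perturbation with the opposite sign gives a reduction of the same
#' size.
#'
#' @inheritParams age_derivative
#' @param x A [methyl_matrix] supplying the cohort spread (ignored when
#'   `delta_m` is given).
#' @param delta_m Perturbation size; default `2 * mean_cpg_std(x)`.
#' @return List of class `perturbation_result`: `node`, `l_max`,
#'   `derivative` (years per unit methylation), `delta_m`, `delta_a`
#'   (signed, for a +delta_m perturbation), `delta_a_abs`,
#'   `effective_beta`.
#' @export
delta_a <- function(network, clock, x = NULL, node, l_max = 4,
                    delta_m = NULL, paths = "walks") {
  if (is.null(delta_m)) {
    if (is.null(x)) stop("supply either `x` or `delta_m`")
    delta_m <- 2 * mean_cpg_std(x)
  }
  deriv <- age_derivative(network, clock, node, l_max = l_max,
                          paths = paths)
  eff <- if (l_max >= 1L)
    effective_beta(network, node, l_max = l_max, paths = paths)
  else stats::setNames(numeric(length(network$nodes)), network$nodes)
  structure(list(node = node, l_max = l_max, derivative = deriv,
                 delta_m = delta_m, delta_a = deriv * delta_m,
                 delta_a_abs = abs(deriv * delta_m),
                 effective_beta = eff),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf(
    "perturbation of %s (l_max = %d): da/dm = %.3f yr, delta_m = %.4f, |delta_a| = %.3f yr\n",
    x$node, x$l_max, x$derivative, x$delta_m, x$delta_a_abs))
  invisible(x)
}

#' Project the sample cloud onto the clock direction
#'
#' Each sample is a point in methylation space (one axis per CpG). This
#' decomposes every sample vector m(q) into its component along the clock
#' coefficient vector H (which, in the linear branch, determines the
#' estimated age via \eqn{a = (a_t+1)|H| \cdot \mathrm{along} + a_t}) and
#' the distance d(q) of its perpendicular part from the centre of mass of
#' all perpendicular parts.
#'
#' @param x A [methyl_matrix]; rows must cover the clock CpGs.
#' @param clock A [clock_model] with a non-zero coefficient vector.
#' @return List of class `projection_result`: `along` (named vector,
#'   m(q).H/|H|), `perp_distance` (named vector d(q) >= 0), `h_norm`.
#' @export
project_cloud <- function(x, clock) {
  h <- clock$coefficients
  hn <- sqrt(sum(h^2))
  if (hn == 0) stop("clock vector is zero")
  m <- unclass_matrix(x)[names(h), , drop = FALSE]
  along <- drop(crossprod(m, h)) / hn
  perp <- m - outer(h / hn, along)        # perpendicular components
  centre <- rowMeans(perp)
  d <- sqrt(colSums((perp - centre)^2))
  structure(list(along = stats::setNames(along, colnames(m)),
                 perp_distance = stats::setNames(d, colnames(m)),
                 h_norm = hn),
            class = "projection_result")
}

#' Geometry of a perturbation displacement in methylation space
#'
#' The displacement induced by perturbing CpG i is the vector with
#' `delta_m` at coordinate i plus the propagated change
#' \eqn{\beta^{\mathrm{eff}}_{ji}\,\Delta m_i} at every other coordinate
#' (at `l_max = 0`, only coordinate i moves). Its angle with the clock
#' vector H measures how well the induced change aligns with the natural
#' direction of ageing.
#'
#' @inheritParams delta_a
#' @return List of class `displacement_geometry`: `displacement` (named
#'   vector), `length`, `angle` (radians with H; `NA` and
#'   `zero_displacement = TRUE` if the displacement vanishes).
#' @export
displacement_geometry <- function(network, clock, x = NULL, node,
                                  l_max = 4, delta_m = NULL,
                                  paths = "walks") {
  if (is.null(delta_m)) {
    if (is.null(x)) stop("supply either `x` or `delta_m`")
    delta_m <- 2 * mean_cpg_std(x)
  }
  nodes <- network$nodes
  disp <- stats::setNames(numeric(length(nodes)), nodes)
  disp[node] <- delta_m
  if (l_max >= 1L)
    disp <- disp + effective_beta(network, node, l_max = l_max,
                                  paths = paths) * delta_m
  len <- sqrt(sum(disp^2))
  h <- clock$coefficients[nodes]
  if (any(is.na(h))) stop("clock missing network nodes")
  hn <- sqrt(sum(h^2))
  zero <- len == 0 || hn == 0
  ang <- if (zero) NA_real_ else
    acos(max(-1, min(1, sum(disp * h) / (len * hn))))
  structure(list(displacement = disp, length = len, angle = ang,
                 zero_displacement = len == 0),
            class = "displacement_geometry")
}

#' Per-node perturbation summary over a whole network
#'
#' Runs [delta_a()] and [displacement_geometry()] for every node and
#' tabulates the results, including the angle with H at `l_max = 0`
#' (isolated perturbation) for comparison.
#'
#' @inheritParams delta_a
#' @return A `data.table` with columns `cpg_id`, `derivative`, `delta_a`,
#'   `delta_a_abs`, `angle_l0`, `angle_lmax`.
#' @export
perturb_all <- function(network, clock, x = NULL, l_max = 4,
                        delta_m = NULL, paths = "walks") {
  if (is.null(delta_m)) {
    if (is.null(x)) stop("supply either `x` or `delta_m`")
    delta_m <- 2 * mean_cpg_std(x)
  }
  rows <- lapply(network$nodes, function(nd) {
    pa <- delta_a(network, clock, node = nd, l_max = l_max,
                  delta_m = delta_m, paths = paths)
    g0 <- displacement_geometry(network, clock, node = nd, l_max = 0,
                                delta_m = delta_m)
    gl <- displacement_geometry(network, clock, node = nd, l_max = l_max,
                                delta_m = delta_m, paths = paths)
    data.table::data.table(cpg_id = nd, derivative = pa$derivative,
                           delta_a = pa$delta_a,
                           delta_a_abs = pa$delta_a_abs,
                           angle_l0 = g0$angle, angle_lmax = gl$angle)
  })
  data.table::rbindlist(rows)
}
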