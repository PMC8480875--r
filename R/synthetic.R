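#' Generate a synthetic methylation cohort with a planted network
#'
#' Simulates a cohort with the statistical structure the downstream
#' analysis assumes: a sparse directed acyclic coefficient network among
#' CpGs (the planted truth that neighbourhood Lasso regression should
#' recover), age-dependent mean shifts, and Gaussian noise. Methylation
#' levels are produced by solving the linear structural model
#' \deqn{m_k = \mu_k + s_k\,\mathrm{age} + \sum_i B_{ki} m_i + \varepsilon_k}
#' in topological order, then each CpG is affinely rescaled into
#' \[0.05, 0.95\] so levels are valid beta values while the model stays
#' exactly linear. The planted network reported in the result is the
#' coefficient matrix re-expressed in the rescaled coordinates, i.e. the
#' truth an inference run on the returned matrix should find.
#'
#' A synthetic clock tracking the simulated ages is fitted with
#' [fit_synthetic_clock()] and returned alongside.
#'
#' @param n_cpgs Number of CpGs (>= 3).
#' @param n_samples Number of samples (>= 10).
#' @param edge_density Fraction of ordered node pairs carrying a link
#'   (0 <= density < 0.5; the DAG constraint caps attainable density).
#' @param coefficient_scale Typical magnitude of a planted coefficient;
#'   entries are drawn uniformly in ±\[0.5, 1.5\] x this scale.
#' @param noise_sd Standard deviation of the per-CpG Gaussian noise.
#' @param age_range Two-element vector (years); ages are uniform in it.
#' @param seed Integer seed; regeneration with identical parameters and
#'   seed is bit-identical.
#' @param age_slope_range Magnitude range of the per-CpG age slope
#'   (methylation units per year; sign random).
#' @param adult_threshold Adult threshold passed to the clock fit.
#' @return An object of class `synthetic_cohort`: list with `matrix`
#'   (a [methyl_matrix] with ages), `true_network` (a [signed_network]),
#'   `clock` (a [clock_model]), `clock_rmse` (years) and
#'   `generator_params`.
#' @export
generate_cohort <- function(n_cpgs = 30, n_samples = 600,
                            edge_density = 0.05, coefficient_scale = 1,
                            noise_sd = 0.02, age_range = c(21, 101),
                            seed = 1,
                            age_slope_range = c(0.0005, 0.002),
                            adult_threshold = 20) {
  if (n_cpgs < 3L) stop("n_cpgs must be >= 3")
  if (n_samples < 10L) stop("n_samples must be >= 10")
  if (edge_density < 0 || edge_density >= 0.5)
    stop("edge_density must be in [0, 0.5) for an acyclic truth")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    stop("age_range must be (lo, hi) with lo < hi")

  params <- list(n_cpgs = n_cpgs, n_samples = n_samples,
                 edge_density = edge_density,
                 coefficient_scale = coefficient_scale,
                 noise_sd = noise_sd, age_range = age_range, seed = seed,
                 age_slope_range = age_slope_range,
                 adult_threshold = adult_threshold)
  cpgs <- sprintf("cg%03d", seq_len(n_cpgs))
  samples <- sprintf("s%04d", seq_len(n_samples))

  sim <- with_local_seed(seed, {
    ages <- stats::runif(n_samples, age_range[1], age_range[2])
    # DAG in the order cg001 < cg002 < ...: links only from earlier to
    # later CpGs. Each of the n(n-1)/2 admissible pairs is kept with
    # probability 2 * edge_density so the expected link count equals
    # edge_density * n * (n - 1).
    B <- matrix(0, n_cpgs, n_cpgs, dimnames = list(cpgs, cpgs))
    for (k in seq_len(n_cpgs)) {
      if (k == 1L) next
      pick <- stats::runif(k - 1L) < 2 * edge_density
      if (any(pick)) {
        mag <- stats::runif(sum(pick), 0.5, 1.5) * coefficient_scale
        B[k, which(pick)] <- mag * sample(c(-1, 1), sum(pick),
                                          replace = TRUE)
      }
    }
    mu <- stats::runif(n_cpgs, 0.2, 0.8)
    slope <- stats::runif(n_cpgs, age_slope_range[1], age_slope_range[2]) *
      sample(c(-1, 1), n_cpgs, replace = TRUE)
    eps <- matrix(stats::rnorm(n_cpgs * n_samples, sd = noise_sd),
                  n_cpgs, n_samples)
    m <- matrix(0, n_cpgs, n_samples, dimnames = list(cpgs, samples))
    for (k in seq_len(n_cpgs))   # topological order = row order
      m[k, ] <- mu[k] + slope[k] * ages +
        drop(B[k, , drop = FALSE] %*% m) + eps[k, ]
    list(ages = ages, B = B, m = m)
  })

  # Affine rescale each CpG into [0.05, 0.95]; in the new coordinates
  # m'_k = a_k + b_k m_k, so the effective coefficient matrix is
  # B'_{ki} = b_k B_{ki} / b_i.
  lo <- apply(sim$m, 1L, min)
  hi <- apply(sim$m, 1L, max)
  if (any(hi - lo < .Machine$double.eps))
    stop("degenerate CpG with zero range; increase noise_sd")
  b <- 0.9 / (hi - lo)
  m_scaled <- 0.05 + (sim$m - lo) * b
  B_eff <- sim$B * outer(b, 1 / b)

  mat <- methyl_matrix(m_scaled, ages = sim$ages)
  net <- signed_network(B_eff)
  clock <- NULL
  clock_rmse <- NA_real_
  if (age_range[1] > adult_threshold) {
    fit <- fit_synthetic_clock(mat, adult_threshold = adult_threshold)
    clock <- fit$clock
    clock_rmse <- fit$rmse
  }
  structure(list(matrix = mat, true_network = net, clock = clock,
                 clock_rmse = clock_rmse, generator_params = params),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d CpGs x %d samples, %d planted links, clock RMSE %.3g yr\n",
    nrow(x$matrix), ncol(x$matrix), n_links(x$true_network), x$clock_rmse))
  invisible(x)
}

#' Fit a synthetic linear clock to a cohort with known ages
#'
#' Finds coefficients H minimising
#' \deqn{\sum_q \big[(a_t + 1) H \cdot m(q) + a_t - \mathrm{age}(q)\big]^2}
#' (plus a tiny ridge term for conditioning), i.e. a clock whose linear
#' adult branch tracks the simulated chronological ages. All ages must lie
#' above the adult threshold so the linear branch applies throughout.
#'
#' @param x A [methyl_matrix] with ages.
#' @param adult_threshold Adult threshold a_t in years (default 20).
#' @param ridge Optional ridge penalty on the singular values (default 0;
#'   conditioning is handled by truncating negligible singular values in
#'   the minimum-norm least-squares solve).
#' @return List with `clock` (a [clock_model]), `rmse` (root-mean-square
#'   error of the clock ages against the true ages, years) and
#'   `fitted_ages`.
#' @export
fit_synthetic_clock <- function(x, adult_threshold = 20, ridge = 0) {
  ages <- sample_ages(x)
  if (is.null(ages)) stop("matrix has no ages")
  if (any(ages <= adult_threshold))
    stop("all ages must exceed the adult threshold (linear branch)")
  m <- unclass_matrix(x)
  if (all(apply(m, 1L, stats::sd) == 0))
    warning("constant methylation matrix: design is rank-deficient, ",
            "the clock cannot track age")
  y <- (ages - adult_threshold) / (adult_threshold + 1)
  # minimum-norm least squares for y ~ t(m) h via SVD; singular values
  # below a relative machine tolerance are truncated so rank-deficient
  # designs (e.g. noiseless cohorts) stay well conditioned
  sv <- svd(t(m))
  keep <- sv$d > max(sv$d) * max(dim(m)) * .Machine$double.eps
  filt <- ifelse(keep, sv$d / (sv$d^2 + ridge), 0)
  h <- drop(sv$v %*% (filt * crossprod(sv$u, y)))
  names(h) <- rownames(m)
  if (all(h == 0)) h[1] <- .Machine$double.eps  # degenerate, keep valid
  clock <- clock_model(h, adult_threshold = adult_threshold)
  fitted <- horvath_age_matrix(x, clock)
  list(clock = clock, rmse = sqrt(mean((fitted - ages)^2)),
       fitted_ages = fitted)
}

#' Identifiable support of a planted directed network
#'
#' Per-node linear regression of each CpG on all others identifies
#' conditional dependencies, not causal arrows: for a directed acyclic
#' generative model the recoverable structure is the *moral graph* —
#' the undirected skeleton of the planted links plus couplings between
#' co-parents of a shared target. This returns that identifiable support
#' as a set of unordered node pairs; `moral = FALSE` gives the bare
#' skeleton.
#'
#' @param network A [signed_network] (typically a planted truth).
#' @param moral Include co-parent (spouse) pairs (default `TRUE`).
#' @return Character vector of unordered pairs `"id1|id2"` with
#'   `id1 < id2`.
#' @export
planted_support <- function(network, moral = TRUE) {
  b <- as.matrix(network$beta) != 0
  nm <- rownames(b)
  prs <- character(0)
  for (j in seq_len(nrow(b))) {
    pa <- which(b[j, ])
    for (i in pa)
      prs <- c(prs, paste(nm[min(i, j)], nm[max(i, j)], sep = "|"))
    if (moral && length(pa) > 1L) {
      cp <- utils::combn(sort(pa), 2L)
      prs <- c(prs, paste(nm[cp[1L, ]], nm[cp[2L, ]], sep = "|"))
    }
  }
  unique(prs)
}

#' Support-recovery precision and recall of an inferred network
#'
#' Compares the undirected support of an inferred network (links with
#' weight at or above `weight_floor`, as unordered pairs) against the
#' identifiable support of the planted truth ([planted_support()]).
#' The floor screens out the small-magnitude coefficients that
#' cross-validated Lasso retains around the true structure.
#'
#' @param truth Planted [signed_network].
#' @param inferred Inferred [signed_network].
#' @param weight_floor Minimum |beta| for an inferred link to count
#'   (default 0.15).
#' @param moral Evaluate against the moral graph (default) or the bare
#'   skeleton.
#' @return List with `precision`, `recall`, `n_true`, `n_inferred`.
#' @export
support_recovery <- function(truth, inferred, weight_floor = 0.15,
                             moral = TRUE) {
  true_pairs <- planted_support(truth, moral = moral)
  ed <- network_edges(inferred)
  ed <- ed[ed$weight >= weight_floor, ]
  inf_pairs <- unique(paste(pmin(ed$source, ed$target),
                            pmax(ed$source, ed$target), sep = "|"))
  tp <- length(intersect(true_pairs, inf_pairs))
  list(precision = if (length(inf_pairs)) tp / length(inf_pairs) else NA,
       recall = if (length(true_pairs)) tp / length(true_pairs) else NA,
       n_true = length(true_pairs), n_inferred = length(inf_pairs))
}

#' Write a synthetic cohort to an output directory
#'
#' Produces the plain-text artefacts a real-data run would start from:
#' `betas.tsv`, `metadata.tsv`, `clock.csv`, `true_network.tsv` (edge
#' list) and `generator_params.json`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(cohort$matrix, file.path(dir, "betas.tsv"),
                    metadata = file.path(dir, "metadata.tsv"))
  if (!is.null(cohort$clock))
    write_clock(cohort$clock, file.path(dir, "clock.csv"))
  write_network(cohort$true_network, file.path(dir, "true_network.tsv"))
  jsonlite::write_json(cohort$generator_params,
                       file.path(dir, "generator_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
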