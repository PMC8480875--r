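#' Run the full methylation-network analysis pipeline
#'
#' Orchestrates every stage on one input cohort: per-node Lasso network
#' inference, efficiency-based weight thresholding, hierarchy analysis
#' with a degree-preserving null ensemble, control-centrality analysis
#' with a threshold sweep, perturbation propagation, and the top-k
#' ranking table. All stage outputs are written to `out_dir` as TSV/JSON
#' together with a manifest recording every parameter and seed, so a run
#' is reproducible from the manifest alone.
#'
#' @param x A [methyl_matrix], or `NULL` when `synthetic` is given.
#' @param clock A [clock_model]; defaults to the synthetic cohort's clock
#'   when `synthetic` is used.
#' @param synthetic Optional list of [generate_cohort()] arguments; used
#'   instead of `x`/`clock` (exactly one input mode must be supplied).
#' @param out_dir Output directory; `NULL` skips file output.
#' @param n_folds CV folds for the Lasso fits.
#' @param seed Integer seed governing every random stage.
#' @param m Step horizon for m-reach.
#' @param null_samples Null-ensemble size for the GRC comparison (0 to
#'   skip).
#' @param threshold `"auto"` (efficiency-based scan) or a numeric w*.
#' @param grid_points Grid size for the threshold scan.
#' @param sweep_lo,sweep_hi,sweep_n Control-centrality threshold sweep
#'   (defaults 0.04, 0.1, 60).
#' @param l_max Maximal propagation chain length.
#' @param top_k Size of the ranking lists.
#' @return List of class `methylnet_run`: `network`, `scan`,
#'   `thresholded`, `hierarchy`, `control_single`, `control_sweep`,
#'   `perturbation`, `ranking`, `summary`, `manifest`.
#' @export
run_full <- function(x = NULL, clock = NULL, synthetic = NULL,
                     out_dir = NULL, n_folds = 10, seed = 1, m = 3,
                     null_samples = 1000, threshold = "auto",
                     grid_points = 200, sweep_lo = 0.04, sweep_hi = 0.1,
                     sweep_n = 60, l_max = 4, top_k = 20) {
  if (is.null(x) == is.null(synthetic))
    stop("supply exactly one of `x` or `synthetic`")
  if (!is.null(synthetic)) {
    cohort <- do.call(generate_cohort, synthetic)
    x <- cohort$matrix
    if (is.null(clock)) clock <- cohort$clock
  }
  if (is.null(clock)) stop("no clock supplied")
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(name, writer) if (!is.null(out_dir)) writer(
    file.path(out_dir, name))

  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))

  network <- stage("infer", build_network(x, n_folds = n_folds,
                                          seed = seed))
  emit("network_full.tsv", function(p) write_network(network, p))

  scan <- NULL
  w_star <- threshold
  if (identical(threshold, "auto")) {
    if (n_links(network) == 0L) {
      w_star <- 0           # nothing to sparsify in an empty network
    } else {
      scan <- stage("threshold",
                    scan_thresholds(network, grid_points = grid_points))
      w_star <- scan$w_star
      emit("threshold_scan.tsv", function(p)
        data.table::fwrite(scan$scan, p, sep = "\t"))
    }
  }
  thresholded <- stage("threshold", threshold_network(network, w_star))
  emit("network_thresholded.tsv", function(p)
    write_network(thresholded, p))

  hier <- stage("hierarchy",
                hierarchy_analysis(thresholded, m = m, null_samples = 0))
  grc_profile <- NULL
  if (null_samples > 0) {
    grc_profile <- stage("hierarchy", grc_null_profile(
      thresholded, ms = sort(unique(c(2:5, m))),
      n_samples = null_samples, seed = derive_seed(seed, 1)))
    emit("grc_null_profile.tsv", function(p)
      data.table::fwrite(grc_profile, p, sep = "\t"))
  }
  emit("hierarchy.tsv", function(p) data.table::fwrite(
    data.table::data.table(cpg_id = names(hier$reach),
                           reach = hier$reach,
                           level = hier$levels[names(hier$reach)]),
    p, sep = "\t"))

  control_single <- stage("control",
                          relative_control_centrality(thresholded))
  csweep <- stage("control", tryCatch(
    sweep_averaged_control(network, w_lo = sweep_lo, w_hi = sweep_hi,
                           n_thresholds = sweep_n),
    error = function(e) {
      if (!grepl("empties", conditionMessage(e))) stop(e)
      # degenerate network: every node controls only itself
      n <- length(network$nodes)
      structure(list(averaged = stats::setNames(rep(1 / n, n),
                                                network$nodes),
                     per_threshold = NULL, thresholds = numeric(0)),
                class = "control_sweep")
    }))
  emit("control.tsv", function(p) data.table::fwrite(
    data.table::data.table(cpg_id = names(control_single),
                           c_single = control_single,
                           c_avg = csweep$averaged[names(control_single)]),
    p, sep = "\t"))

  pert <- stage("perturbation",
                perturb_all(thresholded, clock, x, l_max = l_max))
  emit("perturbation.tsv", function(p)
    data.table::fwrite(pert, p, sep = "\t"))

  ranking <- stage("ranking", ranking_table(
    delta_a_abs = stats::setNames(pert$delta_a_abs, pert$cpg_id),
    reach = hier$reach, c_avg = csweep$averaged, k = top_k))
  emit("ranking.tsv", function(p)
    data.table::fwrite(ranking$table, p, sep = "\t"))

  nodes <- names(hier$reach)
  summary <- list(
    n_cpgs = nrow(x), n_samples = ncol(x),
    mean_degree_prethreshold = mean_degree(network),
    w_star = w_star,
    n_links_thresholded = n_links(thresholded),
    grc = hier$grc,
    grc_null_z = if (!is.null(grc_profile))
      grc_profile$z[grc_profile$m == m] else NA_real_,
    grc_null_p = if (!is.null(grc_profile))
      grc_profile$p[grc_profile$m == m] else NA_real_,
    mean_abs_delta_a = mean(pert$delta_a_abs),
    max_abs_delta_a = max(pert$delta_a_abs),
    pearson_reach_c_single =
      safe_cor(hier$reach, control_single[nodes]),
    pearson_reach_c_avg =
      safe_cor(hier$reach, csweep$averaged[nodes]),
    overlap_reach_c_avg = ranking$overlaps["reach", "c_avg"],
    angle_improved_fraction =
      mean(pert$angle_lmax < pert$angle_l0, na.rm = TRUE))
  emit("summary.json", function(p)
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA))

  manifest <- list(
    package_version = as.character(utils::packageVersion("methylnet")),
    n_folds = n_folds, seed = seed, m = m,
    null_samples = null_samples, threshold = threshold,
    grid_points = grid_points,
    sweep = c(sweep_lo, sweep_hi, sweep_n), l_max = l_max,
    top_k = top_k, synthetic = synthetic)
  emit("manifest.json", function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         null = "null"))

  structure(list(network = network, scan = scan,
                 thresholded = thresholded, hierarchy = hier,
                 grc_profile = grc_profile,
                 control_single = control_single, control_sweep = csweep,
                 perturbation = pert, ranking = ranking,
                 summary = summary, manifest = manifest),
            class = "methylnet_run")
}

#' @export
print.methylnet_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "methylnet_run: %d CpGs x %d samples\n",
    "  pre-threshold <k> = %.2f, w* = %g, %d links kept\n",
    "  GRC(m) = %.4f (null z = %.2f), mean |delta_a| = %.3f yr (max %.3f)\n",
    "  cor(r_m, <c>) = %.3f, top-%d overlap (r_m, <c>) = %d\n"),
    s$n_cpgs, s$n_samples, s$mean_degree_prethreshold,
    if (is.numeric(s$w_star)) s$w_star else NA, s$n_links_thresholded,
    s$grc, s$grc_null_z, s$mean_abs_delta_a, s$max_abs_delta_a,
    s$pearson_reach_c_avg, nrow(x$ranking$top$reach),
    s$overlap_reach_c_avg))
  invisible(x)
}

#' Top-k ranking table across the three node scores
#'
#' Ranks nodes by |Delta a| (perturbation impact), m-reach (hierarchy
#' position) and sweep-averaged control centrality; reports the top-k per
#' criterion (ties broken by CpG id, so lists have exactly k members) and
#' all pairwise overlap counts between the lists.
#'
#' @param delta_a_abs,reach,c_avg Named numeric score vectors over the
#'   same node set.
#' @param k List size (<= number of nodes).
#' @return List of class `ranking_table`: `table` (per-node scores and
#'   top-k membership flags), `top` (list of three k-row tables),
#'   `overlaps` (3 x 3 count matrix).
#' @export
ranking_table <- function(delta_a_abs, reach, c_avg, k = 20) {
  nodes <- sort(names(delta_a_abs))
  if (!setequal(nodes, names(reach)) || !setequal(nodes, names(c_avg)))
    stop("score vectors must share the same node set")
  if (k > length(nodes)) stop("k exceeds the number of nodes")
  scores <- data.table::data.table(
    cpg_id = nodes, delta_a_abs = delta_a_abs[nodes],
    reach = reach[nodes], c_avg = c_avg[nodes])
  top_ids <- function(col) {
    ord <- order(-scores[[col]], scores$cpg_id)
    scores$cpg_id[ord[seq_len(k)]]
  }
  crit <- c("delta_a_abs", "reach", "c_avg")
  top <- lapply(crit, function(cl)
    scores[match(top_ids(cl), scores$cpg_id)])
  names(top) <- crit
  overlaps <- outer(crit, crit, Vectorize(function(a, b)
    length(intersect(top[[a]]$cpg_id, top[[b]]$cpg_id))))
  dimnames(overlaps) <- list(crit, crit)
  for (cl in crit)
    scores[[paste0("top_", cl)]] <- scores$cpg_id %in% top[[cl]]$cpg_id
  structure(list(table = scores, top = top, overlaps = overlaps, k = k),
            class = "ranking_table")
}

#' @export
print.ranking_table <- function(x, ...) {
  cat(sprintf("ranking_table: top-%d lists; overlap counts:\n", x$k))
  print(x$overlaps)
  invisible(x)
}

#' Hierarchy-position conservation under node-set mixing
#'
#' Tests whether nodes keep their hierarchical standing when embedded in
#' networks built from different node sets: each replicate mixes the
#' given seed CpGs with randomly drawn CpGs from a larger pool, re-runs
#' inference, thresholding and hierarchy on the mixed set, and records
#' where the seed nodes land (level and reach percentile).
#'
#' @param seed_nodes CpG ids whose position conservation is probed.
#' @param pool A [methyl_matrix] containing the seed CpGs and the
#'   candidate CpGs to mix in.
#' @param n_networks Number of mixed replicates (default 50).
#' @param network_size Nodes per mixed network (>= length(seed_nodes)).
#' @param seed Integer seed.
#' @param m Step horizon for reach.
#' @param n_folds CV folds for inference.
#' @param threshold `"auto"` or numeric w* for each replicate.
#' @return List of class `mixed_hierarchy`: `positions` (data.table of
#'   replicate, cpg_id, is_seed, reach, level, reach_percentile),
#'   `seed_percentiles`, `level_density` (seed vs all, by level).
#' @export
mixed_hierarchy_experiment <- function(seed_nodes, pool, n_networks = 50,
                                       network_size, seed = 1, m = 3,
                                       n_folds = 10,
                                       threshold = "auto") {
  stopifnot(all(seed_nodes %in% rownames(pool)))
  candidates <- setdiff(rownames(pool), seed_nodes)
  extra <- network_size - length(seed_nodes)
  if (extra < 0) stop("network_size smaller than the seed set")
  if (length(candidates) < extra)
    stop("pool too small: ", length(candidates), " candidates for ",
         extra, " slots")
  reps <- lapply(seq_len(n_networks), function(r) {
    rseed <- derive_seed(seed, r)
    chosen <- with_local_seed(rseed,
      c(seed_nodes, sample(candidates, extra)))
    sub <- methyl_matrix(unclass_matrix(pool)[chosen, , drop = FALSE],
                         ages = sample_ages(pool))
    net <- build_network(sub, n_folds = n_folds, seed = rseed)
    w_star <- if (identical(threshold, "auto"))
      scan_thresholds(net)$w_star else threshold
    reach <- m_reach_all(threshold_network(net, w_star), m = m)
    lev <- assign_levels(reach)
    data.table::data.table(
      replicate = r, cpg_id = names(reach),
      is_seed = names(reach) %in% seed_nodes,
      reach = unname(reach), level = unname(lev[names(reach)]),
      reach_percentile = (rank(reach, ties.method = "average") - 1) /
        (length(reach) - 1))
  })
  positions <- data.table::rbindlist(reps)
  lev_tab <- function(dt) {
    tab <- table(factor(dt$level, levels = 0:max(positions$level)))
    as.numeric(tab) / sum(tab)
  }
  structure(list(
    positions = positions,
    seed_percentiles = positions$reach_percentile[positions$is_seed],
    level_density = data.table::data.table(
      level = 0:max(positions$level),
      all = lev_tab(positions),
      seed = lev_tab(positions[positions$is_seed, ]))),
    class = "mixed_hierarchy")
}

#' @export
print.mixed_hierarchy <- function(x, ...) {
  cat(sprintf(
    "mixed_hierarchy: %d replicates, median seed reach percentile %.2f\n",
    max(x$positions$replicate), stats::median(x$seed_percentiles)))
  invisible(x)
}
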