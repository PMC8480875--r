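make_pair_matrix <- function(n = 200, seed = 21) {
  # m_j = 0.5 * m_i + small noise; 3 further independent CpGs
  withr::with_seed(seed, {
    mi <- runif(n, 0.2, 0.9)
    mj <- 0.5 * mi + rnorm(n, sd = 0.005) + 0.05
    other <- matrix(runif(3 * n, 0.1, 0.9), 3, n)
    vals <- rbind(mi, mj, other)
    dimnames(vals) <- list(c("cgi", "cgj", "cga", "cgb", "cgc"),
                           sprintf("s%03d", 1:n))
    methyl_matrix(pmin(pmax(vals, 0), 1))
  })
}

test_that("node Lasso recovers a single strong predictor", {
  mm <- make_pair_matrix()
  fit <- fit_node_lasso("cgj", mm, seed = 1)
  expect_lt(abs(fit$coefficients[["cgi"]] - 0.5), 0.05)
  expect_true(all(abs(fit$coefficients[setdiff(names(fit$coefficients),
                                               "cgi")]) < 0.01))
})

test_that("node Lasso on pure noise finds (almost) nothing", {
  # null simulation: response independent of all regressors; most CV fits
  # must be exactly empty and no spurious coefficient may approach the
  # magnitude of a genuine planted dependency
  maxima <- vapply(1:20, function(s) {
    mm <- withr::with_seed(1000 + s, {
      vals <- matrix(runif(5 * 200, 0.1, 0.9), 5, 200,
                     dimnames = list(paste0("cg", 1:5), paste0("s", 1:200)))
      methyl_matrix(vals)
    })
    max(abs(fit_node_lasso("cg1", mm, seed = s)$coefficients))
  }, numeric(1))
  expect_identical(stats::median(maxima), 0)
  expect_lt(max(maxima), 0.25)
  # the conservative CV choice keeps the null even cleaner
  maxima_1se <- vapply(1:10, function(s) {
    mm <- withr::with_seed(1000 + s, {
      vals <- matrix(runif(5 * 200, 0.1, 0.9), 5, 200,
                     dimnames = list(paste0("cg", 1:5), paste0("s", 1:200)))
      methyl_matrix(vals)
    })
    max(abs(fit_node_lasso("cg1", mm, seed = s,
                           lambda_choice = "lambda.1se")$coefficients))
  }, numeric(1))
  expect_lt(max(maxima_1se), 0.1)
})

test_that("fits are invariant to sample order under fixed folds", {
  mm <- make_pair_matrix(n = 80)
  foldid <- cv_fold_assignment(80, 10, seed = 3)
  f1 <- fit_node_lasso("cgj", mm, foldid = foldid)
  perm <- withr::with_seed(5, sample(80))
  mm_perm <- methyl_matrix(unclass(mm)[, perm])
  f2 <- fit_node_lasso("cgj", mm_perm, foldid = foldid[perm])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("constant response yields a zero model with a warning", {
  vals <- rbind(rep(0.4, 30), matrix(runif(60), 2, 30))
  dimnames(vals) <- list(paste0("cg", 1:3), paste0("s", 1:30))
  mm <- methyl_matrix(vals)
  expect_warning(fit <- fit_node_lasso("cg1", mm, seed = 1), "constant")
  expect_true(all(fit$coefficients == 0))
  expect_error(fit_node_lasso("nope", mm), "not in matrix")
})

test_that("build_network assembles one Lasso fit per response", {
  mm <- make_pair_matrix(n = 120)
  net <- build_network(mm, seed = 2)
  expect_s3_class(net, "signed_network")
  expect_identical(net$nodes, rownames(mm))
  expect_null(net$threshold)
  ed <- network_edges(net)
  # the strong planted dependency appears in both directions
  expect_true(any(ed$source == "cgi" & ed$target == "cgj"))
  expect_equal(ed$weight, abs(ed$beta))
})

test_that("network of mutually independent noise is near-empty", {
  mm <- withr::with_seed(77, {
    vals <- matrix(runif(3 * 120, 0.1, 0.9), 3, 120,
                   dimnames = list(paste0("cg", 1:3), paste0("s", 1:120)))
    methyl_matrix(vals)
  })
  net <- build_network(mm, seed = 1)
  ed <- network_edges(net)
  expect_true(nrow(ed) == 0 || max(ed$weight) < 0.05)
})

test_that("global efficiency matches closed forms", {
  full3 <- adj_to_igraph(matrix(1, 3, 3) - diag(3))
  expect_equal(global_efficiency(full3), 1.0)
  two <- adj_to_igraph(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(global_efficiency(two), 0.5)
  empty <- adj_to_igraph(matrix(0, 4, 4))
  expect_equal(global_efficiency(empty), 0)
  expect_error(global_efficiency(adj_to_igraph(matrix(0, 1, 1))),
               "at least 2")
})

test_that("local efficiency matches closed forms", {
  tri <- adj_to_igraph(matrix(1, 3, 3) - diag(3))
  expect_equal(local_efficiency(tri), 1.0)
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1
  expect_equal(local_efficiency(adj_to_igraph(star)), 0)
  expect_equal(local_efficiency(adj_to_igraph(matrix(0, 3, 3))), 0)
})

test_that("quality J composes the efficiencies and the density", {
  full3 <- adj_to_igraph(matrix(1, 3, 3) - diag(3))
  expect_equal(quality_J(full3), 2.0)
  two <- adj_to_igraph(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(quality_J(two), 1.0)   # (0.5 + 0) / 0.5
  expect_error(quality_J(adj_to_igraph(matrix(0, 3, 3))), "removed all")
})

test_that("efficiencies stay within [0, 1] on random digraphs", {
  withr::with_seed(42, {
    for (k in 1:25) {
      g <- adj_to_igraph(random_adjacency(sample(3:8, 1), runif(1, 0.1, 0.9)))
      if (igraph::ecount(g) == 0) next
      eg <- global_efficiency(g)
      el <- local_efficiency(g)
      expect_gte(eg, 0); expect_lte(eg, 1)
      expect_gte(el, 0); expect_lte(el, 1)
    }
  })
})

test_that("threshold scan removes weak satellite links on a planted toy", {
  # 4 mutually interconnected core nodes (|beta| = 0.9) plus 8 weak links
  # to satellite nodes (|beta| = 0.05)
  p <- 12
  b <- matrix(0, p, p)
  core <- 1:4
  for (i in core) for (j in core) if (i != j) b[j, i] <- 0.9
  sat <- 5:12
  b[cbind(sat, rep(core, 2))] <- 0.05
  net <- net_from_beta(b)
  scan <- scan_thresholds(net, grid = c(0.01, 0.5))
  expect_equal(scan$w_star, 0.5)
  # quality at each candidate agrees with direct evaluation
  j_dense <- quality_J(as_igraph(threshold_network(net, 0.01)))
  j_sparse <- quality_J(as_igraph(threshold_network(net, 0.5)))
  expect_equal(scan$scan$J, c(j_dense, j_sparse))
  expect_gt(j_sparse, j_dense)
  one <- scan_thresholds(net, grid = 0.3)
  expect_equal(one$w_star, 0.3)
})

test_that("thresholding is monotone and keeps signs", {
  withr::with_seed(8, {
    b <- random_adjacency(10, 0.4) * matrix(runif(100, -1, 1), 10, 10)
  })
  net <- net_from_beta(b)
  t1 <- threshold_network(net, 0.2)
  t2 <- threshold_network(net, 0.5)
  e1 <- network_edges(t1); e2 <- network_edges(t2)
  expect_true(all(paste(e2$source, e2$target) %in%
                  paste(e1$source, e1$target)))
  expect_true(all(e1$weight >= 0.2))
  expect_true(any(e1$beta < 0))   # signs survive thresholding
  expect_equal(t2$threshold, 0.5)
})
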