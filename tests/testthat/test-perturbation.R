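test_that("effective coefficients match hand-enumerated walks", {
  # single link i -> j
  b <- matrix(0, 3, 3); b[2, 1] <- 0.5
  eff <- effective_beta(net_from_beta(b), "n01", l_max = 4)
  expect_equal(unname(eff), c(0, 0.5, 0))
  # chain i -> k -> j
  b2 <- matrix(0, 3, 3); b2[2, 1] <- 0.4; b2[3, 2] <- 0.5
  eff2 <- effective_beta(net_from_beta(b2), "n01", l_max = 2)
  expect_equal(unname(eff2), c(0, 0.4, 0.2))
  # 2-cycle: odd walks reach the partner, even walks return home
  b3 <- matrix(0, 2, 2); b3[2, 1] <- 0.5; b3[1, 2] <- 0.5
  eff3 <- effective_beta(net_from_beta(b3), "n01", l_max = 4)
  expect_equal(unname(eff3[2]), 0.5 + 0.125)          # lengths 1, 3
  expect_equal(unname(eff3[1]), 0.25 + 0.0625)        # lengths 2, 4
  expect_error(effective_beta(net_from_beta(b), "n01", l_max = 0),
               "l_max")
})

test_that("sparse walk sums equal the enumeration oracle everywhere", {
  withr::with_seed(7, {
    for (k in 1:40) {
      n <- sample(2:6, 1)
      b <- random_adjacency(n, runif(1, 0.2, 0.7)) *
        matrix(runif(n * n, -1, 1), n, n)
      net <- net_from_beta(b)
      i <- sample(n, 1)
      l <- sample(1:4, 1)
      expect_equal(unname(effective_beta(net, net$nodes[i], l_max = l)),
                   oracle_effective_beta(b, i, l),
                   tolerance = 1e-12)
    }
  })
})

test_that("simple-path mode differs from walk sums only through cycles", {
  # DAG: identical
  b <- matrix(0, 4, 4); b[2, 1] <- 0.4; b[3, 2] <- 0.5; b[4, 3] <- -0.3
  net <- net_from_beta(b)
  expect_equal(effective_beta(net, "n01", 4, paths = "simple"),
               effective_beta(net, "n01", 4))
  # 2-cycle: simple paths stop at length 1
  b2 <- matrix(0, 2, 2); b2[2, 1] <- 0.5; b2[1, 2] <- 0.5
  net2 <- net_from_beta(b2)
  expect_equal(unname(effective_beta(net2, "n01", 4, paths = "simple")),
               c(0, 0.5))
})

test_that("age derivative follows the propagated chain rule", {
  at <- 20
  cl0 <- clock_model(c(n01 = 0.1, n02 = 0.2, n03 = -0.3), at)
  empty <- net_from_beta(matrix(0, 3, 3))
  expect_equal(age_derivative(empty, cl0, "n01", l_max = 0), 2.1)
  expect_equal(age_derivative(empty, cl0, "n01", l_max = 4), 2.1)
  b <- matrix(0, 3, 3); b[2, 1] <- 0.5
  net <- net_from_beta(b)
  expect_equal(age_derivative(net, cl0, "n01", l_max = 1),
               21 * (0.1 + 0.2 * 0.5))   # = 4.2
  bad <- clock_model(c(n01 = 0.1), at)
  expect_error(age_derivative(net, bad, "n01"), "missing")
})

test_that("derivative truncation adds exactly the order-l walk term", {
  withr::with_seed(23, {
    b <- random_adjacency(5, 0.5) * matrix(runif(25, -0.8, 0.8), 5, 5)
    net <- net_from_beta(b)
    h <- runif(5, -0.5, 0.5)
    cl <- clock_model(setNames(h, net$nodes), 20)
    for (l in 2:4) {
      d_l <- age_derivative(net, cl, "n01", l_max = l)
      d_prev <- age_derivative(net, cl, "n01", l_max = l - 1)
      # order-l term from the oracle: products over walks of exactly length l
      term <- sum(h * (oracle_effective_beta(b, 1, l) -
                         oracle_effective_beta(b, 1, l - 1)))
      expect_equal(d_l - d_prev, 21 * term, tolerance = 1e-10)
    }
  })
})

test_that("delta_a scales linearly and composes derivative and spread", {
  cl <- clock_model(c(n01 = 0.1, n02 = 0.2, n03 = -0.3), 20)
  empty <- net_from_beta(matrix(0, 3, 3))
  res <- delta_a(empty, cl, node = "n01", l_max = 0, delta_m = 0.1)
  expect_equal(res$delta_a, 0.21)
  expect_equal(res$delta_a, res$derivative * res$delta_m)
  res2 <- delta_a(empty, cl, node = "n01", l_max = 0, delta_m = 0.2)
  expect_equal(res2$delta_a, 2 * res$delta_a)
  # zero-variance cohort implies zero perturbation
  const <- methyl_matrix(matrix(0.5, 3, 4,
                                dimnames = list(c("n01", "n02", "n03"),
                                                paste0("s", 1:4))))
  res3 <- delta_a(empty, cl, const, node = "n02", l_max = 0)
  expect_equal(res3$delta_a, 0)
})

test_that("projection geometry matches hand-worked coordinates", {
  # H = (1, 0); samples (3, 4) and (3, 0)
  vals <- matrix(c(0.3, 0.3, 0.4, 0.0), 2, 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("q1", "q2")))
  mm <- methyl_matrix(vals)
  cl <- clock_model(c(a = 1, b = 0), 20)
  pr <- project_cloud(mm, cl)
  expect_equal(unname(pr$along), c(0.3, 0.3))
  expect_equal(unname(pr$perp_distance), c(0.2, 0.2))
  single <- methyl_matrix(vals[, 1, drop = FALSE])
  expect_equal(unname(project_cloud(single, cl)$perp_distance), 0)
})

test_that("along-H coordinate reproduces the linear-branch age estimate", {
  co <- generate_cohort(n_cpgs = 10, n_samples = 40, seed = 6)
  pr <- project_cloud(co$matrix, co$clock)
  a_from_proj <- (co$clock$adult_threshold + 1) * pr$h_norm * pr$along +
    co$clock$adult_threshold
  expect_equal(unname(a_from_proj),
               unname(horvath_age_matrix(co$matrix, co$clock)),
               tolerance = 1e-10)
})

test_that("displacement angles behave at the collinear and orthogonal poles", {
  empty <- net_from_beta(matrix(0, 3, 3))
  cl_e1 <- clock_model(c(n01 = 0.7, n02 = 0, n03 = 0), 20)
  g <- displacement_geometry(empty, cl_e1, node = "n01", l_max = 0,
                             delta_m = 0.1)
  expect_equal(g$angle, 0)
  cl_perp <- clock_model(c(n01 = 0, n02 = 0.5, n03 = 0), 20)
  g2 <- displacement_geometry(empty, cl_perp, node = "n01", l_max = 0,
                              delta_m = 0.1)
  expect_equal(g2$angle, pi / 2)
  g3 <- displacement_geometry(empty, cl_e1, node = "n02", l_max = 0,
                              delta_m = 0)
  expect_true(g3$zero_displacement)
  expect_identical(g3$angle, NA_real_)
})

test_that("propagation over a network pulls displacement toward H", {
  # i alone is orthogonal to H; its out-link feeds the H-carrying node
  b <- matrix(0, 3, 3); b[2, 1] <- 0.8
  net <- net_from_beta(b)
  cl <- clock_model(c(n01 = 0.01, n02 = 0.9, n03 = 0), 20)
  a0 <- displacement_geometry(net, cl, node = "n01", l_max = 0,
                              delta_m = 0.1)$angle
  a4 <- displacement_geometry(net, cl, node = "n01", l_max = 4,
                              delta_m = 0.1)$angle
  expect_lt(a4, a0)
})

test_that("perturbing the true network matches generative propagation", {
  co <- generate_cohort(n_cpgs = 15, n_samples = 60, seed = 11)
  net <- co$true_network
  cl <- co$clock
  dm <- 2 * mean_cpg_std(co$matrix)
  bmat <- as.matrix(net$beta)
  h <- cl$coefficients[net$nodes]
  for (nd in net$nodes[c(1, 5, 10)]) {
    res <- delta_a(net, cl, co$matrix, node = nd, l_max = 4)
    i <- match(nd, net$nodes)
    # truncated analytic propagation of the generative linear model
    acc <- numeric(15); v <- numeric(15); v[i] <- 1
    for (l in 1:4) { v <- drop(bmat %*% v); acc <- acc + v }
    expected <- 21 * (h[[nd]] + sum(h * acc)) * dm
    expect_equal(res$delta_a, expected, tolerance = 1e-8)
  }
})

test_that("perturb_all tabulates every node with both angles", {
  co <- generate_cohort(n_cpgs = 8, n_samples = 40, seed = 13)
  tab <- perturb_all(co$true_network, co$clock, co$matrix, l_max = 4)
  expect_identical(tab$cpg_id, co$true_network$nodes)
  expect_equal(tab$delta_a_abs, abs(tab$delta_a))
  expect_true(all(is.finite(tab$angle_l0)))
})
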