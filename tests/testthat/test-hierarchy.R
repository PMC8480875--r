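chain3 <- function() adj_to_igraph(matrix(c(0, 1, 0,
                                            0, 0, 1,
                                            0, 0, 0), 3, 3, byrow = TRUE))

test_that("m-reach on the 3-chain matches hand values", {
  g <- chain3()
  expect_equal(m_reach(g, "n01", m = 3), 1.0)
  expect_equal(m_reach(g, "n01", m = 1), 0.5)
  expect_equal(m_reach(g, "n03", m = 5), 0.0)
  expect_error(m_reach(g, "nope", 2), "not in graph")
  r <- m_reach_all(g, m = 2)
  expect_equal(unname(r), c(1, 0.5, 0))
})

test_that("m-reach is monotone non-decreasing in m", {
  withr::with_seed(31, {
    for (k in 1:10) {
      g <- adj_to_igraph(random_adjacency(7, 0.3))
      r_prev <- m_reach_all(g, 1)
      for (m in 2:5) {
        r <- m_reach_all(g, m)
        expect_true(all(r >= r_prev - 1e-12))
        r_prev <- r
      }
    }
  })
})

test_that("GRC matches closed forms on star, cycle and chain", {
  star <- matrix(0, 6, 6); star[1, 2:6] <- 1
  expect_equal(grc(adj_to_igraph(star), m = 3), 1.0)
  cyc <- matrix(0, 5, 5); cyc[cbind(1:5, c(2:5, 1))] <- 1
  expect_equal(grc(adj_to_igraph(cyc), m = 4), 0.0)
  expect_equal(grc(chain3(), m = 2), 0.75)
})

test_that("BFS reach and GRC agree with the matrix-power oracle", {
  withr::with_seed(99, {
    for (k in 1:60) {
      n <- sample(3:8, 1)
      adj <- random_adjacency(n, runif(1, 0.1, 0.8))
      m <- sample(1:5, 1)
      g <- adj_to_igraph(adj)
      expect_equal(unname(m_reach_all(g, m)), oracle_reach(adj, m))
      expect_equal(grc(g, m), oracle_grc(adj, m))
    }
  })
})

test_that("link randomization preserves both degree sequences exactly", {
  withr::with_seed(13, {
    for (k in 1:10) {
      adj <- random_adjacency(8, 0.35)
      g <- adj_to_igraph(adj)
      if (igraph::ecount(g) < 2) next
      r <- randomize_links(g, swaps_per_link = 10, seed = k)
      expect_identical(igraph::degree(r, mode = "in"),
                       igraph::degree(g, mode = "in"))
      expect_identical(igraph::degree(r, mode = "out"),
                       igraph::degree(g, mode = "out"))
      expect_identical(igraph::ecount(r), igraph::ecount(g))
      expect_true(igraph::is_simple(r))
    }
  })
})

test_that("randomization is seed-deterministic and moves links", {
  adj <- withr::with_seed(3, random_adjacency(10, 0.3))
  g <- adj_to_igraph(adj)
  r1 <- randomize_links(g, seed = 5)
  r2 <- randomize_links(g, seed = 5)
  expect_identical(igraph::as_edgelist(r1), igraph::as_edgelist(r2))
  r3 <- randomize_links(g, seed = 6)
  expect_false(identical(igraph::as_edgelist(r1),
                         igraph::as_edgelist(r3)))
})

test_that("two disjoint links admit exactly one swap outcome", {
  adj <- matrix(0, 4, 4); adj[1, 2] <- 1; adj[3, 4] <- 1
  g <- adj_to_igraph(adj)
  r <- randomize_links(g, swaps_per_link = 0.5, seed = 1)  # one swap
  el <- igraph::as_edgelist(r)
  expect_setequal(paste(el[, 1], el[, 2]),
                  c("n01 n04", "n03 n02"))
})

test_that("a rigid graph raises the rigidity error with acceptance rate", {
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1
  expect_error(randomize_links(adj_to_igraph(star), seed = 1, max_tries = 5),
               "too rigid.*acceptance")
})

test_that("GRC null flags degenerate ensembles instead of dividing by zero", {
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1
  res <- grc_null(adj_to_igraph(star), m = 3, n_samples = 50, seed = 2)
  expect_true(res$degenerate)
  expect_identical(res$z, NA_real_)
  expect_equal(res$null_sd, 0)
  expect_equal(res$observed, 1)
})

test_that("a directed cycle is never more hierarchical than its null", {
  cyc <- matrix(0, 6, 6); cyc[cbind(1:6, c(2:6, 1))] <- 1
  res <- grc_null(adj_to_igraph(cyc), m = 3, n_samples = 100, seed = 4)
  expect_equal(res$observed, 0)
  expect_true(res$degenerate || res$z <= 0)
})

test_that("level assignment groups by the reach-gap rule", {
  expect_equal(unname(assign_levels(c(a = 0.5, b = 0.5, c = 0.5))),
               c(0L, 0L, 0L))
  lv <- assign_levels(c(a = 1.0, b = 0.5, c = 0.0))
  expect_equal(lv, c(a = 0L, b = 1L, c = 2L))
  lv2 <- assign_levels(c(a = 1.0, b = 0.99, c = 0.0))
  expect_equal(lv2, c(a = 0L, b = 0L, c = 1L))
  expect_equal(unname(assign_levels(c(x = 0.3))), 0L)
})

test_that("the multi-horizon null profile matches the single-m null", {
  adj <- layered_graph(3, 5, 0.6, seed = 9)
  g <- adj_to_igraph(adj)
  prof <- grc_null_profile(g, ms = 2:4, n_samples = 60, seed = 11)
  single <- grc_null(g, m = 3, n_samples = 60, seed = 11)
  # identical ensemble stream, so the m = 3 row must agree exactly
  expect_equal(prof$z[prof$m == 3], single$z)
  expect_equal(prof$observed, vapply(2:4, function(m) grc(g, m),
                                     numeric(1)))
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1
  prof_star <- grc_null_profile(adj_to_igraph(star), ms = 2:3,
                                n_samples = 20, seed = 1)
  expect_true(all(prof_star$degenerate))
})

test_that("hierarchy_analysis bundles reach, levels, GRC and the null", {
  adj <- layered_graph(3, 4, 0.7, seed = 12)
  g <- adj_to_igraph(adj)
  h <- hierarchy_analysis(g, m = 3, null_samples = 30, seed = 1)
  expect_equal(h$grc, grc(g, 3))
  expect_equal(h$reach, m_reach_all(g, 3))
  expect_identical(sort(unique(unname(h$levels))),
                   seq(0L, max(h$levels)))
  expect_length(h$null$null_samples, 30)
})
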