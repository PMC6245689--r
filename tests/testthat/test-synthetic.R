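test_that("generate_network builds connected right-skewed networks", {
  net2 <- generate_network(2, seed = 1)
  expect_equal(nrow(net2$edges), 1)
  expect_error(generate_network(1), "at least 2")
  maxdeg <- meddeg <- numeric(20)
  for (s in 1:20) {
    net <- generate_network(200, seed = s)
    expect_gte(nrow(net$edges), 199)
    expect_lte(nrow(net$edges), 2 * 199)
    g <- igraph::graph_from_data_frame(net$edges[, 1:2], vertices = net$genes)
    expect_true(igraph::is_connected(g, mode = "weak"))
    expect_false(any(net$edges$from == net$edges$to))
    deg <- igraph::degree(g)
    maxdeg[s] <- max(deg); meddeg[s] <- median(deg)
  }
  expect_true(all(maxdeg > meddeg))     # right-skewed degree distribution
  expect_true(all(net$edges$strength >= 0.5 & net$edges$strength <= 1))
})

test_that("simulate_expression couples targets to regulators", {
  # noiseless 2-gene chain: target a deterministic monotone function of regulator
  net <- structure(list(genes = c("g1", "g2"),
                        edges = data.frame(from = "g1", to = "g2",
                                           sign = 1, strength = 1)),
                   class = "true_network")
  X <- simulate_expression(net, p = 50, noise_sd = 0, seed = 2)
  ct <- copula_transform(X)
  expect_equal(abs(cor(ct[1, ], ct[2, ])), 1, tolerance = 1e-9)

  # adjacent pairs carry more MI than random non-adjacent pairs
  wins <- 0
  for (s in 1:10) {
    net <- generate_network(50, seed = 100 + s)
    X <- simulate_expression(net, p = 100, noise_sd = 0.1)
    mi <- mi_matrix(copula_transform(X))
    adj <- as.matrix(net$edges[, 1:2])
    edge_mi <- mi$M[adj]
    non_edges <- which(upper.tri(mi$M), arr.ind = TRUE)
    keys <- paste(pmin(adj[, 1], adj[, 2]), pmax(adj[, 1], adj[, 2]))
    nm <- mi$M[non_edges][!(paste(
      pmin(net$genes[non_edges[, 1]], net$genes[non_edges[, 2]]),
      pmax(net$genes[non_edges[, 1]], net$genes[non_edges[, 2]])) %in% keys)]
    wins <- wins + (median(edge_mi) > median(nm))
  }
  expect_gte(wins, 9)

  # independent roots have near-zero MI
  net0 <- structure(list(genes = c("r1", "r2"),
                         edges = data.frame(from = character(0), to = character(0),
                                            sign = numeric(0), strength = numeric(0))),
                    class = "true_network")
  X0 <- simulate_expression(net0, p = 2000, seed = 3)
  expect_lt(gaussian_mi(X0[1, ], X0[2, ]), 0.01)
})

test_that("inject_antisense behaves across the coupling range", {
  set.seed(60)
  X <- toy_expression(10, 30)
  Xi <- inject_antisense(X, c("g1", "g2"), coupling = 1, seed = 4)
  expect_equal(nrow(Xi), 12)
  expect_equal(Xi["g1_AS", ], -X["g1", ])
  expect_warning(mi <- gaussian_mi(Xi["g1", ], Xi["g1_AS", ]), "collinear")
  expect_equal(mi, 1e6)
  # coupling 0: pure noise, low MI
  X0 <- inject_antisense(X, "g3", coupling = 0, seed = 5)
  expect_lt(gaussian_mi(X0["g3", ], X0["g3_AS", ]), 0.3)
  # duplicate injection errors
  expect_error(inject_antisense(Xi, "g1", 0.5), "duplicate|present")
  expect_error(inject_antisense(X, "g1", 1.5), "coupling")
})

test_that("f1_score computes the printed formulas", {
  truth <- structure(list(genes = c("a", "b", "c", "d"),
                          edges = data.frame(from = c("a", "b", "c"),
                                             to = c("b", "c", "d"),
                                             sign = 1, strength = 1)),
                     class = "true_network")
  perfect <- net_fixture(c("a", "b", "c", "d"),
                         list(c("a", "b"), c("b", "c"), c("c", "d")),
                         directed = FALSE)
  sc <- f1_score(truth, perfect)
  expect_equal(c(sc$precision, sc$recall, sc$f1), c(1, 1, 1))
  # TP=1, FP=1, FN=2 -> precision .5, recall 1/3
  part <- net_fixture(c("a", "b", "c", "d"),
                      list(c("a", "b"), c("a", "c")), directed = FALSE)
  sc2 <- f1_score(truth, part)
  expect_equal(sc2$precision, 0.5)
  expect_equal(sc2$recall, 1 / 3)
  expect_equal(sc2$f1, 2 * (0.5 * 1 / 3) / (0.5 + 1 / 3))
  # TP=2, FP=0, FN=1 -> precision 1, recall 2/3, F1 = 0.8
  part2 <- net_fixture(c("a", "b", "c", "d"),
                       list(c("a", "b"), c("b", "c")), directed = FALSE)
  sc3 <- f1_score(truth, part2)
  expect_equal(c(sc3$precision, sc3$recall, sc3$f1), c(1, 2 / 3, 0.8))
  # empty inferred network: F1 = 0 by convention
  empty <- core_network(c("a", "b", "c", "d"), matrix(FALSE, 4, 4))
  expect_equal(f1_score(truth, empty)$f1, 0)
  expect_error(f1_score(structure(list(genes = "a",
                                       edges = data.frame()),
                                  class = "true_network"), perfect),
               "no edges")
})

test_that("run_study is reproducible and returns tidy rows", {
  b1 <- run_study(n = 15, p = 20, S = 2, rates = c(0, 0.5), seed = 77,
                  n_perm = 10)
  b2 <- run_study(n = 15, p = 20, S = 2, rates = c(0, 0.5), seed = 77,
                  n_perm = 10)
  expect_identical(b1, b2)
  expect_setequal(unique(b1$method), c("c3net", "ecn_0", "ecn_0.5"))
  expect_equal(nrow(b1), 2 * 3)
  expect_true(all(b1$j >= 10 & b1$j <= 20))
  expect_true(all(b1$f1 >= 0 & b1$f1 <= 1))
})

test_that("precision does not increase from low to full accepting rate", {
  b <- run_study(n = 25, p = 40, S = 8, rates = c(0, 1), seed = 101,
                 n_perm = 15)
  p0 <- b$precision[b$method == "ecn_0"]
  p1 <- b$precision[b$method == "ecn_1"]
  expect_true(all(p1 <= p0 + 1e-12))
})
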