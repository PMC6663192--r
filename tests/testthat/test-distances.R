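make_pair <- function(seed, p = 8, n = 6) {
  set.seed(seed)
  list(metric_weights(correlation_matrix(matrix(rnorm(n * p), n, p))),
       metric_weights(correlation_matrix(matrix(rnorm(n * p), n, p))))
}

test_that("Lp distances follow their direct formulas", {
  nets <- make_pair(1)
  for (ord in list(1, 2, Inf))
    expect_equal(lp_distance(nets[[1]], nets[[1]], ord), 0)

  # single differing edge: every order returns the difference
  w <- matrix(0.5, 4, 4); diag(w) <- 0
  w2 <- w; w2[1, 2] <- w2[2, 1] <- 0.8
  a <- weighted_network(w); b <- weighted_network(w2)
  for (ord in list(1, 2, Inf))
    expect_equal(lp_distance(a, b, ord), 0.3)

  d <- nets[[1]]$weights - nets[[2]]$weights
  d <- abs(d[upper.tri(d)])
  expect_equal(lp_distance(nets[[1]], nets[[2]], 1), sum(d))
  expect_equal(lp_distance(nets[[1]], nets[[2]], 2), sqrt(sum(d^2)))
  expect_equal(lp_distance(nets[[1]], nets[[2]], Inf), max(d))

  expect_error(lp_distance(nets[[1]], rand_network(5, 1)), "node set")
})

test_that("GH distance is half the Linf gap of minimax matrices", {
  nets <- make_pair(2)
  expect_equal(gh_distance(nets[[1]], nets[[1]]), 0)

  # doubling all weights doubles the ultrametric: GH = max(s)/2
  s1 <- single_linkage_matrix(nets[[1]])
  doubled <- weighted_network(2 * nets[[1]]$weights)
  expect_equal(gh_distance(nets[[1]], doubled), max(s1) / 2)

  for (seed in 3:5) {
    nets <- make_pair(seed)
    oracle <- max(abs(brute_minimax(nets[[1]]$weights) -
                      brute_minimax(nets[[2]]$weights))) / 2
    expect_equal(gh_distance(nets[[1]], nets[[2]]), oracle)
  }
})

test_that("GH distance satisfies the triangle inequality", {
  for (seed in 6:8) {
    n1 <- rand_network(7, seed)
    n2 <- rand_network(7, seed + 100)
    n3 <- rand_network(7, seed + 200)
    expect_lte(gh_distance(n1, n3),
               gh_distance(n1, n2) + gh_distance(n2, n3) + 1e-12)
  }
})

test_that("bottleneck distance is exact against the bijection oracle", {
  # one off-diagonal point vs empty diagram: matched to its projection
  expect_equal(bettinet:::.bottleneck_points(cbind(0, 1),
                                             matrix(0, 0, 2)), 0.5)
  set.seed(9)
  for (rep in 1:6) {
    m <- sample(0:4, 1); n <- sample(1:4, 1)
    pts1 <- matrix(sort(runif(2 * m)), ncol = 2, byrow = TRUE)
    pts2 <- matrix(sort(runif(2 * n)), ncol = 2, byrow = TRUE)
    if (m == 0) pts1 <- matrix(0, 0, 2)
    expect_equal(bettinet:::.bottleneck_points(pts1, pts2),
                 brute_bottleneck(pts1, pts2), tolerance = 1e-12)
  }
})

test_that("bottleneck on networks is symmetric and zero on identity", {
  nets <- make_pair(10, p = 6)
  for (dim in 0:1) {
    expect_equal(bottleneck_distance_networks(nets[[1]], nets[[1]], dim), 0)
    expect_equal(bottleneck_distance_networks(nets[[1]], nets[[2]], dim),
                 bottleneck_distance_networks(nets[[2]], nets[[1]], dim))
    expect_gte(bottleneck_distance_networks(nets[[1]], nets[[2]], dim), 0)
  }
})

test_that("KS statistic reproduces hand-enumerated Betti gaps", {
  tri <- edges_network(3, list(list(1, 2, 0.1), list(2, 3, 0.2),
                               list(1, 3, 0.3)))
  path <- edges_network(3, list(list(1, 2, 0.1), list(2, 3, 0.2)))
  # grids: union {0, .1, .2, .3}; triangle beta0 = 1,1,2,3, path = 1,2,3,3
  ks0 <- ks_statistic(tri, path, 0)
  expect_equal(ks0$grid, c(0, 0.1, 0.2, 0.3))
  expect_equal(ks0$gaps, c(0, 1, 1, 0), ignore_attr = TRUE)
  expect_equal(ks0$D, 1)
  # beta1: triangle has the single cycle below 0.1, the path none
  ks1 <- ks_statistic(tri, path, 1)
  expect_equal(ks1$D, 1)
  expect_equal(ks1$gaps, c(1, 0, 0, 0), ignore_attr = TRUE)

  nets <- make_pair(11)
  expect_equal(ks_statistic(nets[[1]], nets[[1]], 0)$D, 0)
  expect_equal(ks_statistic(nets[[1]], nets[[1]], 1)$D, 0)
})

test_that("KS is invariant under common monotone reparameterization, Lp is not", {
  for (seed in 12:14) {
    nets <- make_pair(seed)
    for (dim in 0:1) {
      d0 <- ks_statistic(nets[[1]], nets[[2]], dim)$D
      for (phi in list(function(w) w^2, function(w) log1p(w),
                       function(w) 5 * w)) {
        t1 <- weighted_network(phi(nets[[1]]$weights))
        t2 <- weighted_network(phi(nets[[2]]$weights))
        expect_equal(ks_statistic(t1, t2, dim)$D, d0)
      }
    }
    sq1 <- weighted_network(nets[[1]]$weights^2)
    sq2 <- weighted_network(nets[[2]]$weights^2)
    expect_false(isTRUE(all.equal(lp_distance(nets[[1]], nets[[2]], 2),
                                  lp_distance(sq1, sq2, 2))))
  }
})

test_that("modularity difference matches exhaustive partition search", {
  # two 4-cliques (as weights) vs a uniform complete graph
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 1; w[5:8, 5:8] <- 1; diag(w) <- 0
  cliques <- weighted_network(w)
  uni <- weighted_network(matrix(1, 8, 8) - diag(8))

  brute_q <- function(net) {
    max(vapply(all_partitions(8),
               function(mb) manual_modularity(net$weights, mb), numeric(1)))
  }
  d <- modularity_difference(cliques, uni)
  expect_equal(as.numeric(d), abs(brute_q(cliques) - brute_q(uni)),
               tolerance = 1e-10)
  expect_equal(as.numeric(modularity_difference(cliques, cliques)), 0)
  expect_equal(as.numeric(modularity_difference(uni, cliques)),
               as.numeric(d))
  expect_gte(as.numeric(d), 0)
})

test_that("network_distance dispatches and rejects unknown methods", {
  nets <- make_pair(15, p = 5)
  for (m in c("l1", "l2", "linf", "gh", "bottleneck0", "bottleneck1",
              "ks0", "ks1", "qmod")) {
    v <- network_distance(nets[[1]], nets[[2]], m)
    expect_true(is.numeric(v) && v >= 0)
    expect_equal(network_distance(nets[[1]], nets[[1]], m), 0)
  }
  expect_error(network_distance(nets[[1]], nets[[2]], "wasserstein"),
               "unknown")
})
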