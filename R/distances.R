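## Network distances on a shared node set: Lp on edge weights,
## Gromov-Hausdorff on single-linkage matrices, bottleneck on persistence
## diagrams, Kolmogorov-Smirnov on Betti curves, and the Q-modularity
## difference comparator.

.check_pair <- function(net1, net2) {
  net1 <- .as_network(net1)
  net2 <- .as_network(net2)
  if (length(net1$labels) != length(net2$labels))
    stop("networks must share a node set")
  if (!identical(net1$labels, net2$labels) &&
      !setequal(net1$labels, net2$labels))
    stop("networks must share a node set")
  list(net1, net2)
}

#' Lp distance between weighted networks
#'
#' Entrywise norm of the upper-triangle weight differences (each edge
#' counted once): sum of absolute differences (order 1), root sum of
#' squares (order 2), or maximum absolute difference (order `Inf`).
#'
#' @param net1,net2 [weighted_network()] objects on the same node set.
#' @param order 1, 2 or `Inf`.
#' @return Nonnegative scalar.
#' @export
lp_distance <- function(net1, net2, order = 2) {
  nets <- .check_pair(net1, net2)
  d <- nets[[1]]$weights - nets[[2]]$weights
  d <- abs(d[upper.tri(d)])
  if (identical(order, 1) || identical(order, 1L)) sum(d)
  else if (identical(order, 2) || identical(order, 2L)) sqrt(sum(d^2))
  else if (is.infinite(order)) if (length(d)) max(d) else 0
  else stop("order must be 1, 2 or Inf")
}

#' Gromov-Hausdorff distance between networks via dendrograms
#'
#' Half the maximum absolute difference between the two single-linkage
#' (minimax/ultrametric) matrices.
#'
#' @inheritParams lp_distance
#' @return Nonnegative scalar.
#' @export
gh_distance <- function(net1, net2) {
  nets <- .check_pair(net1, net2)
  s1 <- single_linkage_matrix(nets[[1]])
  s2 <- single_linkage_matrix(nets[[2]])
  max(abs(s1 - s2)) / 2
}

## Exact bottleneck distance between two point sets (m x 2 matrices).
## Each diagram is augmented with the orthogonal projections of the other's
## points onto the diagonal; pairs of augmented (diagonal) points cost 0.
## The optimum is found by binary search over candidate costs with a
## bipartite perfect-matching feasibility check (augmenting paths).
.bottleneck_points <- function(pts1, pts2) {
  m <- nrow(pts1); n <- nrow(pts2)
  if (m == 0 && n == 0) return(0)
  proj <- function(pts) {
    mid <- (pts[, 1] + pts[, 2]) / 2
    cbind(mid, mid)
  }
  a <- rbind(pts1, proj(pts2))   # m + n points
  b <- rbind(pts2, proj(pts1))
  N <- m + n
  cost <- matrix(0, N, N)
  for (i in seq_len(N))
    cost[i, ] <- pmax(abs(a[i, 1] - b[, 1]), abs(a[i, 2] - b[, 2]))
  if (m < N && n < N)
    cost[(m + 1):N, (n + 1):N] <- 0  # diagonal-to-diagonal pairs are free
  .bottleneck_cost_cpp(cost)
}

#' Bottleneck distance between two networks' persistence diagrams
#'
#' The minimum over bijections (after augmenting each diagram with the
#' other's diagonal projections) of the maximum L-infinity point
#' displacement, computed exactly.
#'
#' @inheritParams lp_distance
#' @param dimension 0 or 1.
#' @param essential_death Passed to [persistence_diagram()]; by default the
#'   common maximum edge weight of the two networks, so that identical
#'   networks are at distance zero.
#' @return Nonnegative scalar.
#' @export
bottleneck_distance_networks <- function(net1, net2, dimension = 0,
                                         essential_death = NULL) {
  nets <- .check_pair(net1, net2)
  if (is.null(essential_death))
    essential_death <- max(nets[[1]]$weights, nets[[2]]$weights)
  d1 <- persistence_diagram(nets[[1]], dimension, essential_death)
  d2 <- persistence_diagram(nets[[2]], dimension, essential_death)
  .bottleneck_points(d1$points, d2$points)
}

#' Kolmogorov-Smirnov statistic between Betti curves
#'
#' The maximum absolute difference between the two networks' Betti step
#' functions across filtration levels. With the default grid (the union of
#' both networks' unique positive edge weights, plus zero) the discrete
#' maximum equals the true supremum over all levels, and the statistic is
#' invariant under any common strictly increasing transform of the weights.
#'
#' @inheritParams lp_distance
#' @param dimension 0 (connected components) or 1 (cycles).
#' @param grid Optional vector of filtration levels.
#' @return Object of class `ks_statistic`: list with `D` (integer),
#'   `dimension`, `grid` and `gaps` (per-level absolute differences).
#' @export
ks_statistic <- function(net1, net2, dimension = 1, grid = NULL) {
  nets <- .check_pair(net1, net2)
  if (!dimension %in% c(0, 1)) stop("dimension must be 0 or 1")
  if (is.null(grid)) {
    w1 <- nets[[1]]$weights[upper.tri(nets[[1]]$weights)]
    w2 <- nets[[2]]$weights[upper.tri(nets[[2]]$weights)]
    grid <- sort(unique(c(0, w1[w1 > 0], w2[w2 > 0])))
  }
  if (length(grid) == 0) stop("filtration grid is empty")
  grid <- sort(unique(as.numeric(grid)))
  col <- if (dimension == 0) "beta0" else "beta1"
  b1 <- .betti_profile(nets[[1]]$weights, grid)[, col]
  b2 <- .betti_profile(nets[[2]]$weights, grid)[, col]
  gaps <- abs(b1 - b2)
  structure(list(D = max(gaps), dimension = dimension, grid = grid,
                 gaps = gaps),
            class = "ks_statistic")
}

#' @export
print.ks_statistic <- function(x, ...) {
  cat(sprintf("KS statistic (beta%d): D = %d over %d filtration levels\n",
              x$dimension, x$D, length(x$grid)))
  invisible(x)
}

#' Q-modularity difference between networks
#'
#' Absolute difference of the weighted Newman modularity of the partitions
#' found by greedy agglomerative modularity maximization
#' (`igraph::cluster_fast_greedy`) on each network.
#'
#' @inheritParams lp_distance
#' @return Nonnegative scalar with attribute `partitions` (the two
#'   memberships).
#' @export
modularity_difference <- function(net1, net2) {
  nets <- .check_pair(net1, net2)
  qmod <- function(net) {
    g <- igraph::graph_from_adjacency_matrix(net$weights,
                                             mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    cm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
    list(Q = max(cm$modularity), membership = igraph::membership(cm))
  }
  a <- qmod(nets[[1]]); b <- qmod(nets[[2]])
  structure(abs(a$Q - b$Q),
            partitions = list(a$membership, b$membership))
}

#' Compute a named network distance
#'
#' Dispatch helper used by the permutation engine and the command line:
#' `"l1"`, `"l2"`, `"linf"`, `"gh"`, `"bottleneck0"`, `"bottleneck1"`,
#' `"ks0"`, `"ks1"`, `"qmod"`.
#'
#' @inheritParams lp_distance
#' @param method Distance name.
#' @return Nonnegative scalar distance value.
#' @export
network_distance <- function(net1, net2, method) {
  switch(method,
         l1 = lp_distance(net1, net2, 1),
         l2 = lp_distance(net1, net2, 2),
         linf = lp_distance(net1, net2, Inf),
         gh = gh_distance(net1, net2),
         bottleneck0 = bottleneck_distance_networks(net1, net2, 0),
         bottleneck1 = bottleneck_distance_networks(net1, net2, 1),
         ks0 = ks_statistic(net1, net2, 0)$D,
         ks1 = ks_statistic(net1, net2, 1)$D,
         qmod = as.numeric(modularity_difference(net1, net2)),
         stop(sprintf("unknown distance method '%s'", method)))
}
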