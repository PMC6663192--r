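## Betti numbers, Betti curves over filtrations, single-linkage structures
## and persistence diagrams of graph filtrations.

.edge_list <- function(weights) {
  ut <- which(upper.tri(weights) & weights > 0, arr.ind = TRUE)
  list(i = ut[, 1] - 1L, j = ut[, 2] - 1L,
       w = weights[cbind(ut[, 1], ut[, 2])])
}

## Betti profile of an arbitrary symmetric matrix over arbitrary query
## levels; entries <= 0 are never kept (strict thresholding). Internal core
## shared by betti_curves, ks_statistic and the twin pipeline.
.betti_profile <- function(weights, levels) {
  p <- nrow(weights)
  w <- weights
  w[is.na(w)] <- -Inf           # undefined edges treated as absent
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  prof <- .betti_profile_cpp(ut[, 1] - 1L, ut[, 2] - 1L,
                             w[cbind(ut[, 1], ut[, 2])], p,
                             as.numeric(levels))
  colnames(prof) <- c("beta0", "beta1", "edges")
  prof
}

#' Zeroth Betti number of a binary network
#'
#' The number of connected components; isolated nodes count.
#'
#' @param bin A `binary_network` from [threshold_network()] (or an
#'   adjacency matrix).
#' @return Integer in `[1, p]`.
#' @export
betti0 <- function(bin) {
  adj <- if (inherits(bin, "binary_network")) bin$adjacency else as.matrix(bin)
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$no
}

#' First Betti number of a binary network
#'
#' The number of independent cycles, from the Euler characteristic of a
#' graph: beta1 = beta0 - p + q for p nodes and q edges.
#'
#' @inheritParams betti0
#' @return Nonnegative integer.
#' @export
betti1 <- function(bin) {
  adj <- if (inherits(bin, "binary_network")) bin$adjacency else as.matrix(bin)
  p <- nrow(adj)
  q <- sum(adj != 0) / 2
  betti0(adj) - p + q
}

#' Betti curves over a graph filtration
#'
#' beta0 and beta1 evaluated at every filtration level. Over the graph
#' filtration, edges leave one at a time (up to ties), so beta0 is
#' nondecreasing and beta1 nonincreasing in the level, each changing by at
#' most one per deleted edge.
#'
#' @param net A [weighted_network()] (or weight matrix).
#' @param filt Optional [filtration_levels()] result; defaults to the
#'   network's own filtration.
#' @return Object of class `betti_curve`: list with `levels`, `beta0`,
#'   `beta1`, `edges` (edge counts) and `p`.
#' @export
betti_curves <- function(net, filt = NULL) {
  net <- .as_network(net)
  if (is.null(filt)) filt <- filtration_levels(net)
  prof <- .betti_profile(net$weights, filt$levels)
  structure(list(levels = filt$levels,
                 beta0 = prof[, "beta0"],
                 beta1 = prof[, "beta1"],
                 edges = prof[, "edges"],
                 p = length(net$labels)),
            class = "betti_curve")
}

#' @export
print.betti_curve <- function(x, ...) {
  cat(sprintf("Betti curves over %d levels: beta0 %d..%d, beta1 %d..%d\n",
              length(x$levels), min(x$beta0), max(x$beta0),
              max(x$beta1), min(x$beta1)))
  invisible(x)
}

#' @export
as.data.frame.betti_curve <- function(x, ...) {
  data.frame(level = x$levels, beta0 = x$beta0, beta1 = x$beta1,
             edges = x$edges)
}

.check_complete <- function(net) {
  w <- net$weights
  off <- w[upper.tri(w)]
  if (any(off <= 0))
    stop("complete weight matrix required: structural zeros present ",
         "(disconnected weighted graph)")
  invisible(net)
}

#' Single-linkage matrix of a complete weighted network
#'
#' Entry (i, j) is the single-linkage distance: the minimum over paths from
#' i to j of the maximum edge weight along the path, equivalently the level
#' at which the two nodes' components merge during single-linkage
#' clustering. The result is an ultrametric: s_ij <= max(s_ik, s_kj).
#'
#' @param net A [weighted_network()] with all off-diagonal weights positive.
#' @return Symmetric p x p matrix with zero diagonal.
#' @export
single_linkage_matrix <- function(net) {
  net <- .as_network(net)
  .check_complete(net)
  if (length(net$labels) == 1) return(net$weights)
  h <- stats::hclust(stats::as.dist(net$weights), method = "single")
  s <- as.matrix(stats::cophenetic(h))
  s[net$labels, net$labels, drop = FALSE]
}

#' Single-linkage dendrogram merge sequence
#'
#' The ordered merges of single-linkage clustering; over the graph
#' filtration run in the node-connecting direction, components merge in
#' exactly this sequence. A connected weighted network on p nodes yields
#' p - 1 merges at nondecreasing levels.
#'
#' @inheritParams single_linkage_matrix
#' @return Object of class `sl_dendrogram`: list of merges, each a list
#'   with `level`, `a` and `b` (label vectors of the merged clusters).
#' @export
sl_dendrogram <- function(net) {
  net <- .as_network(net)
  .check_complete(net)
  h <- stats::hclust(stats::as.dist(net$weights), method = "single")
  members <- vector("list", nrow(h$merge))
  merges <- vector("list", nrow(h$merge))
  for (k in seq_len(nrow(h$merge))) {
    a <- if (h$merge[k, 1] < 0) net$labels[-h$merge[k, 1]] else members[[h$merge[k, 1]]]
    b <- if (h$merge[k, 2] < 0) net$labels[-h$merge[k, 2]] else members[[h$merge[k, 2]]]
    members[[k]] <- c(a, b)
    merges[[k]] <- list(level = h$height[k], a = a, b = b)
  }
  structure(merges, class = "sl_dendrogram")
}

#' @export
print.sl_dendrogram <- function(x, ...) {
  cat(sprintf("Single-linkage dendrogram: %d merges at levels %s\n",
              length(x), paste(signif(vapply(x, function(m) m$level, numeric(1)), 4),
                               collapse = ", ")))
  invisible(x)
}

#' Persistence diagram of a graph filtration
#'
#' Recorded in the node-connecting direction (edges inserted by increasing
#' weight). Dimension 0: every node is born at 0; a component dies at each
#' single-linkage merge level, and one essential component never dies.
#' Dimension 1: a cycle is born at each edge whose endpoints are already
#' connected when it is inserted; a 1-skeleton has no 2-cells, so no cycle
#' ever dies. Essential (infinite) deaths are replaced by a finite
#' substitute, by default the maximum edge weight.
#'
#' @inheritParams single_linkage_matrix
#' @param dimension 0 or 1.
#' @param essential_death Finite death value for essential classes;
#'   defaults to the maximum edge weight.
#' @return Object of class `persistence_diagram`: list with `dimension`,
#'   `points` (m x 2 matrix of births/deaths), `essential` (logical vector)
#'   and `essential_death`.
#' @export
persistence_diagram <- function(net, dimension = 0, essential_death = NULL) {
  net <- .as_network(net)
  .check_complete(net)
  if (!dimension %in% c(0, 1)) stop("dimension must be 0 or 1")
  p <- length(net$labels)
  el <- .edge_list(net$weights)
  if (is.null(essential_death)) essential_death <- max(el$w)
  roles <- .edge_roles_cpp(el$i, el$j, el$w, p)
  if (dimension == 0) {
    deaths <- sort(el$w[roles == 1L])
    pts <- cbind(birth = rep(0, p), death = c(deaths, essential_death))
    ess <- c(rep(FALSE, p - 1), TRUE)
  } else {
    births <- sort(el$w[roles == 2L])
    pts <- cbind(birth = births,
                 death = rep(essential_death, length(births)))
    ess <- rep(TRUE, length(births))
  }
  structure(list(dimension = dimension, points = pts, essential = ess,
                 essential_death = essential_death),
            class = "persistence_diagram")
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("Persistence diagram (dimension %d): %d points, %d essential\n",
              x$dimension, nrow(x$points), sum(x$essential)))
  invisible(x)
}
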