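## Weighted networks, correlation-based edge weights, thresholding and
## filtration levels.

#' Construct a weighted network
#'
#' A weighted network is a node set together with a symmetric, nonnegative
#' edge-weight matrix with zero diagonal. Edge weights of exactly zero are
#' treated as absent edges.
#'
#' @param weights Square numeric matrix of edge weights (symmetric within
#'   tolerance, zero diagonal, nonnegative, finite).
#' @param labels Optional character vector of node labels; defaults to the
#'   matrix dimnames or `V1..Vp`.
#' @return An object of class `weighted_network` with elements `weights`
#'   (the validated matrix) and `labels`.
#' @examples
#' w <- matrix(0, 3, 3)
#' w[upper.tri(w)] <- c(0.2, 0.5, 0.9)
#' net <- weighted_network(w + t(w))
#' @export
weighted_network <- function(weights, labels = NULL) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  if (p != ncol(weights)) stop("weight matrix must be square")
  if (!all(is.finite(weights))) stop("weights must be finite")
  asym <- abs(weights - t(weights))
  if (max(asym) > .tol) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("weight matrix not symmetric: worst entry (%d, %d)",
                 ij[1], ij[2]))
  }
  if (max(abs(diag(weights))) > .tol) stop("diagonal must be zero")
  if (min(weights) < -.tol) stop("weights must be nonnegative")
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  weights[weights < 0] <- 0
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(weights))) rownames(weights)
              else paste0("V", seq_len(p))
  }
  if (length(labels) != p) stop("labels length must match node count")
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  cat(sprintf("Weighted network: %d nodes, %d positive edges (max weight %.4g)\n",
              length(x$labels), sum(w > 0), if (length(w)) max(w) else 0))
  invisible(x)
}

.as_network <- function(x) {
  if (inherits(x, "weighted_network")) x else weighted_network(x)
}

#' Pearson correlation matrix of a node-measurement matrix
#'
#' Columns are nodes, rows are samples. Equivalent to centering and
#' unit-norm scaling each column and taking inner products.
#'
#' @param data Numeric matrix (n samples x p nodes), n >= 2.
#' @return p x p correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("at least 2 samples are required")
  if (!all(is.finite(data))) stop("data must be finite")
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(data)[which(sds == 0)[1]]
    if (is.null(bad)) bad <- paste0("column ", which(sds == 0)[1])
    stop(sprintf("constant column: %s has zero variance", bad))
  }
  r <- stats::cor(data)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

.check_corr <- function(corr) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr)) stop("correlation matrix must be square")
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix not symmetric")
  if (max(abs(corr)) > 1 + 1e-8) stop("correlation entries must lie in [-1, 1]")
  if (max(abs(diag(corr) - 1)) > 1e-8) stop("correlation diagonal must be 1")
  corr
}

#' Metric edge weights from correlations
#'
#' Maps correlation rho to the weight sqrt(1 - rho), which satisfies the
#' triangle inequality (and all metric axioms) on the node set, taking
#' values in `[0, sqrt(2)]`.
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @return A [weighted_network()].
#' @export
metric_weights <- function(corr) {
  corr <- .check_corr(corr)
  w <- sqrt(pmax(1 - corr, 0))
  diag(w) <- 0
  weighted_network(w, labels = rownames(corr))
}

#' One-minus-correlation edge weights
#'
#' Maps correlation rho to the weight 1 - rho (clipped at zero only for
#' rho exceeding 1 by numerical tolerance). A strictly decreasing function
#' of rho, so it ranks edges identically to [metric_weights()].
#'
#' @inheritParams metric_weights
#' @return A [weighted_network()].
#' @export
one_minus_weights <- function(corr) {
  corr <- .check_corr(corr)
  w <- pmax(1 - corr, 0)
  diag(w) <- 0
  weighted_network(w, labels = rownames(corr))
}

.weight_transform <- function(name = c("metric", "oneminus")) {
  switch(match.arg(name), metric = metric_weights, oneminus = one_minus_weights)
}

#' Threshold a weighted network into a binary network
#'
#' An edge is kept if and only if its weight is strictly greater than the
#' filtration level `eps`; edges equal to the level are removed. At
#' `eps = 0` a positively weighted complete network stays complete; at or
#' beyond the maximum weight only the node set remains.
#'
#' @param net A [weighted_network()] (or a weight matrix).
#' @param eps Filtration level, >= 0.
#' @return An object of class `binary_network` with elements `adjacency`,
#'   `labels` and `level`.
#' @export
threshold_network <- function(net, eps) {
  net <- .as_network(net)
  if (!is.numeric(eps) || length(eps) != 1 || eps < 0)
    stop("eps must be a single nonnegative number")
  adj <- (net$weights > eps) * 1L
  diag(adj) <- 0L
  structure(list(adjacency = adj, labels = net$labels, level = eps),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("Binary network at level %.4g: %d nodes, %d edges\n",
              x$level, length(x$labels), sum(x$adjacency) / 2))
  invisible(x)
}

#' Filtration levels of a weighted network
#'
#' The sorted unique positive edge weights, preceded by zero. Tied edge
#' weights collapse to one level (all tied edges enter or leave together).
#' Thresholding at these levels produces every distinct binary network of
#' the graph filtration: q + 1 of them for q unique positive weights.
#'
#' @param net A [weighted_network()] (or a weight matrix).
#' @return An object of class `filtration`: list with `levels`
#'   (`c(0, w_(1), ..., w_(q))`) and `q`.
#' @export
filtration_levels <- function(net) {
  net <- .as_network(net)
  w <- net$weights[upper.tri(net$weights)]
  w <- sort(unique(w[w > 0]))
  if (length(w) == 0) stop("network has no positive edge weight")
  structure(list(levels = c(0, w), q = length(w)), class = "filtration")
}

#' @export
print.filtration <- function(x, ...) {
  cat(sprintf("Graph filtration: q = %d unique positive weights in [%.4g, %.4g]\n",
              x$q, x$levels[2], x$levels[x$q + 1]))
  invisible(x)
}
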