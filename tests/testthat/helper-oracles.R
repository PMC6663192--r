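# Independent oracles and fixture builders, deliberately naive: brute-force
# enumeration and textbook algorithms against which the package's fast
# paths are checked.

# Complete weighted network with distinct positive weights.
rand_network <- function(p, seed) {
  set.seed(seed)
  w <- matrix(0, p, p)
  vals <- sample(seq_len(p * (p - 1) / 2)) / (p * (p - 1) / 2)
  w[upper.tri(w)] <- vals
  weighted_network(w + t(w))
}

# Random spanning tree with distinct weights.
rand_tree <- function(p, seed) {
  set.seed(seed)
  w <- matrix(0, p, p)
  for (v in 2:p) {
    u <- sample(v - 1, 1)
    w[u, v] <- w[v, u] <- v - 1 + stats::runif(1)
  }
  weighted_network(w)
}

# Connected-component count by breadth-first flood fill.
bfs_components <- function(adj) {
  p <- nrow(adj)
  visited <- rep(FALSE, p)
  comps <- 0
  for (s in seq_len(p)) {
    if (visited[s]) next
    comps <- comps + 1
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(adj[u, ] != 0 & !visited)
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comps
}

# Naive per-level Betti numbers: threshold from scratch at each level.
naive_betti <- function(weights, levels) {
  p <- nrow(weights)
  t(vapply(levels, function(eps) {
    adj <- (weights > eps) & upper.tri(weights)
    adj <- adj | t(adj)
    b0 <- bfs_components(adj)
    q <- sum(adj) / 2
    c(beta0 = b0, beta1 = b0 - p + q)
  }, c(beta0 = 0, beta1 = 0)))
}

# Minimax path weight by exhaustive enumeration of simple paths (p <= 8).
brute_minimax <- function(weights) {
  p <- nrow(weights)
  best <- matrix(Inf, p, p)
  diag(best) <- 0
  extend <- function(path, maxw) {
    u <- path[length(path)]
    s <- path[1]
    if (maxw < best[s, u]) best[s, u] <<- best[u, s] <<- maxw
    for (v in setdiff(seq_len(p), path))
      if (weights[u, v] > 0) extend(c(path, v), max(maxw, weights[u, v]))
  }
  for (s in seq_len(p - 1)) extend(s, 0)
  best
}

# All monotone lattice paths (0,0) -> (q,q); returns each path's max |u - v|.
lattice_path_gaps <- function(q) {
  steps_up <- utils::combn(2 * q, q)
  apply(steps_up, 2, function(up) {
    du <- rep(0L, 2 * q)
    du[up] <- 1L
    u <- cumsum(du)
    v <- seq_len(2 * q) - u
    max(abs(u - v))
  })
}

# All set partitions of 1..n (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, kmax) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return()
    }
    for (g in seq_len(kmax + 1)) rec(c(assign, g), max(kmax, g))
  }
  rec(integer(0), 0)
  out
}

# Weighted Newman modularity of a membership vector, from the definition.
manual_modularity <- function(weights, membership) {
  W <- sum(weights) / 2
  k <- rowSums(weights)
  total <- 0
  p <- nrow(weights)
  for (i in seq_len(p))
    for (j in seq_len(p))
      if (membership[i] == membership[j])
        total <- total + weights[i, j] - k[i] * k[j] / (2 * W)
  total / (2 * W)
}

# Bottleneck distance by exhaustive enumeration of bijections between the
# diagonally augmented point sets (small diagrams only).
brute_bottleneck <- function(pts1, pts2) {
  m <- nrow(pts1); n <- nrow(pts2)
  proj <- function(pts) {
    mid <- (pts[, 1] + pts[, 2]) / 2
    cbind(mid, mid)
  }
  a <- rbind(pts1, proj(pts2))
  b <- rbind(pts2, proj(pts1))
  N <- m + n
  cost <- matrix(0, N, N)
  for (i in seq_len(N))
    cost[i, ] <- pmax(abs(a[i, 1] - b[, 1]), abs(a[i, 2] - b[, 2]))
  if (m < N && n < N) cost[(m + 1):N, (n + 1):N] <- 0
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(rest) c(v[i], rest))), recursive = FALSE)
  }
  min(vapply(perms(seq_len(N)), function(sigma)
    max(cost[cbind(seq_len(N), sigma)]), numeric(1)))
}

# Assemble a weighted network from an explicit edge list.
edges_network <- function(p, edges, labels = NULL) {
  w <- matrix(0, p, p)
  for (e in edges) w[e[[1]], e[[2]]] <- w[e[[2]], e[[1]]] <- e[[3]]
  if (!is.null(labels)) dimnames(w) <- list(labels, labels)
  weighted_network(w)
}
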