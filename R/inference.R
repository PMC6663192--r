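## Exact combinatorial null distribution of the KS statistic on Betti
## curves, its asymptotic series, the combined two-sample KS test, and a
## generic two-sample permutation engine.

#' Band-restricted lattice-path count table
#'
#' The recursion A(u,v) = A(u-1,v) + A(u,v-1) inside the band |u - v| < d,
#' with A(0,0) = 0, boundary cells equal to 1 on the in-band axes, and 0
#' outside the band. The corner A(q,q) counts the monotone lattice paths
#' from (0,0) to (q,q) whose maximum gap |u - v| stays below d.
#'
#' Values are returned as doubles; for large q where the counts exceed
#' double precision use [exact_tail_probability()], which carries the same
#' recursion in exact big-integer arithmetic.
#'
#' @param q Path length (number of filtration levels per network), >= 1.
#' @param d Band width parameter, >= 1.
#' @return `(q+1) x (q+1)` numeric matrix, rows/cols indexed 0..q.
#' @export
lattice_count_table <- function(q, d) {
  stopifnot(q >= 1, d >= 1)
  A <- matrix(0, q + 1, q + 1)
  for (v in 1:q) if (v < d) A[1, v + 1] <- 1
  for (u in 1:q) {
    if (u < d) A[u + 1, 1] <- 1
    for (v in 1:q) {
      if (abs(u - v) < d) A[u + 1, v + 1] <- A[u, v + 1] + A[u + 1, v]
    }
  }
  dimnames(A) <- list(0:q, 0:q)
  A
}

#' Exact tail probability of the KS statistic under the null
#'
#' `P(D_q >= d) = 1 - A(q,q) / C(2q, q)`, where A(q,q) counts the monotone
#' lattice paths staying strictly inside the band |u - v| < d. Both the
#' path count and the central binomial coefficient are computed in exact
#' big-integer arithmetic (no overflow for q up to at least 10^4), and the
#' probability is the exact ratio converted to double.
#'
#' @param q Number of filtration levels per network, >= 1.
#' @param d Integer threshold for the statistic; non-integer values are an
#'   error (discretize first, see [ks_test()]).
#' @return Probability in `[0, 1]`; 1 for d <= 1 (every nontrivial path
#'   attains gap 1), 0 for d > q.
#' @export
exact_tail_probability <- function(q, d) {
  if (!is.numeric(q) || length(q) != 1 || q < 1 || q != round(q))
    stop("q must be a positive integer")
  if (!is.numeric(d) || length(d) != 1 || abs(d - round(d)) > 0)
    stop("d must be an integer; discretize the statistic first")
  .exact_tail_cpp(as.integer(q), as.integer(round(d)))
}

#' Asymptotic tail probability of the KS statistic
#'
#' The large-q limit `p = 2 * sum_{i>=1} (-1)^(i-1) exp(-2 i^2 d^2)` with
#' the normalized statistic `d = D_q / sqrt(2q)`, summed until terms fall
#' below 1e-16 and clamped to `[0, 1]`. Returns 1 for a (numerically) zero
#' statistic.
#'
#' @param D Observed statistic (maximum Betti gap), >= 0.
#' @param q Number of filtration levels per network, >= 1.
#' @param ceiling_mode If `TRUE`, use the least integer greater than the
#'   normalized statistic instead of its raw value.
#' @return Probability in `[0, 1]`.
#' @export
asymptotic_pvalue <- function(D, q, ceiling_mode = FALSE) {
  stopifnot(q >= 1, D >= 0)
  d <- D / sqrt(2 * q)
  if (ceiling_mode) d <- floor(d) + 1
  if (d <= 1e-3) return(1)
  p <- 0
  i <- 1
  repeat {
    term <- 2 * (-1)^(i - 1) * exp(-2 * i^2 * d^2)
    p <- p + term
    if (abs(term) < 1e-16 || i > 10000) break
    i <- i + 1
  }
  min(max(p, 0), 1)
}

#' Two-sample KS test on Betti curves
#'
#' Computes the KS statistic over the union filtration grid and both the
#' exact combinatorial p-value (Theorem-3 lattice counting; skipped when q
#' exceeds `exact_q_budget`) and the asymptotic series p-value. The number
#' of filtration levels q is the number of positive levels in the grid.
#' The test is invariant under any common strictly increasing transform of
#' the edge weights.
#'
#' @inheritParams ks_statistic
#' @param exact_q_budget Largest q for which the exact big-integer
#'   computation is attempted.
#' @param ceiling_mode Passed to [asymptotic_pvalue()].
#' @return Object of class `ks_test`: list with `D`, `q`, `p_exact` (may be
#'   `NA`), `p_asymptotic`, `p_value` (exact when available), `d_o`
#'   (normalized statistic) and `dimension`.
#' @export
ks_test <- function(net1, net2, dimension = 1, grid = NULL,
                    exact_q_budget = 1000, ceiling_mode = FALSE) {
  ks <- ks_statistic(net1, net2, dimension, grid)
  q <- sum(ks$grid > 0)
  if (q < 1) stop("filtration grid has no positive level")
  p_exact <- if (q <= exact_q_budget)
    exact_tail_probability(q, ks$D) else NA_real_
  p_asym <- asymptotic_pvalue(ks$D, q, ceiling_mode)
  structure(list(D = ks$D, q = q, p_exact = p_exact,
                 p_asymptotic = p_asym,
                 p_value = if (is.na(p_exact)) p_asym else p_exact,
                 d_o = ks$D / sqrt(2 * q), dimension = dimension,
                 statistic = ks),
            class = "ks_test")
}

#' @export
print.ks_test <- function(x, ...) {
  cat(sprintf("KS test (beta%d): D = %d, q = %d, p_exact = %s, p_asymptotic = %.4g\n",
              x$dimension, x$D, x$q,
              if (is.na(x$p_exact)) "NA" else sprintf("%.4g", x$p_exact),
              x$p_asymptotic))
  invisible(x)
}

#' Two-sample permutation test on a network distance
#'
#' Rows of the two data matrices are pooled and reassigned to groups; each
#' reassignment rebuilds both correlation networks with the chosen weight
#' transform and recomputes the distance. When the number of distinct
#' group assignments `C(m+n, m)` is at most `max_exact` they are all
#' enumerated (an exact test); otherwise `n_perm` assignments are sampled
#' uniformly. The p-value is the fraction of permuted distances greater
#' than or equal to the observed one.
#'
#' @param data1,data2 Numeric sample-by-node matrices with the same node
#'   count (m x p and n x p, m and n >= 2).
#' @param method Distance name, see [network_distance()].
#' @param weight_transform `"metric"` for sqrt(1 - correlation) weights or
#'   `"oneminus"` for 1 - correlation.
#' @param max_exact Enumeration threshold on `C(m+n, m)`.
#' @param n_perm Number of sampled assignments in the Monte-Carlo regime.
#' @param seed Optional integer seed for the Monte-Carlo regime.
#' @return Object of class `permutation_test`: list with `observed`,
#'   `p_value`, `n_evaluated`, `exact`, `method` and `seed`.
#' @export
permutation_test <- function(data1, data2, method = "gh",
                             weight_transform = c("metric", "oneminus"),
                             max_exact = 10000, n_perm = 1000, seed = NULL) {
  data1 <- as.matrix(data1); data2 <- as.matrix(data2)
  if (ncol(data1) != ncol(data2)) stop("node counts differ between groups")
  if (nrow(data1) < 2 || nrow(data2) < 2) stop("need at least 2 samples per group")
  transform <- .weight_transform(match.arg(weight_transform))
  build <- function(x) transform(correlation_matrix(x))
  dist_fun <- function(g1, g2) network_distance(build(g1), build(g2), method)

  m <- nrow(data1); n <- nrow(data2)
  pooled <- rbind(data1, data2)
  observed <- dist_fun(data1, data2)

  n_total <- choose(m + n, m)
  exact <- n_total <= max_exact
  if (exact) {
    assignments <- utils::combn(m + n, m)
  } else {
    if (!is.null(seed)) set.seed(seed)
    assignments <- replicate(n_perm, sample.int(m + n, m))
  }
  d_perm <- apply(assignments, 2, function(idx)
    dist_fun(pooled[idx, , drop = FALSE], pooled[-idx, , drop = FALSE]))
  structure(list(observed = observed,
                 p_value = mean(d_perm >= observed),
                 n_evaluated = ncol(assignments), exact = exact,
                 method = method, seed = seed, null_distances = d_perm),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s): observed = %.4g, p = %.4g (%s, %d assignments)\n",
              x$method, x$observed, x$p_value,
              if (x$exact) "exact enumeration" else "Monte-Carlo",
              x$n_evaluated))
  invisible(x)
}
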