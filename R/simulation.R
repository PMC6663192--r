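## Modular correlation-network simulation benchmark: null and
## block-dependent data generators and the false-positive/false-negative
## rate experiment.

#' Simulate a null (independent) node-measurement matrix
#'
#' Each node's measurement vector is an independent standard normal
#' n-vector, so the population correlation between any two nodes is zero.
#'
#' @param p Number of nodes, >= 2.
#' @param n Number of samples, >= 2.
#' @param seed Optional integer seed.
#' @return n x p numeric matrix with columns `V1..Vp`.
#' @export
simulate_null_group <- function(p, n, seed = NULL) {
  stopifnot(p >= 2, n >= 2)
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p)
  colnames(x) <- paste0("V", seq_len(p))
  x
}

#' Simulate a modular (block-dependent) node-measurement matrix
#'
#' Hierarchical linear model: the p nodes are split into k equal blocks of
#' size c = p/k; every node in a block equals that block's anchor column of
#' `base` plus fresh independent N(0, sigma^2) noise. Within-block
#' population correlation is 1/(1 + sigma^2); between-block correlations
#' are zero.
#'
#' @param base n x p matrix of anchor data (e.g. from
#'   [simulate_null_group()]).
#' @param k Number of modules; must divide p.
#' @param sigma Noise standard deviation, >= 0.
#' @param seed Optional integer seed.
#' @return n x p numeric matrix.
#' @export
simulate_modular_group <- function(base, k, sigma = 0.1, seed = NULL) {
  base <- as.matrix(base)
  p <- ncol(base); n <- nrow(base)
  if (p %% k != 0) stop(sprintf("k = %d does not divide p = %d", k, p))
  if (sigma < 0) stop("sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  csize <- p %/% k
  anchors <- rep(seq(1, p, by = csize), each = csize)
  y <- base[, anchors, drop = FALSE] +
    matrix(stats::rnorm(n * p, sd = sigma), n, p)
  colnames(y) <- paste0("V", seq_len(p))
  y
}

#' Simulation benchmark configuration
#'
#' @param p Number of nodes.
#' @param n Samples per group (the benchmark uses 5).
#' @param sigma Within-block noise standard deviation (the benchmark uses
#'   0.1).
#' @param n_reps Number of replicates per comparison.
#' @param alpha Significance level.
#' @param distances Character vector of distance names (see
#'   [network_distance()]); `"ks0"`/`"ks1"` use the exact/asymptotic KS
#'   null, all others the permutation test.
#' @param weight_transform `"metric"` (sqrt(1 - correlation), the default)
#'   or `"oneminus"`; the KS and GH results are invariant to this choice.
#' @param seed Integer seed for the whole experiment.
#' @param exact_q_budget Passed to [ks_test()].
#' @param max_exact,n_perm Passed to [permutation_test()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(p = 20, n = 5, sigma = 0.1, n_reps = 100,
                       alpha = 0.05, distances = c("ks0", "ks1"),
                       weight_transform = c("metric", "oneminus"),
                       seed = 1, exact_q_budget = 1000,
                       max_exact = 500, n_perm = 500) {
  stopifnot(p >= 2, n >= 2, sigma >= 0, n_reps >= 1)
  structure(list(p = p, n = n, sigma = sigma, n_reps = n_reps,
                 alpha = alpha, distances = distances,
                 weight_transform = match.arg(weight_transform),
                 seed = seed, exact_q_budget = exact_q_budget,
                 max_exact = max_exact, n_perm = n_perm),
            class = "sim_config")
}

#' Rejection-rate experiment over modular-network comparisons
#'
#' For each comparison (k1, k2) and each replicate, draws a k1-group and a
#' k2-group (same-k null pairs share the anchor data; different-k pairs use
#' independent anchors), builds each group's correlation network from its n
#' samples, and tests each configured distance. KS distances use the
#' combinatorial/asymptotic null; other distances use the permutation test
#' with full enumeration when feasible. Same-k rows report the false
#' positive rate (fraction of replicates with p < alpha); different-k rows
#' report the false negative rate (fraction with p > alpha).
#'
#' @param cfg A [sim_config()].
#' @param comparisons List of length-2 vectors `c(k1, k2)`; each k must
#'   divide `cfg$p`.
#' @return Data frame of class `rate_table` with one row per comparison
#'   (`comparison`, `type`, then one column per distance), and attributes
#'   `n_reps`, `alpha`, `seed`.
#' @export
rejection_rate_experiment <- function(cfg, comparisons) {
  stopifnot(inherits(cfg, "sim_config"))
  transform <- .weight_transform(cfg$weight_transform)
  set.seed(cfg$seed)
  rows <- lapply(comparisons, function(ks) {
    k1 <- ks[1]; k2 <- ks[2]
    null_case <- k1 == k2
    hits <- matrix(NA_real_, cfg$n_reps, length(cfg$distances),
                   dimnames = list(NULL, cfg$distances))
    for (r in seq_len(cfg$n_reps)) {
      base1 <- simulate_null_group(cfg$p, cfg$n)
      g1 <- simulate_modular_group(base1, k1, cfg$sigma)
      base2 <- if (null_case) base1 else simulate_null_group(cfg$p, cfg$n)
      g2 <- simulate_modular_group(base2, k2, cfg$sigma)
      net1 <- transform(correlation_matrix(g1))
      net2 <- transform(correlation_matrix(g2))
      for (m in cfg$distances) {
        pval <- if (m %in% c("ks0", "ks1")) {
          ks_test(net1, net2, dimension = as.integer(substring(m, 3)),
                  exact_q_budget = cfg$exact_q_budget)$p_value
        } else {
          permutation_test(g1, g2, method = m,
                           weight_transform = cfg$weight_transform,
                           max_exact = cfg$max_exact,
                           n_perm = cfg$n_perm)$p_value
        }
        hits[r, m] <- pval
      }
    }
    rates <- if (null_case) colMeans(hits < cfg$alpha)
             else colMeans(hits > cfg$alpha)
    c(list(comparison = sprintf("%d vs. %d", k1, k2),
           type = if (null_case) "false_positive" else "false_negative"),
      as.list(rates))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  attr(out, "n_reps") <- cfg$n_reps
  attr(out, "alpha") <- cfg$alpha
  attr(out, "seed") <- cfg$seed
  class(out) <- c("rate_table", class(out))
  out
}
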