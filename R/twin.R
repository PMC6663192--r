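## Twin-heritability pipeline: cosine-series representation of parcel time
## series, subject connectivity, edgewise twin correlations, Falconer
## heritability, KS inference between twin groups, and a synthetic ACE
## cohort generator.

#' Cosine-series representation of parcel time series
#'
#' Each parcel's series is placed on the unit interval, its temporal mean
#' removed, and expanded in the cosine basis psi_0(t) = 1,
#' psi_l(t) = sqrt(2) cos(l pi t) (orthonormal on `[0, 1]`) by least
#' squares. The coefficient vectors compress and denoise the series; with
#' k = 119 the representation has 120 spectral features per parcel.
#'
#' @param ts p x T numeric matrix (parcels by timepoints), T > k + 1.
#' @param k Expansion order (default 119).
#' @param basis_scale Scale of the non-constant basis functions;
#'   `sqrt(2)` (orthonormal, default) or 2.
#' @return Object of class `cosine_coefficients`: list with `coeffs`
#'   (p x (k+1) matrix) and `k`.
#' @export
cosine_representation <- function(ts, k = 119, basis_scale = sqrt(2)) {
  ts <- as.matrix(ts)
  T_ <- ncol(ts)
  if (T_ < k + 1)
    stop(sprintf("T = %d timepoints cannot support order k = %d (need T >= k+1)",
                 T_, k))
  if (!all(is.finite(ts))) stop("time series must be finite")
  t01 <- seq(0, 1, length.out = T_)
  B <- cbind(1, vapply(seq_len(k),
                       function(l) basis_scale * cos(l * pi * t01),
                       numeric(T_)))
  centered <- ts - rowMeans(ts)
  fit <- stats::lm.fit(B, t(centered))
  coeffs <- t(fit$coefficients)
  dimnames(coeffs) <- list(rownames(ts), paste0("c", 0:k))
  structure(list(coeffs = coeffs, k = k), class = "cosine_coefficients")
}

#' Subject connectivity from cosine coefficients
#'
#' Pearson correlation between the coefficient vectors of every pair of
#' parcels: the subject-level connectivity matrix.
#'
#' @param coeffs A `cosine_coefficients` object or a p x f feature matrix.
#' @return p x p correlation matrix (symmetric, unit diagonal).
#' @export
subject_connectivity <- function(coeffs) {
  m <- if (inherits(coeffs, "cosine_coefficients")) coeffs$coeffs
       else as.matrix(coeffs)
  if (ncol(m) < 2) stop("need at least 2 features per parcel")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    lab <- rownames(m)[bad]
    stop(sprintf("parcel %s has zero-variance coefficients",
                 if (is.null(lab)) bad else lab))
  }
  C <- stats::cor(t(m))
  diag(C) <- 1
  C
}

#' Edgewise twin correlation of a group of connectivity pairs
#'
#' Entry (i, j) is the Pearson correlation, across twin pairs, between
#' twin A's and twin B's connectivity at edge (i, j); the cross-correlation
#' matrix is then symmetrized as (M + t(M))/2 since twin order carries no
#' information. Edges with zero variance across pairs in either twin are
#' reported as `NA` (count in attribute `n_undefined`), never silently
#' zeroed.
#'
#' @param pairs List of >= 3 twin pairs, each a list with elements `A` and
#'   `B` (p x p connectivity matrices).
#' @return p x p symmetric matrix of edgewise twin correlations (diagonal
#'   `NA`-free, set to 1).
#' @export
twin_group_correlation <- function(pairs) {
  if (length(pairs) < 3) stop("need at least 3 twin pairs")
  p <- nrow(pairs[[1]]$A)
  a <- vapply(pairs, function(pr) as.numeric(pr$A), numeric(p * p))
  b <- vapply(pairs, function(pr) as.numeric(pr$B), numeric(p * p))
  M <- matrix(NA_real_, p, p)
  sda <- apply(a, 1, stats::sd)
  sdb <- apply(b, 1, stats::sd)
  ok <- sda > 0 & sdb > 0
  M[ok] <- vapply(which(ok), function(e) stats::cor(a[e, ], b[e, ]),
                  numeric(1))
  M <- matrix(M, p, p)
  S <- (M + t(M)) / 2
  diag(S) <- 1
  attr(S, "n_undefined") <- sum(is.na(S[upper.tri(S)]))
  S
}

#' Falconer heritability index
#'
#' `HI = 2 * (C_MZ - C_DZ)` entrywise: under the ACE decomposition the MZ
#' twin correlation is A + C and the DZ correlation A/2 + C, so twice the
#' difference recovers the additive genetic share A. Raw values are
#' returned (sampling noise can push them below 0 or above 1); thresholded
#' display is a reporting choice, not a data mutation.
#'
#' @param c_mz,c_dz Symmetric group twin-correlation matrices of equal
#'   shape.
#' @return Matrix of the same shape.
#' @export
falconer_heritability <- function(c_mz, c_dz) {
  c_mz <- as.matrix(c_mz); c_dz <- as.matrix(c_dz)
  if (!all(dim(c_mz) == dim(c_dz))) stop("matrix shapes differ")
  2 * (c_mz - c_dz)
}

#' Synthetic ACE twin-cohort configuration
#'
#' @param p Number of network nodes.
#' @param a2 Additive-genetic variance proportion (A).
#' @param c2 Common-environment variance proportion (C); the unique
#'   environment share is e2 = 1 - a2 - c2.
#' @param n_mz,n_dz Numbers of MZ and DZ twin pairs.
#' @param edge_mean,edge_sd Affine map from the latent standard-normal
#'   edge scores to the connectivity scale; defaults keep essentially all
#'   entries inside `[-1, 1]` (values are clipped at the boundary).
#' @param seed Optional integer seed.
#' @return List of class `ace_config`.
#' @export
ace_config <- function(p = 20, a2 = 0.6, c2 = 0.2, n_mz = 100, n_dz = 60,
                       edge_mean = 0.3, edge_sd = 0.15, seed = NULL) {
  if (a2 < 0 || c2 < 0 || a2 + c2 > 1 + 1e-12)
    stop("need a2 >= 0, c2 >= 0, a2 + c2 <= 1")
  structure(list(p = p, a2 = a2, c2 = c2, e2 = 1 - a2 - c2, n_mz = n_mz,
                 n_dz = n_dz, edge_mean = edge_mean, edge_sd = edge_sd,
                 seed = seed),
            class = "ace_config")
}

#' Simulate a synthetic ACE twin cohort
#'
#' The ACE decomposition is applied directly to each connectivity edge:
#' the latent edge score of a twin is sqrt(a2) g + sqrt(c2) h + sqrt(e2) e,
#' where the genetic component g is identical across MZ co-twins and
#' correlates exactly 0.5 across DZ co-twins (shared and independent
#' halves of its variance), the common-environment component h is shared
#' within every pair, and e is unique. Edgewise twin correlations are
#' therefore exactly A + C = a2 + c2 in the MZ group and A/2 + C =
#' a2/2 + c2 in the DZ group, matching the Falconer identities. Latent
#' scores are mapped affinely to the correlation scale (see
#' [ace_config()]).
#'
#' @param cfg An [ace_config()].
#' @return Object of class `twin_cohort`: list with `mz_pairs` and
#'   `dz_pairs` (lists of `list(A =, B =)` connectivity matrices) and the
#'   generating `config`.
#' @export
simulate_twin_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "ace_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  p <- cfg$p
  ne <- p * (p - 1) / 2
  to_matrix <- function(z) {
    c_ij <- pmin(pmax(cfg$edge_mean + cfg$edge_sd * z, -1), 1)
    m <- matrix(0, p, p)
    m[upper.tri(m)] <- c_ij
    m <- m + t(m)
    diag(m) <- 1
    dimnames(m) <- list(paste0("V", 1:p), paste0("V", 1:p))
    m
  }
  draw_pair <- function(genetic_corr) {
    h <- stats::rnorm(ne)
    if (genetic_corr == 1) {
      g_a <- g_b <- stats::rnorm(ne)
    } else {  # corr 0.5: shared plus independent halves of the variance
      s <- stats::rnorm(ne)
      g_a <- (s + stats::rnorm(ne)) / sqrt(2)
      g_b <- (s + stats::rnorm(ne)) / sqrt(2)
    }
    z_a <- sqrt(cfg$a2) * g_a + sqrt(cfg$c2) * h + sqrt(cfg$e2) * stats::rnorm(ne)
    z_b <- sqrt(cfg$a2) * g_b + sqrt(cfg$c2) * h + sqrt(cfg$e2) * stats::rnorm(ne)
    list(A = to_matrix(z_a), B = to_matrix(z_b))
  }
  structure(list(mz_pairs = lapply(seq_len(cfg$n_mz),
                                   function(i) draw_pair(1)),
                 dz_pairs = lapply(seq_len(cfg$n_dz),
                                   function(i) draw_pair(0.5)),
                 config = cfg),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ACE twin cohort: %d MZ and %d DZ pairs, %d nodes (a2 = %.2f, c2 = %.2f)\n",
              length(x$mz_pairs), length(x$dz_pairs), x$config$p,
              x$config$a2, x$config$c2))
  invisible(x)
}

#' KS inference between MZ and DZ group correlation matrices
#'
#' Builds graph filtrations directly on the two twin-correlation matrices
#' (entries kept when strictly greater than the level; negative entries
#' are never kept), evaluates both Betti curves on a common grid (default:
#' 101 levels from 0 to 1 in steps of 0.01), and tests the maximum
#' per-level Betti gap with the combinatorial/asymptotic KS null, with q
#' bound to the number of positive grid levels. The KS statistic is
#' invariant under common monotone transforms of the entries, so the
#' filtration can run on correlations without converting them to metric
#' weights. Undefined (`NA`) edges are treated as absent and counted.
#'
#' @param c_mz,c_dz Symmetric group twin-correlation matrices.
#' @param grid Filtration levels (default `seq(0, 1, 0.01)`).
#' @param exact_q_budget Passed to [ks_test()] machinery.
#' @return Object of class `heritability_result`: list with `C_MZ`,
#'   `C_DZ`, `HI`, `betti_mz`, `betti_dz` (data frames over the grid),
#'   `ks0`, `ks1`, `n_undefined`.
#' @export
twin_ks_inference <- function(c_mz, c_dz, grid = seq(0, 1, by = 0.01),
                              exact_q_budget = 1000) {
  c_mz <- as.matrix(c_mz); c_dz <- as.matrix(c_dz)
  if (!all(dim(c_mz) == dim(c_dz))) stop("matrix shapes differ")
  if (length(grid) == 0) stop("filtration grid is empty")
  grid <- sort(unique(as.numeric(grid)))
  p <- nrow(c_mz)
  prof_mz <- .betti_profile(c_mz, grid)
  prof_dz <- .betti_profile(c_dz, grid)
  q <- sum(grid > 0)
  one_test <- function(dim) {
    col <- if (dim == 0) "beta0" else "beta1"
    D <- max(abs(prof_mz[, col] - prof_dz[, col]))
    p_exact <- if (q <= exact_q_budget) exact_tail_probability(q, D)
               else NA_real_
    p_asym <- asymptotic_pvalue(D, q)
    structure(list(D = D, q = q, p_exact = p_exact, p_asymptotic = p_asym,
                   p_value = if (is.na(p_exact)) p_asym else p_exact,
                   d_o = D / sqrt(2 * q), dimension = dim),
              class = "ks_test")
  }
  n_undef <- sum(is.na(c_mz[upper.tri(c_mz)])) +
    sum(is.na(c_dz[upper.tri(c_dz)]))
  structure(list(C_MZ = c_mz, C_DZ = c_dz,
                 HI = falconer_heritability(c_mz, c_dz),
                 betti_mz = data.frame(level = grid,
                                       beta0 = prof_mz[, "beta0"],
                                       beta1 = prof_mz[, "beta1"]),
                 betti_dz = data.frame(level = grid,
                                       beta0 = prof_dz[, "beta0"],
                                       beta1 = prof_dz[, "beta1"]),
                 ks0 = one_test(0), ks1 = one_test(1),
                 n_undefined = n_undef, p = p),
            class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat(sprintf("Twin KS inference on %d nodes (%d undefined edges)\n",
              x$p, x$n_undefined))
  cat(sprintf("  beta0: D = %d, p = %.3g\n", x$ks0$D, x$ks0$p_value))
  cat(sprintf("  beta1: D = %d, p = %.3g\n", x$ks1$D, x$ks1$p_value))
  cat(sprintf("  mean edgewise HI = %.3f\n",
              mean(x$HI[upper.tri(x$HI)], na.rm = TRUE)))
  invisible(x)
}
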