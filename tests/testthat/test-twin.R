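test_that("cosine representation recovers basis signals exactly", {
  T_ <- 80
  t01 <- seq(0, 1, length.out = T_)
  # constant signal: everything vanishes after mean removal
  cst <- cosine_representation(matrix(5, 2, T_), k = 6)
  expect_lt(max(abs(cst$coeffs)), 1e-10)
  # a pure first basis function comes back as c1 = 1
  sig <- rbind(sqrt(2) * cos(pi * t01), sqrt(2) * cos(3 * pi * t01))
  cr <- cosine_representation(sig, k = 8)
  expect_equal(unname(cr$coeffs[1, "c1"]), 1, tolerance = 1e-10)
  expect_lt(max(abs(cr$coeffs[1, setdiff(colnames(cr$coeffs), "c1")])), 1e-10)
  expect_equal(unname(cr$coeffs[2, "c3"]), 1, tolerance = 1e-10)

  expect_error(cosine_representation(matrix(rnorm(10), 1, 10), k = 10),
               "timepoints")
})

test_that("reconstruction error is nonincreasing in the expansion order", {
  set.seed(1)
  T_ <- 60
  ts <- matrix(rnorm(3 * T_), 3, T_)
  t01 <- seq(0, 1, length.out = T_)
  mse <- vapply(c(2, 5, 10, 20, 40), function(k) {
    cr <- cosine_representation(ts, k = k)
    B <- cbind(1, vapply(seq_len(k), function(l) sqrt(2) * cos(l * pi * t01),
                         numeric(T_)))
    mean((ts - rowMeans(ts) - cr$coeffs %*% t(B))^2)
  }, numeric(1))
  expect_true(all(diff(mse) <= 1e-12))
  # full order reproduces the centered signal to numerical precision
  crf <- cosine_representation(ts, k = T_ - 1)
  Bf <- cbind(1, vapply(seq_len(T_ - 1), function(l) sqrt(2) * cos(l * pi * t01),
                        numeric(T_)))
  expect_lt(max(abs(ts - rowMeans(ts) - crf$coeffs %*% t(Bf))), 1e-6)
})

test_that("subject connectivity is the correlation of coefficient vectors", {
  set.seed(2)
  co <- matrix(rnorm(4 * 10), 4, 10,
               dimnames = list(paste0("P", 1:4), NULL))
  co[2, ] <- co[1, ]
  co[3, ] <- -co[1, ]
  C <- subject_connectivity(co)
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], -1)
  expect_equal(C, t(C))
  expect_equal(C[2, 4], stats::cor(co[2, ], co[4, ]))

  co[4, ] <- 0
  expect_error(subject_connectivity(co), "P4")
})

test_that("twin group correlation is symmetric and swap-invariant", {
  set.seed(3)
  coh <- simulate_twin_cohort(ace_config(p = 8, a2 = 0.5, c2 = 0.2,
                                         n_mz = 30, n_dz = 3))
  M <- twin_group_correlation(coh$mz_pairs)
  expect_equal(M, t(M))
  swapped <- lapply(coh$mz_pairs, function(pr) list(A = pr$B, B = pr$A))
  expect_equal(twin_group_correlation(swapped), M)

  # identical co-twins: every edge correlates perfectly
  clones <- lapply(coh$mz_pairs[1:5], function(pr) list(A = pr$A, B = pr$A))
  Mc <- twin_group_correlation(clones)
  expect_equal(max(abs(Mc[upper.tri(Mc)] - 1)), 0, tolerance = 1e-12)

  expect_error(twin_group_correlation(coh$mz_pairs[1:2]), "3 twin pairs")
})

test_that("zero-variance edges are flagged, not zeroed", {
  set.seed(4)
  pairs <- lapply(1:5, function(i) {
    m <- diag(3) * 0 + 0.5 * matrix(stats::runif(9), 3, 3)
    m <- (m + t(m)) / 2; diag(m) <- 1
    m[1, 2] <- m[2, 1] <- 0.25  # constant across pairs in both twins
    list(A = m, B = m + 0)
  })
  M <- twin_group_correlation(pairs)
  expect_true(is.na(M[1, 2]))
  expect_gte(attr(M, "n_undefined"), 1)
})

test_that("Falconer formula doubles the MZ-DZ gap", {
  cmz <- matrix(c(1, 1, 1, 1), 2, 2)
  cdz <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  hi <- falconer_heritability(cmz, cdz)
  expect_equal(hi[1, 2], 1)
  expect_equal(falconer_heritability(cdz, cdz), matrix(0, 2, 2))
  expect_error(falconer_heritability(cmz, matrix(1, 3, 3)), "shape")
})

test_that("ACE cohort correlations hit the Falconer identities", {
  # degenerate corners
  coh1 <- simulate_twin_cohort(ace_config(p = 8, a2 = 1, c2 = 0, n_mz = 150,
                                          n_dz = 3, seed = 5))
  m1 <- twin_group_correlation(coh1$mz_pairs)
  expect_gt(mean(m1[upper.tri(m1)]), 0.99)

  coh0 <- simulate_twin_cohort(ace_config(p = 8, a2 = 0, c2 = 0, n_mz = 150,
                                          n_dz = 150, seed = 6))
  m0 <- twin_group_correlation(coh0$mz_pairs)
  d0 <- twin_group_correlation(coh0$dz_pairs)
  expect_lt(abs(mean(m0[upper.tri(m0)])), 0.05)
  expect_lt(abs(mean(d0[upper.tri(d0)])), 0.05)

  # interior point: MZ -> a2 + c2, DZ -> a2/2 + c2
  coh <- simulate_twin_cohort(ace_config(p = 10, a2 = 0.6, c2 = 0.2,
                                         n_mz = 300, n_dz = 300, seed = 7))
  mz <- twin_group_correlation(coh$mz_pairs)
  dz <- twin_group_correlation(coh$dz_pairs)
  expect_lt(abs(mean(mz[upper.tri(mz)]) - 0.8), 0.03)
  expect_lt(abs(mean(dz[upper.tri(dz)]) - 0.5), 0.03)
})

test_that("twin KS inference is degenerate on identical groups", {
  set.seed(8)
  coh <- simulate_twin_cohort(ace_config(p = 10, a2 = 0.5, c2 = 0.2,
                                         n_mz = 20, n_dz = 3))
  cmz <- twin_group_correlation(coh$mz_pairs)
  res <- twin_ks_inference(cmz, cmz)
  expect_equal(res$ks0$D, 0)
  expect_equal(res$ks1$D, 0)
  expect_equal(res$ks0$p_value, 1)
  expect_equal(res$ks1$p_value, 1)
  expect_equal(res$HI, matrix(0, 10, 10), ignore_attr = TRUE)
  # negative entries never survive strict thresholding at eps >= 0
  neg <- diag(10); neg[1, 2] <- neg[2, 1] <- -0.9
  resn <- twin_ks_inference(neg, neg)
  expect_equal(resn$betti_mz$beta0, rep(10, 101), ignore_attr = TRUE)
})

test_that("a strongly heritable cohort is detected at high significance", {
  coh <- simulate_twin_cohort(ace_config(p = 30, a2 = 0.8, c2 = 0.1,
                                         n_mz = 120, n_dz = 120, seed = 9))
  res <- twin_ks_inference(twin_group_correlation(coh$mz_pairs),
                           twin_group_correlation(coh$dz_pairs))
  expect_lt(res$ks0$p_value, 0.001)
  expect_lt(res$ks1$p_value, 0.001)
  # MZ twins stay more connected (and more cyclic) than DZ at every level
  expect_true(all(res$betti_mz$beta0 <= res$betti_dz$beta0))
})

test_that("twin KS p-values are calibrated under the exchangeable null", {
  # a2 = 0 makes MZ and DZ sharing structures identical; 13 nodes keep the
  # 78 edge steps within the 100-level filtration grid the null assumes
  set.seed(10)
  rej <- replicate(100, {
    draw <- function() {
      coh <- simulate_twin_cohort(ace_config(p = 13, a2 = 0, c2 = 0.5,
                                             n_mz = 40, n_dz = 3))
      twin_group_correlation(coh$mz_pairs)
    }
    res <- twin_ks_inference(draw(), draw())
    res$ks0$p_value < 0.05 || res$ks1$p_value < 0.05
  })
  expect_lte(mean(rej), 0.10)
})
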