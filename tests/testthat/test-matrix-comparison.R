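test_that("Krzanowski subspace handles identical, disjoint and random sets", {
  S <- make_spd(10, seed = 1)
  res <- krzanowski_subspace(list(S, S, S, S), k = 3)
  expect_equal(max(res$Delta), 4, tolerance = 1e-8)
  expect_lt(min(res$delta_angles[1, ]), 1e-6)
  # trace conservation: trace(H) = k * p
  expect_equal(sum(diag(res$H)), 3 * 4, tolerance = 1e-10)

  # orthogonal leading eigenvectors, k = 1: Delta = {1, 1}
  S1 <- diag(c(5, 1, 0.5))
  S2 <- diag(c(1, 5, 0.5))
  res2 <- krzanowski_subspace(list(S1, S2), k = 1)
  expect_equal(sort(res2$Delta, decreasing = TRUE)[1:2], c(1, 1),
               tolerance = 1e-10)

  # brute-force projector oracle on a random set
  mats <- lapply(1:3, function(i) make_spd(8, seed = 10 + i))
  k <- 3
  res3 <- krzanowski_subspace(mats, k)
  H_brute <- Reduce(`+`, lapply(mats, function(m) {
    v <- eigen(m, symmetric = TRUE)$vectors[, 1:k]
    v %*% t(v)
  }))
  eb <- eigen(H_brute, symmetric = TRUE)
  expect_equal(res3$Delta, eb$values, tolerance = 1e-8)
  for (i in 1:3) {
    Ai <- eigen(mats[[i]], symmetric = TRUE)$vectors[, 1:k]
    d_brute <- acos(sqrt(pmin(colSums(crossprod(Ai, eb$vectors)^2), 1))) * 180 / pi
    expect_equal(res3$delta_angles[, i], d_brute, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  expect_error(krzanowski_subspace(list(S, S), k = 6), "floor")
})

test_that("comparison statistics are invariant to a common orthogonal basis change", {
  mats <- lapply(1:4, function(i) make_spd(8, seed = 20 + i))
  Q <- qr.Q(qr(matrix(rnorm(64), 8)))
  rot <- lapply(mats, function(m) t(Q) %*% m %*% Q)
  r1 <- krzanowski_subspace(mats, 3)
  r2 <- krzanowski_subspace(rot, 3)
  expect_equal(r1$Delta, r2$Delta, tolerance = 1e-8)
  expect_equal(euclidean_matrix_distance(mats[[1]], mats[[2]],
                                         upper_triangular = FALSE),
               euclidean_matrix_distance(rot[[1]], rot[[2]],
                                         upper_triangular = FALSE),
               tolerance = 1e-8)
  expect_equal(eccentricity(mats[[3]]), eccentricity(rot[[3]]),
               tolerance = 1e-8)
  a1 <- first_eigenvector_angle(mats[[1]], mats[[2]], n_random = 10)$angle
  a2 <- first_eigenvector_angle(rot[[1]], rot[[2]], n_random = 10)$angle
  expect_equal(a1, a2, tolerance = 1e-8)
})

test_that("matrix Euclidean distance follows the root convention", {
  S <- diag(2)
  expect_equal(euclidean_matrix_distance(S, S), 0)
  S2 <- S + rbind(c(3, 0), c(0, 4))
  expect_equal(euclidean_matrix_distance(S, S2), 5)
  # triangle and full modes differ exactly by the duplicated off-diagonals
  A <- make_spd(4, seed = 5)
  B <- make_spd(4, seed = 6)
  diffm <- A - B
  tri2 <- euclidean_matrix_distance(A, B)^2
  full2 <- euclidean_matrix_distance(A, B, upper_triangular = FALSE)^2
  expect_equal(full2 - tri2, sum(diffm[lower.tri(diffm)]^2), tolerance = 1e-10)
})

test_that("matrix correlation and its landmark-permutation test behave", {
  S <- make_landmark_cov(5, seed = 2)
  expect_equal(matrix_correlation(S, 2 * S, n_perm = 50, seed = 1)$r, 1)
  # identical matrices: small p at n_perm = 999
  mc <- matrix_correlation(S, S, n_perm = 999, seed = 2)
  expect_lte(mc$p, 0.05)
  # independent random matrices: typically non-significant
  ps <- sapply(1:20, function(r) {
    A <- make_landmark_cov(10, seed = 100 + r)
    B <- make_landmark_cov(10, seed = 200 + r)
    matrix_correlation(A, B, n_perm = 99, seed = r)$p
  })
  expect_gte(mean(ps > 0.05), 0.7)
  expect_error(matrix_correlation(make_spd(3), make_spd(3)), "at least 2")
})

test_that("eccentricity is the ratio of the two leading eigenvalues", {
  expect_equal(eccentricity(diag(3)), 1)
  expect_equal(eccentricity(diag(c(4, 2, 1))), 2)
  S <- make_spd(6, seed = 9)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(eccentricity(S), ev[1] / ev[2], tolerance = 1e-10)
  expect_error(eccentricity(matrix(0, 3, 3)), "rank")
})

test_that("first-eigenvector angles match the q = 3 sphere-cap null", {
  S <- make_spd(4, seed = 11)
  res_same <- first_eigenvector_angle(S, S, n_random = 1000, seed = 1)
  expect_equal(res_same$angle, 0, tolerance = 1e-8)
  expect_lte(res_same$p, 2 / 1000)
  # orthogonal leading axes
  res_orth <- first_eigenvector_angle(diag(c(5, 1)), diag(c(1, 5)),
                                      n_random = 500, seed = 2)
  expect_equal(res_orth$angle, 90, tolerance = 1e-8)
  expect_equal(res_orth$p, 1)
  # analytic oracle in q = 3: P(angle <= 60) = 1 - cos(60 deg) = 0.5
  A <- diag(c(3, 1, 0.5))
  v <- c(cos(pi / 3), sin(pi / 3), 0)
  B <- 3 * tcrossprod(v) + 0.1 * diag(3)
  res3 <- first_eigenvector_angle(A, B, n_random = 20000, seed = 3)
  expect_equal(res3$angle, 60, tolerance = 1e-6)
  se <- sqrt(0.25 / 20000)
  expect_lt(abs(res3$p - 0.5), 3 * se)
})

test_that("half-configuration extraction keeps the right coordinates", {
  map <- default_symmetry_map(17, 10)
  S <- cov_matrix(make_landmark_cov(44, seed = 4), "P")
  withmid <- prepare_half_configuration(S, map, include_midline = TRUE)
  expect_equal(nrow(withmid$matrix), 81)   # (17 + 10) * 3
  nomid <- prepare_half_configuration(S, map, include_midline = FALSE)
  expect_equal(nrow(nomid$matrix), 51)     # 17 * 3
  # idempotent
  again <- prepare_half_configuration(withmid, map, include_midline = TRUE)
  expect_identical(again$matrix, withmid$matrix)
  expect_error(
    prepare_half_configuration(cov_matrix(diag(3), "G", basis = "pc"), map),
    "landmark")
})

test_that("shared-covariance cohorts give shrinking subspace angles with n", {
  # anisotropic noise with a common eigenstructure across the symmetric and
  # FA levels; with isotropic noise the leading subspace is undefined and
  # the angles cannot converge
  angles <- sapply(c(60, 500), function(n) {
    fix <- make_distance_cohort(n = n, n_markers = 5, n_chromosomes = 1,
                                seed = 7, anisotropy = 0.7)
    dec <- fix$decomposition
    P <- prepare_half_configuration(sample_covariance(dec$symmetric, "P"),
                                    fix$cohort$map, include_midline = FALSE)
    FAm <- prepare_half_configuration(sample_covariance(dec$asymmetric, "FA"),
                                      fix$cohort$map, include_midline = FALSE)
    res <- krzanowski_subspace(list(P, FAm), k = 4)
    mean(res$delta_angles[1:2, ])
  })
  expect_lt(angles[2], angles[1])
})
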