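test_that("reflect_relabel is an involution that mirrors displacements", {
  map <- default_symmetry_map(1, 1)
  cfg <- rbind(c(1, 0.5, 0.2), c(-1, 0.5, 0.2), c(0, -1, 0.3))
  expect_equal(reflect_relabel(reflect_relabel(cfg, map), map), cfg)
  # displace the left landmark; the reflected copy displaces its partner by
  # the mirrored displacement (hand-computed 3-landmark case)
  delta <- c(0.05, -0.02, 0.01)
  cfg2 <- cfg
  cfg2[1, ] <- cfg2[1, ] + delta
  ref <- reflect_relabel(cfg2, map)
  expect_equal(ref[2, ] - cfg[2, ], delta * c(-1, 1, 1))
  expect_error(reflect_relabel(cfg[1:2, ], map), "landmarks")
})

test_that("shape-space dimension bookkeeping matches the object-symmetry formulas", {
  expect_identical(symmetric_dimension(17, 10), 67L)
  expect_identical(asymmetric_dimension(17, 10), 58L)
  # total shape space 3*44 - 7 = 125 splits into 67 + 58
  expect_identical(symmetric_dimension(17, 10) + asymmetric_dimension(17, 10),
                   3L * 44L - 7L)
  expect_identical(symmetric_dimension(0, 3), 2L)
  expect_error(symmetric_dimension(0, 2), "Degenerate")
})

test_that("GPA decomposes symmetric cohorts into consensus plus zero asymmetry", {
  base <- simulate_base_shape(4, 3, seed = 1)
  map <- attr(base, "map")
  arr <- array(rep(base, 5), dim = c(nrow(base), 3, 5))
  dec <- gpa_object_symmetry(arr, map)
  expect_lt(max(abs(dec$asymmetric)), 1e-10)
  expect_lt(max(abs(sweep(dec$symmetric, 2, colMeans(dec$symmetric)))), 1e-10)
  # consensus is itself symmetric
  expect_lt(max(abs(reflect_relabel(dec$consensus, map) - dec$consensus)), 1e-8)
})

test_that("GPA is invariant to similarity transforms of the input", {
  cfg <- simulation_config(n_individuals = 8, n_markers = 5, n_chromosomes = 1,
                           n_pairs = 4, n_midline = 3, seed = 3,
                           nuisance_transforms = FALSE)
  co <- simulate_cohort(cfg)
  dec1 <- gpa_object_symmetry(co$landmarks, co$map)
  arr2 <- co$landmarks
  set.seed(7)
  for (i in seq_len(dim(arr2)[3])) {
    rot <- shaperobust:::random_rotation()
    arr2[, , i] <- (arr2[, , i] %*% rot) * runif(1, 0.5, 2) +
      matrix(rnorm(3), nrow(arr2), 3, byrow = TRUE)
  }
  dec2 <- gpa_object_symmetry(arr2, co$map)
  # tangent coordinates are defined up to a common rotation of the consensus
  # frame; all Procrustes distances and component norms must be invariant
  d1 <- as.matrix(dist(dec1$symmetric))
  d2 <- as.matrix(dist(dec2$symmetric))
  expect_lt(max(abs(d1 - d2)), 1e-8)
  expect_lt(max(abs(sqrt(rowSums(dec1$asymmetric^2)) -
                    sqrt(rowSums(dec2$asymmetric^2)))), 1e-8)
  p1 <- shape_pca(dec1)$pca_eigenvalues
  p2 <- shape_pca(dec2)$pca_eigenvalues
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("side-specific noise lands in the asymmetric component (two-copy oracle)", {
  # independently coded oracle on 5 individuals: average each configuration
  # with its reflected-relabeled copy after aligning both to the template
  base <- simulate_base_shape(4, 3, seed = 5)
  map <- attr(base, "map")
  set.seed(8)
  n <- 5
  arr <- array(NA_real_, dim = c(nrow(base), 3, n))
  for (i in seq_len(n)) {
    z <- rnorm(shaperobust:::asym_free_dim(map), sd = 1e-3)
    pert <- shaperobust:::asym_perturbation(z, map)
    arr[, , i] <- base + matrix(pert, nrow(base), 3, byrow = TRUE)
  }
  dec <- gpa_object_symmetry(arr, map)
  # symmetric components collapse to the consensus within O(noise^2)
  expect_lt(max(abs(sweep(dec$symmetric, 2, colMeans(dec$symmetric)))), 1e-5)
  expect_gt(sum(apply(dec$asymmetric, 2, var)), 0)

  # oracle: half the original-minus-reflected difference, scaled to unit
  # centroid size and with the nuisance directions the superimposition
  # removes (x-translation, rotations about y and z) projected out, equals
  # the asymmetric component to O(noise^2)
  cs <- sqrt(sum(scale(base, scale = FALSE)^2))
  cons <- dec$consensus
  gen_rot <- function(axis3) {
    Gmat <- matrix(0, 3, 3)
    Gmat[axis3[1], axis3[2]] <- 1
    Gmat[axis3[2], axis3[1]] <- -1
    as.numeric(t(cons %*% Gmat))
  }
  p <- nrow(base)
  trans_x <- as.numeric(t(matrix(c(1, 0, 0), p, 3, byrow = TRUE)))
  nuis <- qr.Q(qr(cbind(trans_x, gen_rot(c(1, 2)), gen_rot(c(1, 3)))))
  for (i in seq_len(n)) {
    planted <- (arr[, , i] - reflect_relabel(arr[, , i], map)) / 2
    v <- as.numeric(t(planted)) / cs
    v <- v - nuis %*% crossprod(nuis, v)
    expect_equal(dec$asymmetric[i, ], as.numeric(v),
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("symmetric and asymmetric subspaces are orthogonal with conserved variance", {
  fix <- make_distance_cohort(n = 40, n_markers = 10, seed = 21,
                              variance_pairs = list(
                                list(marker_j = 1L, marker_k = 5L,
                                     lambda = 1, level = "fa")))
  dec <- fix$decomposition
  # every symmetric component vector is orthogonal to every asymmetric one
  dots <- dec$symmetric %*% t(dec$asymmetric)
  expect_lt(max(abs(dots)), 1e-8)
  # their spanned subspaces are orthogonal too
  sv_s <- svd(dec$symmetric)$v[, 1:5]
  sv_a <- svd(dec$asymmetric)$v[, 1:5]
  expect_lt(max(abs(crossprod(sv_s, sv_a))), 1e-8)
  # rank bounds at a meaningful singular-value threshold (the similarity
  # dof suppressed by superimposition reappear only at second order)
  num_rank <- function(m, tol = 1e-3) {
    sv <- svd(m, nu = 0, nv = 0)$d
    sum(sv > tol * sv[1])
  }
  expect_lte(num_rank(dec$symmetric), symmetric_dimension(5, 4))
  expect_lte(num_rank(dec$asymmetric), asymmetric_dimension(5, 4))
})

test_that("shape PCA drops null dimensions and preserves variance", {
  fix <- make_distance_cohort(n = 200, n_markers = 5, n_chromosomes = 1,
                              n_pairs = 5, n_midline = 4, seed = 31)
  dec <- fix$decomposition
  k <- ncol(dec$pca_scores)
  expect_lte(k, symmetric_dimension(5, 4))
  # trace conservation
  expect_equal(sum(apply(dec$pca_scores, 2, var)),
               sum(apply(dec$symmetric, 2, var)), tolerance = 1e-10)
  # back-projection reproduces the centred data
  centred <- sweep(dec$symmetric, 2, dec$pca_center)
  back <- dec$pca_scores %*% t(dec$pca_vectors)
  expect_lt(max(abs(centred - back)), 1e-10)
  # identical shapes: nothing retained
  base <- simulate_base_shape(4, 3, seed = 1)
  arr <- array(rep(base, 4), dim = c(nrow(base), 3, 4))
  dec0 <- shape_pca(gpa_object_symmetry(arr, attr(base, "map")))
  expect_identical(ncol(dec0$pca_scores), 0L)
})
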