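#' Krzanowski common-subspace analysis of covariance matrices
#'
#' For `p` covariance matrices sharing a basis, takes the first `k`
#' eigenvectors `A_i` of each, forms `H = sum_i A_i A_i'`, and
#' eigen-decomposes it. Eigenvalues `Delta` of `H` close to `p` mark
#' directions shared by every matrix; the angle between subspace eigenvector
#' `b` and each matrix's retained subspace is
#' `delta_i = acos(sqrt(b' A_i A_i' b))`. Because the analysis compares
#' whole subspaces it is insensitive to rank-order permutations or rotations
#' of individual principal axes.
#'
#' @param matrices List of `cov_matrix` objects or plain symmetric matrices
#'   with a common dimension.
#' @param k Number of leading eigenvectors retained per matrix; must satisfy
#'   `k <= floor(q / 2)`.
#' @return An object of class `krzanowski_subspace`: list with `H`, `Delta`
#'   (eigenvalues), `b` (eigenvectors), `delta_angles` (degrees; rows =
#'   subspace vectors, columns = input matrices), `k`, `labels`.
#' @export
krzanowski_subspace <- function(matrices, k) {
  mats <- lapply(matrices, cov_values)
  if (length(mats) < 2L) abort("Need at least 2 matrices.")
  q <- nrow(mats[[1L]])
  if (!all(vapply(mats, function(m) all(dim(m) == q), logical(1)))) {
    abort("All matrices must share the same dimension.")
  }
  k <- check_count(k, "k", 1L)
  if (k > floor(q / 2)) {
    abort(sprintf("k = %d exceeds floor(q / 2) = %d; shared subspaces of more than half the space are always degenerate.",
                  k, floor(q / 2)))
  }
  labels <- vapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    if (inherits(m, "cov_matrix")) m$label else sprintf("M%d", i)
  }, character(1))
  A <- lapply(mats, function(m) eigen(m, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE])
  H <- Reduce(`+`, lapply(A, tcrossprod))
  eigH <- eigen((H + t(H)) / 2, symmetric = TRUE)
  Delta <- eigH$values
  b <- eigH$vectors
  delta_angles <- sapply(A, function(Ai) {
    proj <- crossprod(Ai, b)                 # k x q
    cosang <- sqrt(pmin(pmax(colSums(proj^2), 0), 1))
    acos(cosang) * 180 / pi
  })
  colnames(delta_angles) <- labels
  structure(list(H = H, Delta = Delta, b = b, delta_angles = delta_angles,
                 k = k, labels = labels),
            class = "krzanowski_subspace")
}

#' @export
print.krzanowski_subspace <- function(x, ...) {
  cat(sprintf("<krzanowski_subspace> %d matrices (%s), k = %d\n",
              length(x$labels), paste(x$labels, collapse = ", "), x$k))
  cat("  leading Delta:", paste(signif(head(x$Delta, 5L), 4L), collapse = ", "), "\n")
  invisible(x)
}

#' Sweep the retained dimension of the Krzanowski analysis
#'
#' Runs [krzanowski_subspace()] for every `k` in `1..floor(q/2)` and returns
#' a tidy profile of the eigenvalues and angles, the natural summary when no
#' single subspace dimension is privileged.
#'
#' @inheritParams krzanowski_subspace
#' @param k_max Largest `k` (default `floor(q / 2)`).
#' @return Tibble with columns `k`, `rank`, `Delta`, and one `delta_<label>`
#'   angle column per input matrix.
#' @export
krzanowski_profile <- function(matrices, k_max = NULL) {
  q <- nrow(cov_values(matrices[[1L]]))
  k_max <- k_max %||% floor(q / 2)
  purrr::map_dfr(seq_len(k_max), function(k) {
    res <- krzanowski_subspace(matrices, k)
    ang <- as_tibble(res$delta_angles, .name_repair = "minimal")
    names(ang) <- sprintf("delta_%s", res$labels)
    dplyr::bind_cols(tibble(k = k, rank = seq_along(res$Delta),
                            Delta = res$Delta), ang)
  })
}

upper_tri_values <- function(m) m[upper.tri(m, diag = TRUE)]

#' Euclidean distance between covariance matrices
#'
#' Square root of the sum of squared element differences over the upper
#' triangle including the diagonal (each covariance counted once); with
#' `upper_triangular = FALSE` the full-matrix Frobenius norm is used.
#'
#' @param S1,S2 Covariance matrices (`cov_matrix` or plain).
#' @param upper_triangular Restrict to the upper triangle (default).
#' @return A nonnegative scalar.
#' @export
euclidean_matrix_distance <- function(S1, S2, upper_triangular = TRUE) {
  m1 <- cov_values(S1)
  m2 <- cov_values(S2)
  if (!all(dim(m1) == dim(m2))) abort("Matrices must have the same dimensions.")
  diffm <- m1 - m2
  if (upper_triangular) {
    sqrt(sum(upper_tri_values(diffm)^2))
  } else {
    sqrt(sum(diffm^2))
  }
}

permute_landmark_blocks <- function(m, perm, block = 3L) {
  idx <- as.vector(t(outer(perm, seq_len(block), function(l, c) (l - 1L) * block + c)))
  m[idx, idx]
}

#' Element-wise matrix correlation with a landmark-permutation test
#'
#' Pearson correlation of the upper-triangular elements (including the
#' diagonal blocks) of two covariance matrices in the landmark-coordinate
#' basis. Significance comes from permuting whole landmarks of one matrix —
#' xyz coordinate triplets move together, preserving the within-landmark
#' covariance structure — with the add-one convention
#' `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)`.
#'
#' @param S1,S2 Covariance matrices over the same `3 * L` coordinates.
#' @param n_perm Number of landmark permutations (default 10000).
#' @param seed Optional seed.
#' @param block Coordinates per landmark (default 3).
#' @return List with `r` and `p`.
#' @export
matrix_correlation <- function(S1, S2, n_perm = 10000L, seed = NULL, block = 3L) {
  m1 <- cov_values(S1)
  m2 <- cov_values(S2)
  if (!all(dim(m1) == dim(m2))) abort("Matrices must have the same dimensions.")
  if (nrow(m1) %% block != 0L) abort("Matrix dimension is not a multiple of the landmark block size.")
  n_landmarks <- nrow(m1) %/% block
  if (n_landmarks < 2L) abort("Need at least 2 landmarks to permute.")
  r_obs <- cor(upper_tri_values(m1), upper_tri_values(m2))
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n_landmarks)
    r_p <- cor(upper_tri_values(m1),
               upper_tri_values(permute_landmark_blocks(m2, perm, block)))
    if (!is.na(r_p) && r_p >= r_obs) count <- count + 1L
  }
  list(r = r_obs, p = (1 + count) / (1 + n_perm))
}

#' Eccentricity (integration) of a covariance matrix
#'
#' Ratio of the first two eigenvalues; larger values mean variance more
#' concentrated on a single axis (stronger integration).
#'
#' @param S Covariance matrix.
#' @return `lambda_1 / lambda_2`.
#' @export
eccentricity <- function(S) {
  vals <- eigen(cov_values(S), symmetric = TRUE, only.values = TRUE)$values
  if (length(vals) < 2L || vals[2L] <= 0) {
    abort("Matrix rank < 2: eccentricity undefined.")
  }
  vals[1L] / vals[2L]
}

#' Angle between the first eigenvectors of two covariance matrices
#'
#' Folded angle `acos(|v1 . v2|)` in degrees, with significance from the
#' fraction of `n_random` independent uniform-on-the-sphere vector pairs
#' whose angle is at most the observed one.
#'
#' @param S1,S2 Covariance matrices of equal dimension `q >= 2`.
#' @param n_random Number of random vector pairs (default 100000).
#' @param seed Optional seed.
#' @return List with `angle` (degrees) and `p`.
#' @export
first_eigenvector_angle <- function(S1, S2, n_random = 100000L, seed = NULL) {
  m1 <- cov_values(S1)
  m2 <- cov_values(S2)
  if (!all(dim(m1) == dim(m2))) abort("Matrices must have the same dimensions.")
  q <- nrow(m1)
  if (q < 2L) abort("Need dimension >= 2.")
  if (max(abs(m1)) == 0 || max(abs(m2)) == 0) {
    abort("Zero matrix: first eigenvector undefined.")
  }
  v1 <- eigen(m1, symmetric = TRUE)$vectors[, 1L]
  v2 <- eigen(m2, symmetric = TRUE)$vectors[, 1L]
  ang <- acos(min(abs(sum(v1 * v2)), 1)) * 180 / pi
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(rnorm(n_random * q), n_random)
  b <- matrix(rnorm(n_random * q), n_random)
  cosr <- abs(rowSums(a * b)) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  rand_ang <- acos(pmin(cosr, 1)) * 180 / pi
  list(angle = ang, p = mean(rand_ang <= ang))
}

#' Restrict a landmark-basis covariance matrix to a half configuration
#'
#' Keeps one side's paired landmarks (the left column of the symmetry map),
#' plus the midline landmarks when `include_midline = TRUE`. Comparisons
#' involving the FA matrix must exclude the midline (their symmetric-space
#' counterparts carry no matching FA variation there); comparisons among
#' symmetric-shape matrices drop the duplicated right side either way.
#'
#' @param x A `cov_matrix` in the `"landmark"` basis over `3 * L`
#'   coordinates.
#' @param map The `symmetry_map` for the full configuration.
#' @param include_midline Keep the midline landmarks (default `TRUE`).
#' @return A `cov_matrix` restricted to the retained coordinates.
#' @export
prepare_half_configuration <- function(x, map, include_midline = TRUE) {
  stopifnot(inherits(x, "cov_matrix"), inherits(map, "symmetry_map"))
  if (x$basis != "landmark") {
    abort("Half-configuration extraction needs a landmark-coordinate basis.")
  }
  already <- attr(x$matrix, "half_configuration")
  if (isTRUE(already)) return(x)
  if (nrow(x$matrix) != 3L * map$n_landmarks) {
    abort("Matrix dimension does not match 3 x n_landmarks.")
  }
  lms <- map$pairs[, 1L]
  if (include_midline) lms <- c(lms, map$midline)
  lms <- sort(lms)
  idx <- as.vector(t(outer(lms, 1:3, function(l, c) (l - 1L) * 3L + c)))
  sub <- x$matrix[idx, idx]
  attr(sub, "half_configuration") <- TRUE
  out <- cov_matrix(sub, x$label, basis = "landmark")
  attr(out$matrix, "half_configuration") <- TRUE
  out
}

#' Pairwise similarity table for a set of covariance matrices
#'
#' For every matrix pair: the Euclidean distance, the element-wise
#' correlation with its landmark-permutation p-value, and the folded angle
#' between first eigenvectors with its random-vector p-value; per matrix,
#' the eccentricity. Matrices must already be on a common (half-)
#' configuration; see [prepare_half_configuration()].
#'
#' @param matrices Named list of `cov_matrix` objects on a common basis.
#' @param n_perm Landmark permutations for the correlation test.
#' @param n_random Random vector pairs for the angle test.
#' @param seed Optional seed.
#' @return List with `pairs` (tibble: `label_1`, `label_2`, `d_E`, `r`,
#'   `p_r`, `alpha_deg`, `p_alpha`) and `eccentricity` (tibble: `label`,
#'   `eccentricity`).
#' @export
similarity_table <- function(matrices, n_perm = 10000L, n_random = 100000L,
                             seed = NULL) {
  labels <- vapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    if (inherits(m, "cov_matrix")) m$label else (names(matrices)[i] %||% sprintf("M%d", i))
  }, character(1))
  if (!is.null(seed)) set.seed(seed)
  combos <- combn(seq_along(matrices), 2L)
  pairs <- purrr::map_dfr(seq_len(ncol(combos)), function(i) {
    a <- combos[1L, i]
    b <- combos[2L, i]
    mc <- matrix_correlation(matrices[[a]], matrices[[b]], n_perm = n_perm)
    fe <- first_eigenvector_angle(matrices[[a]], matrices[[b]], n_random = n_random)
    tibble(label_1 = labels[a], label_2 = labels[b],
           d_E = euclidean_matrix_distance(matrices[[a]], matrices[[b]]),
           r = mc$r, p_r = mc$p, alpha_deg = fe$angle, p_alpha = fe$p)
  })
  ecc <- tibble(label = labels,
                eccentricity = vapply(matrices, eccentricity, numeric(1)))
  list(pairs = pairs, eccentricity = ecc)
}
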