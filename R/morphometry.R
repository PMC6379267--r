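#' Reflect and relabel a landmark configuration
#'
#' Mirrors a configuration through the midsagittal plane (negating the
#' coordinate along the map's reflection axis) and swaps the left/right
#' landmark labels, so the result is directly comparable to the original.
#' Applying the operation twice returns the input. This is the core step of
#' Procrustes analysis with object symmetry: a configuration is perfectly
#' symmetric exactly when it equals its reflected-relabeled copy up to a
#' similarity transform.
#'
#' @param config A p x 3 landmark matrix.
#' @param map A [symmetry_map()] covering all p landmarks.
#' @return A p x 3 matrix.
#' @export
reflect_relabel <- function(config, map) {
  config <- as.matrix(config)
  stopifnot(inherits(map, "symmetry_map"))
  if (nrow(config) != map$n_landmarks) {
    abort(sprintf("Configuration has %d landmarks but the map covers %d.",
                  nrow(config), map$n_landmarks))
  }
  out <- config
  out[, map$reflection_axis] <- -out[, map$reflection_axis]
  if (nrow(map$pairs) > 0L) {
    left <- map$pairs[, 1L]
    right <- map$pairs[, 2L]
    tmp <- out[left, , drop = FALSE]
    out[left, ] <- out[right, , drop = FALSE]
    out[right, ] <- tmp
  }
  out
}

# The reflect-relabel map as a linear operator on vectorised configurations is
# an orthogonal involution; its +1/-1 eigenspaces are the symmetric and
# asymmetric shape subspaces, which is why the two components are exactly
# orthogonal.
reflect_relabel_vec <- function(v, map) {
  p <- map$n_landmarks
  vec_config(reflect_relabel(unvec_config(v, p), map))
}

#' Dimensionality of the symmetric and asymmetric shape spaces
#'
#' For a 3D configuration of `n_pairs` bilateral landmark pairs and
#' `n_midline` midsagittal landmarks, the symmetric component of shape
#' variation after Procrustes superimposition with object symmetry spans
#' `3 * n_pairs + 2 * n_midline - 4` dimensions, and the asymmetric
#' (fluctuating-asymmetry) component spans `3 * n_pairs + n_midline - 3`.
#' With the classic 17-pair + 10-midline skull layout this gives 67 and 58.
#'
#' @param n_pairs Number of bilateral landmark pairs.
#' @param n_midline Number of midline landmarks.
#' @return An integer dimension count.
#' @export
symmetric_dimension <- function(n_pairs, n_midline) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  n_midline <- check_count(n_midline, "n_midline")
  d <- 3L * n_pairs + 2L * n_midline - 4L
  if (d <= 0L) abort("Degenerate shape: symmetric dimension would be <= 0.")
  d
}

#' @rdname symmetric_dimension
#' @export
asymmetric_dimension <- function(n_pairs, n_midline) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  n_midline <- check_count(n_midline, "n_midline")
  d <- 3L * n_pairs + n_midline - 3L
  if (d <= 0L) abort("Degenerate shape: asymmetric dimension would be <= 0.")
  d
}

# Optimal rotation (no reflection) aligning centred X onto centred target.
kabsch_rotation <- function(x, target) {
  m <- crossprod(x, target)
  s <- svd(m)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)[seq_len(ncol(m))]) %*% t(s$v)
}

#' Generalized Procrustes analysis with object symmetry
#'
#' Superimposes each configuration together with its reflected-relabeled copy
#' (2n configurations in total): translations are removed, configurations are
#' scaled to unit centroid size (unless `scale = FALSE`, the partial
#' superimposition), and rotations are optimised iteratively against a
#' consensus that is re-symmetrised at every step. Each individual's
#' symmetric component is the average of its two aligned copies and its
#' asymmetric (fluctuating-asymmetry) component half their difference; the
#' two sets of components live in exactly orthogonal subspaces.
#'
#' @param coords Landmark data accepted by [as_landmark_array()].
#' @param map A [symmetry_map()].
#' @param tol Convergence tolerance on the root-mean-square consensus
#'   displacement between iterations.
#' @param max_iter Maximum number of alignment iterations.
#' @param scale Scale configurations to unit centroid size (default). With
#'   `FALSE`, only translation and rotation are removed.
#' @param tangent Tangent-space projection applied to the symmetric
#'   component: `"orthogonal"` projects residuals from the consensus onto the
#'   plane orthogonal to it; `"none"` uses raw Procrustes residuals.
#'
#' @return An object of class `symmetry_decomposition`: a list with the
#'   consensus configuration (p x 3), `symmetric` and `asymmetric` n x 3p
#'   component matrices (tangent-space vectors, individuals in rows),
#'   `centroid_sizes`, the map, and iteration metadata. Run [shape_pca()] on
#'   it to add a principal-component basis for the symmetric space.
#' @export
gpa_object_symmetry <- function(coords, map, tol = 1e-9, max_iter = 100L,
                                scale = TRUE, tangent = c("orthogonal", "none")) {
  tangent <- match.arg(tangent)
  arr <- as_landmark_array(coords)
  p <- dim(arr)[1L]
  n <- dim(arr)[3L]
  if (n < 2L) abort("Need at least 2 individuals.")
  if (p < 3L) abort("Need at least 3 landmarks.")
  stopifnot(inherits(map, "symmetry_map"))
  if (map$n_landmarks != p) abort("Symmetry map does not match landmark count.")

  # 2n working copies: originals then reflected-relabeled mirrors.
  work <- array(NA_real_, dim = c(p, 3L, 2L * n))
  csize <- numeric(n)
  for (i in seq_len(n)) {
    cfg <- sweep(arr[, , i], 2L, colMeans(arr[, , i]))
    csize[i] <- sqrt(sum(cfg^2))
    if (csize[i] <= 0) abort("Degenerate configuration with zero centroid size.")
    if (scale) cfg <- cfg / csize[i]
    ref <- reflect_relabel(cfg, map)
    ref <- sweep(ref, 2L, colMeans(ref))
    work[, , i] <- cfg
    work[, , n + i] <- ref
  }

  symmetrize <- function(cfg) (cfg + reflect_relabel(cfg, map)) / 2

  consensus <- symmetrize(work[, , 1L])
  consensus <- sweep(consensus, 2L, colMeans(consensus))
  if (scale) consensus <- consensus / sqrt(sum(consensus^2))

  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(2L * n)) {
      work[, , j] <- work[, , j] %*% kabsch_rotation(work[, , j], consensus)
    }
    new_consensus <- symmetrize(apply(work, c(1L, 2L), mean))
    new_consensus <- sweep(new_consensus, 2L, colMeans(new_consensus))
    if (scale) new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    trace <- c(trace, delta)
    consensus <- new_consensus
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(c(sprintf("GPA did not converge in %d iterations.", max_iter),
            i = sprintf("Last consensus displacements: %s",
                        paste(signif(tail(trace, 5L), 3L), collapse = ", "))))
  }

  cvec <- vec_config(consensus)
  sym <- matrix(NA_real_, n, 3L * p)
  asym <- matrix(NA_real_, n, 3L * p)
  for (i in seq_len(n)) {
    s <- (work[, , i] + work[, , n + i]) / 2
    a <- (work[, , i] - work[, , n + i]) / 2
    sym[i, ] <- vec_config(s)
    asym[i, ] <- vec_config(a)
  }
  if (tangent == "orthogonal") {
    u <- cvec / sqrt(sum(cvec^2))
    resid <- sweep(sym, 2L, cvec)
    sym <- resid - (resid %*% u) %*% t(u)
    asym <- asym - (asym %*% u) %*% t(u)
  } else {
    sym <- sweep(sym, 2L, cvec)
  }
  colnames(sym) <- colnames(asym) <- landmark_colnames(p)
  ids <- dimnames(arr)[[3L]] %||% sprintf("ind_%d", seq_len(n))
  rownames(sym) <- rownames(asym) <- ids

  structure(
    list(consensus = consensus, symmetric = sym, asymmetric = asym,
         centroid_sizes = csize, map = map, tangent = tangent, scale = scale,
         n_iter = iter, trace = trace),
    class = "symmetry_decomposition"
  )
}

#' @export
print.symmetry_decomposition <- function(x, ...) {
  cat(sprintf(
    "<symmetry_decomposition> %d individuals, %d landmarks (%d pairs, %d midline)\n",
    nrow(x$symmetric), x$map$n_landmarks, nrow(x$map$pairs),
    length(x$map$midline)))
  cat(sprintf("  GPA converged in %d iterations; tangent = %s, scaled = %s\n",
              x$n_iter, x$tangent, x$scale))
  if (!is.null(x$pca_scores)) {
    cat(sprintf("  symmetric PCA: %d retained dimensions\n", ncol(x$pca_scores)))
  }
  invisible(x)
}

#' Principal components of the symmetric shape space
#'
#' Centred PCA of the symmetric tangent-space components, dropping the null
#' dimensions created by the superimposition (eigenvalue below
#' `null_tol` times the leading eigenvalue). The retained scores carry the
#' full symmetric variation: back-projection reproduces the centred data to
#' numerical precision, so downstream analyses can work in the reduced basis.
#'
#' @param decomposition A `symmetry_decomposition`.
#' @param null_tol Relative eigenvalue threshold below which a dimension is
#'   treated as null.
#' @param component Which component to decompose, `"symmetric"` (default) or
#'   `"asymmetric"`.
#' @return The decomposition, with `pca_scores` (n x k), `pca_vectors`
#'   (3p x k), `pca_eigenvalues`, `pca_center` and `pca_component` added
#'   (asymmetric results are stored with an `fa_` prefix).
#' @export
shape_pca <- function(decomposition, null_tol = 1e-10,
                      component = c("symmetric", "asymmetric")) {
  stopifnot(inherits(decomposition, "symmetry_decomposition"))
  component <- match.arg(component)
  x <- decomposition[[component]]
  n <- nrow(x)
  if (n < 2L) abort("Need at least 2 individuals for a PCA.")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  sv <- svd(xc)
  eig <- sv$d^2 / (n - 1)
  keep <- if (eig[1L] > 0) which(eig > null_tol * eig[1L]) else integer()
  scores <- xc %*% sv$v[, keep, drop = FALSE]
  rownames(scores) <- rownames(x)
  colnames(scores) <- sprintf("PC%d", seq_along(keep))
  out <- list(scores = scores, vectors = sv$v[, keep, drop = FALSE],
              eigenvalues = eig[keep], center = ctr)
  if (component == "symmetric") {
    decomposition$pca_scores <- out$scores
    decomposition$pca_vectors <- out$vectors
    decomposition$pca_eigenvalues <- out$eigenvalues
    decomposition$pca_center <- out$center
  } else {
    decomposition$fa_pca_scores <- out$scores
    decomposition$fa_pca_vectors <- out$vectors
    decomposition$fa_pca_eigenvalues <- out$eigenvalues
    decomposition$fa_pca_center <- out$center
  }
  decomposition
}

#' Write shape PCA scores and vectors as TSV
#' @param decomposition A `symmetry_decomposition` with PCA computed.
#' @param scores_path,vectors_path Output paths.
#' @return Invisibly, the score path.
#' @export
write_shape_pca <- function(decomposition, scores_path, vectors_path) {
  if (is.null(decomposition$pca_scores)) abort("Run shape_pca() first.")
  sc <- as_tibble(decomposition$pca_scores)
  sc <- dplyr::bind_cols(tibble(id = rownames(decomposition$pca_scores)), sc)
  readr::write_tsv(sc, scores_path)
  vec <- as_tibble(decomposition$pca_vectors, .name_repair = "minimal")
  names(vec) <- sprintf("PC%d", seq_len(ncol(vec)))
  vec <- dplyr::bind_cols(
    tibble(coordinate = landmark_colnames(decomposition$map$n_landmarks)), vec)
  readr::write_tsv(vec, vectors_path)
  invisible(scores_path)
}
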