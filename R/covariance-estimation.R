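#' Covariance matrix container
#'
#' Light wrapper tying a symmetric covariance matrix to its label (P, G, E
#' or FA) and the basis it is expressed in (`"landmark"` coordinates or
#' `"pc"` scores).
#'
#' @param matrix Symmetric numeric matrix.
#' @param label One of `"P"`, `"G"`, `"E"`, `"FA"` (free-form allowed).
#' @param basis Basis descriptor, `"landmark"` or `"pc"`.
#' @return An object of class `cov_matrix`.
#' @export
cov_matrix <- function(matrix, label, basis = "landmark") {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) abort("Covariance matrix must be square.")
  m <- (m + t(m)) / 2
  structure(list(matrix = m, label = label, basis = basis),
            class = "cov_matrix")
}

cov_values <- function(x) if (inherits(x, "cov_matrix")) x$matrix else as.matrix(x)

#' @export
print.cov_matrix <- function(x, ...) {
  cat(sprintf("<cov_matrix> %s (%d x %d, %s basis)\n",
              x$label, nrow(x$matrix), ncol(x$matrix), x$basis))
  invisible(x)
}

#' Sample covariance of shape components
#'
#' Centred covariance (divisor `n - 1`) of the rows of a component matrix:
#' the P matrix from symmetric components, the FA matrix from asymmetric
#' components.
#'
#' @param components Individuals x dimensions matrix.
#' @param label Matrix label (`"P"`, `"FA"`, ...).
#' @param basis Basis descriptor.
#' @return A `cov_matrix`.
#' @export
sample_covariance <- function(components, label = "P", basis = "landmark") {
  x <- as.matrix(components)
  if (nrow(x) < 2L) abort("Need at least 2 individuals.")
  cov_matrix(cov(x), label = label, basis = basis)
}

# Exact univariate REML on pre-rotated contrasts (shared eigen basis).
univariate_reml <- function(ytil, lambda) {
  m <- length(ytil)
  negrll <- function(h) {
    wts <- h * lambda + (1 - h)
    0.5 * (sum(log(wts)) + m * log(sum(ytil^2 / wts) / m))
  }
  opt <- optimize(negrll, c(0, 0.999))
  h <- if (negrll(0) <= opt$objective) 0 else opt$minimum
  wts <- h * lambda + (1 - h)
  s_tot <- sum(ytil^2 / wts) / m
  c(sigma_g2 = h * s_tot, sigma_e2 = (1 - h) * s_tot)
}

# EM-REML for the multivariate one-GRM model on contrast-projected,
# K-eigenrotated data: rows ytil_s ~ N_q(0, lambda_s G + E) independent.
# The E-step is grouped by unique eigenvalue, so structured relatedness
# (few distinct eigenvalues) costs a handful of q x q operations per sweep.
em_reml_multivariate <- function(Ytil, lambda, tol = 1e-5, max_iter = 5000L) {
  m <- nrow(Ytil)
  q <- ncol(Ytil)
  S <- crossprod(Ytil) / m
  G <- S / 2
  E <- S / 2
  groups <- split(seq_len(m), signif(lambda, 12L))
  lam_g <- vapply(groups, function(ix) lambda[ix[1L]], numeric(1))
  W_g <- lapply(groups, function(ix) crossprod(Ytil[ix, , drop = FALSE]))
  n_g <- lengths(groups)
  Iq <- diag(q)
  for (iter in seq_len(max_iter)) {
    G_acc <- matrix(0, q, q)
    E_acc <- matrix(0, q, q)
    for (g in seq_along(groups)) {
      l <- lam_g[g]
      V <- l * G + E
      Vi <- tryCatch(solve(V), error = function(e) {
        solve(V + diag(1e-10 * mean(diag(V)), q))
      })
      GVi <- G %*% Vi
      # sum_s E[g g' | y] / lambda_s, stable at lambda = 0
      G_acc <- G_acc + l * (GVi %*% W_g[[g]] %*% t(GVi)) +
        n_g[g] * (G - l * (GVi %*% G))
      C <- Iq - l * GVi
      E_acc <- E_acc + C %*% W_g[[g]] %*% t(C) +
        n_g[g] * (E - E %*% Vi %*% E)
    }
    G_new <- (G_acc + t(G_acc)) / (2 * m)
    E_new <- (E_acc + t(E_acc)) / (2 * m)
    delta <- max(abs(G_new - G), abs(E_new - E)) /
      max(mean(abs(diag(S))), .Machine$double.eps)
    G <- G_new
    E <- E_new
    if (delta < tol) {
      return(list(G = G, E = E, iterations = iter, converged = TRUE))
    }
  }
  list(G = G, E = E, iterations = max_iter, converged = FALSE)
}

clamp_psd <- function(m, label) {
  eig <- eigen(m, symmetric = TRUE)
  if (any(eig$values < -1e-8 * max(abs(eig$values), 1e-12))) {
    warn(sprintf("Negative variance estimates in %s clamped at 0.", label))
  }
  vals <- pmax(eig$values, 0)
  eig$vectors %*% (t(eig$vectors) * vals)
}

#' Estimate the G and E covariance matrices by block REML
#'
#' Mixed-model decomposition of shape PC scores into additive-genetic (G)
#' and residual (E) covariance given a genomic relatedness matrix. The first
#' `block1_size` PCs are fitted jointly with unstructured genetic and
#' residual covariance (EM on the exact restricted likelihood, computed on
#' intercept-orthogonal contrasts rotated to the GRM eigenbasis); the
#' remaining PCs are fitted as independent univariate REML problems, filling
#' the diagonals with genetic covariances set to zero. G and E are assembled
#' block-diagonal in the PC basis; negative definite parts are clamped at
#' zero.
#'
#' @param pc_scores Individuals x PCs score matrix (e.g.
#'   `decomposition$pca_scores`).
#' @param K A `grm` or relatedness matrix.
#' @param block1_size Number of leading PCs modelled with unstructured
#'   covariance (default 10; 0 gives a fully diagonal model).
#' @param tol,max_iter EM convergence control for the unstructured block.
#' @return List with `G` and `E` (`cov_matrix` objects in the `"pc"` basis),
#'   `h2` (per-PC heritability), `block1_variance_share` and `iterations`.
#' @export
estimate_G_E <- function(pc_scores, K, block1_size = 10L, tol = 1e-5,
                         max_iter = 5000L) {
  Y <- as.matrix(pc_scores)
  n <- nrow(Y)
  q <- ncol(Y)
  block1_size <- check_count(block1_size, "block1_size")
  if (block1_size > q) abort("`block1_size` exceeds the number of PCs.")
  Km <- if (inherits(K, "grm")) K$K else as.matrix(K)
  if (nrow(Km) != n) abort("GRM dimension does not match the scores.")

  Tm <- qr.Q(qr(matrix(1, n, 1L)), complete = TRUE)[, -1L, drop = FALSE]
  Kp <- crossprod(Tm, Km %*% Tm)
  eig <- eigen((Kp + t(Kp)) / 2, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  if (sd(lambda) < 1e-6 * max(mean(lambda), 1e-12)) {
    warn("GRM is numerically proportional to the identity: G and E are poorly identifiable.")
  }
  Ytil <- crossprod(eig$vectors, crossprod(Tm, Y))

  G <- matrix(0, q, q)
  E <- matrix(0, q, q)
  iterations <- 0L
  if (block1_size >= 1L) {
    b1 <- seq_len(block1_size)
    fit1 <- em_reml_multivariate(Ytil[, b1, drop = FALSE], lambda,
                                 tol = tol, max_iter = max_iter)
    if (!fit1$converged) {
      abort(sprintf("REML did not converge for the unstructured block (PC1-PC%d) in %d iterations.",
                    block1_size, max_iter))
    }
    G[b1, b1] <- fit1$G
    E[b1, b1] <- fit1$E
    iterations <- fit1$iterations
  }
  if (block1_size < q) {
    for (j in seq.int(block1_size + 1L, q)) {
      vc <- univariate_reml(Ytil[, j], lambda)
      G[j, j] <- vc[["sigma_g2"]]
      E[j, j] <- vc[["sigma_e2"]]
    }
  }
  G <- clamp_psd(G, "G")
  E <- clamp_psd(E, "E")
  nm <- colnames(Y) %||% sprintf("PC%d", seq_len(q))
  dimnames(G) <- dimnames(E) <- list(nm, nm)
  tot <- colSums(Ytil^2)
  list(G = cov_matrix(G, "G", basis = "pc"),
       E = cov_matrix(E, "E", basis = "pc"),
       h2 = diag(G) / pmax(diag(G) + diag(E), .Machine$double.eps),
       block1_variance_share = if (q > 0) sum(tot[seq_len(block1_size)]) / sum(tot) else NA_real_,
       iterations = iterations)
}

#' Rotate a PC-basis covariance matrix back to landmark coordinates
#'
#' @param x A `cov_matrix` in the `"pc"` basis.
#' @param vectors PCA loading matrix (coordinates x PCs) used to build the
#'   scores.
#' @return A `cov_matrix` in the `"landmark"` basis.
#' @export
cov_to_landmark_basis <- function(x, vectors) {
  stopifnot(inherits(x, "cov_matrix"))
  if (x$basis != "pc") abort("Matrix is not in the PC basis.")
  v <- as.matrix(vectors)
  if (ncol(v) != nrow(x$matrix)) abort("Loading matrix does not match the PC dimension.")
  out <- v %*% x$matrix %*% t(v)
  rownames(out) <- colnames(out) <- rownames(v)
  cov_matrix(out, x$label, basis = "landmark")
}

#' Multivariate heritability spectrum h^2 = G P^{-1}
#'
#' Eigen-decomposes `G P^{-1}` through the equivalent symmetric generalized
#' eigenproblem `G v = h P v` (guaranteeing real eigenvalues), ranking shape
#' directions by the fraction of phenotypic variance that is additive. Null
#' phenotypic dimensions are dropped via a pseudo-inverse when P is
#' singular.
#'
#' @param G,P `cov_matrix` objects (or plain matrices) on the same basis.
#' @return An object of class `heritability_spectrum`: tibble with `rank`,
#'   `eigenvalue` (the heritability of the direction) and
#'   `additive_variance_share`; eigenvectors attached as an attribute.
#' @export
heritability_spectrum <- function(G, P) {
  if (inherits(G, "cov_matrix") && inherits(P, "cov_matrix") &&
      !identical(G$basis, P$basis)) {
    abort("G and P are expressed in different bases.")
  }
  Gm <- cov_values(G)
  Pm <- cov_values(P)
  if (!all(dim(Gm) == dim(Pm))) abort("G and P dimensions differ.")
  eigP <- eigen(Pm, symmetric = TRUE)
  keep <- eigP$values > 1e-10 * max(eigP$values, .Machine$double.eps)
  U <- eigP$vectors[, keep, drop = FALSE]
  inv_sqrt <- 1 / sqrt(eigP$values[keep])
  W <- sweep(U, 2L, inv_sqrt, "*")       # P^{-1/2} action restricted to range(P)
  M <- crossprod(W, Gm %*% W)
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vectors <- W %*% em$vectors
  # normalise eigenvectors in coordinate space
  vectors <- sweep(vectors, 2L, sqrt(colSums(vectors^2)), "/")
  add_var <- vapply(seq_len(ncol(vectors)), function(k) {
    v <- vectors[, k]
    as.numeric(t(v) %*% Gm %*% v)
  }, numeric(1))
  share <- if (sum(add_var) > 0) add_var / sum(add_var) else add_var
  out <- tibble(rank = seq_along(em$values), eigenvalue = em$values,
                additive_variance_share = share)
  class(out) <- c("heritability_spectrum", class(out))
  attr(out, "vectors") <- vectors
  out
}

#' Write a heritability spectrum as TSV
#' @param spectrum A `heritability_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heritability_spectrum <- function(spectrum, path) {
  readr::write_tsv(as_tibble(spectrum), path)
  invisible(path)
}
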