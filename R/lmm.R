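#' Genomic relatedness matrix, optionally leave-one-chromosome-out
#'
#' `K = Z Z' / M` over the included markers, where the columns of `Z` are
#' centred and scaled to unit variance. Monomorphic markers are skipped (and
#' counted). With `exclude_chromosome`, markers on that chromosome are left
#' out (LOCO), so the relatedness correction in a scan is independent of the
#' chromosome being tested.
#'
#' @param dosages A `dosage_matrix` (or a plain numeric matrix, in which case
#'   `exclude_chromosome` must be `NULL`).
#' @param exclude_chromosome Chromosome label to leave out, or `NULL`.
#' @return An object of class `grm`: list with `K` (n x n),
#'   `excluded_chromosome`, `n_markers_used`, `n_monomorphic`.
#' @export
genomic_relatedness <- function(dosages, exclude_chromosome = NULL) {
  if (inherits(dosages, "dosage_matrix")) {
    x <- dosages$dosages
    map <- dosages$map
  } else {
    x <- as.matrix(dosages)
    map <- NULL
    if (!is.null(exclude_chromosome)) {
      abort("Need a dosage_matrix with a marker map to exclude a chromosome.")
    }
  }
  keep <- rep(TRUE, ncol(x))
  if (!is.null(exclude_chromosome)) {
    keep <- map$chrom != exclude_chromosome
  }
  sds <- apply(x[, keep, drop = FALSE], 2L, sd)
  poly <- sds > 0
  n_mono <- sum(!poly)
  z <- x[, keep, drop = FALSE][, poly, drop = FALSE]
  m <- ncol(z)
  if (m == 0L) abort("No polymorphic markers left to build the GRM.")
  z <- scale(z)
  K <- tcrossprod(z) / m
  structure(list(K = K, excluded_chromosome = exclude_chromosome,
                 n_markers_used = m, n_monomorphic = n_mono),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  excl <- x$excluded_chromosome %||% "none"
  cat(sprintf("<grm> %d x %d from %d markers (excluded chromosome: %s)\n",
              nrow(x$K), ncol(x$K), x$n_markers_used, excl))
  invisible(x)
}

distance_values <- function(d) {
  if (inherits(d, "distance_set") || is.data.frame(d)) d[["d"]] else as.numeric(d)
}

#' Null linear mixed model for a distance phenotype
#'
#' REML fit of `d = mean + g + e` with `g ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)`. The restricted likelihood is profiled over the
#' heritability ratio on the eigenbasis of the GRM after projecting out the
#' intercept, so the fit is exact and fast. When `K` is numerically
#' proportional to the identity the two components are not separately
#' identifiable and a warning is raised.
#'
#' @param d A `distance_set` or numeric phenotype vector.
#' @param K A `grm` (or plain covariance matrix).
#' @return An object of class `lmm_null`: list with `sigma_g2`, `sigma_e2`,
#'   `h2`, `loglik` (restricted), `V` (phenotypic covariance) and
#'   `identifiable`.
#' @export
fit_lmm_null <- function(d, K) {
  y <- distance_values(d)
  Km <- if (inherits(K, "grm")) K$K else as.matrix(K)
  n <- length(y)
  if (n < 10L) abort("Need at least 10 individuals for the mixed model.")
  if (nrow(Km) != n) abort("GRM dimension does not match the phenotype.")

  # contrasts orthogonal to the intercept: exact REML on n - 1 dimensions
  Tm <- qr.Q(qr(matrix(1, n, 1L)), complete = TRUE)[, -1L, drop = FALSE]
  Kp <- crossprod(Tm, Km %*% Tm)
  eig <- eigen((Kp + t(Kp)) / 2, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  ytil <- crossprod(eig$vectors, crossprod(Tm, y))[, 1L]
  m <- n - 1L

  identifiable <- sd(lambda) > 1e-6 * max(mean(lambda), 1e-12)
  if (!identifiable) {
    warn("GRM is numerically proportional to the identity: sigma_g2 and sigma_e2 are not separately identifiable.")
  }

  negrll <- function(h) {
    wts <- h * lambda + (1 - h)
    0.5 * (sum(log(wts)) + m * log(sum(ytil^2 / wts) / m))
  }
  opt <- optimize(negrll, c(0, 0.999))
  # compare against the boundary h = 0 explicitly
  h <- if (negrll(0) <= opt$objective) 0 else opt$minimum
  wts <- h * lambda + (1 - h)
  s_tot <- sum(ytil^2 / wts) / m
  sigma_g2 <- h * s_tot
  sigma_e2 <- (1 - h) * s_tot
  rll <- -negrll(h) - 0.5 * m * (1 + log(2 * pi))
  V <- sigma_g2 * Km + sigma_e2 * diag(n)
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 h2 = sigma_g2 / (sigma_g2 + sigma_e2),
                 loglik = rll, V = V, identifiable = identifiable),
            class = "lmm_null")
}

#' @export
print.lmm_null <- function(x, ...) {
  cat(sprintf("<lmm_null> sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
              x$sigma_g2, x$sigma_e2, x$h2))
  invisible(x)
}

#' Whiten phenotype and genotypes by the phenotypic covariance
#'
#' Premultiplies phenotype and genotype columns by `V^{-1/2}`, giving a
#' linear model with uncorrelated unit-variance errors; OLS on the whitened
#' data is exactly GLS on the original data.
#'
#' @param V Positive-definite phenotypic covariance matrix (or an `lmm_null`
#'   fit, whose `V` is used).
#' @param d Phenotype (`distance_set` or numeric vector).
#' @param X Optional matrix of genotype (or covariate) columns.
#' @return List with `d` (whitened phenotype), `X` (whitened columns or
#'   `NULL`), `ones` (whitened intercept column) and `W` (the `V^{-1/2}`
#'   matrix).
#' @export
whiten <- function(V, d, X = NULL) {
  if (inherits(V, "lmm_null")) V <- V$V
  V <- as.matrix(V)
  y <- distance_values(d)
  eig <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (any(eig$values <= 0)) {
    abort("V is not positive definite; cannot whiten.")
  }
  W <- eig$vectors %*% (t(eig$vectors) / sqrt(eig$values))
  list(d = as.numeric(W %*% y),
       X = if (!is.null(X)) W %*% as.matrix(X) else NULL,
       ones = as.numeric(W %*% rep(1, length(y))),
       W = W)
}
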