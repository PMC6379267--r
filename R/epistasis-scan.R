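#' Precompute the standardized-genotype basis for epistatic kernels
#'
#' Centres and scales the dosage columns and stores their cross-product, so
#' that each marker's leave-one-out GRM is obtained by a rank-one downdate
#' instead of a fresh matrix product.
#'
#' @param dosages A `dosage_matrix` or numeric matrix.
#' @return An object of class `epistasis_basis`.
#' @export
epistasis_basis <- function(dosages) {
  x <- if (inherits(dosages, "dosage_matrix")) dosages$dosages else as.matrix(dosages)
  if (ncol(x) < 2L) abort("Need at least 2 markers.")
  sds <- apply(x, 2L, sd)
  z <- x
  poly <- sds > 0
  z[, poly] <- scale(x[, poly, drop = FALSE])
  z[, !poly] <- 0
  structure(list(Z = z, ZZt = tcrossprod(z), M = sum(poly), poly = poly,
                 markers = colnames(x) %||% sprintf("m%d", seq_len(ncol(x)))),
            class = "epistasis_basis")
}

#' Marginal epistatic kernel of a focal marker
#'
#' `K_j = (x_j x_j') o K_{-j}` (elementwise product), where `x_j` is the
#' standardized dosage of the focal marker and `K_{-j}` the standardized
#' cross-product GRM of all other markers. Under a variance-component model
#' this kernel carries the combined pairwise interaction effect of marker
#' `j` with the rest of the genome.
#'
#' @param j Marker index or name.
#' @param dosages A `dosage_matrix`, numeric matrix, or prebuilt
#'   [epistasis_basis()].
#' @return An object of class `epistatic_kernel`: list with `K` (n x n
#'   symmetric PSD matrix), `marker`, `zero` (TRUE when the focal marker is
#'   monomorphic and the kernel is identically zero).
#' @export
epistatic_kernel <- function(j, dosages) {
  basis <- if (inherits(dosages, "epistasis_basis")) dosages else epistasis_basis(dosages)
  if (is.character(j)) j <- match(j, basis$markers)
  j <- check_count(j, "j", 1L)
  if (j > ncol(basis$Z)) abort("Marker index out of range.")
  zj <- basis$Z[, j]
  if (!basis$poly[j] || all(zj == 0)) {
    warn("Focal marker is monomorphic: kernel is identically zero.")
    Kj <- matrix(0, nrow(basis$Z), nrow(basis$Z))
    return(structure(list(K = Kj, marker = basis$markers[j], zero = TRUE),
                     class = "epistatic_kernel"))
  }
  m_rest <- basis$M - 1L
  if (m_rest < 1L) abort("Need at least one other polymorphic marker.")
  K_minus <- (basis$ZZt - tcrossprod(zj)) / m_rest
  Kj <- tcrossprod(zj) * K_minus
  Kj <- (Kj + t(Kj)) / 2
  structure(list(K = Kj, marker = basis$markers[j], zero = FALSE),
            class = "epistatic_kernel")
}

#' Variance-component score test for marginal epistasis
#'
#' Score test of `sigma_epi^2 = 0` in
#' `d = X beta + g_epi + e`, `g_epi ~ N(0, sigma_epi^2 K_j)`: with null OLS
#' residuals `r` and error variance `s2`, the statistic is
#' `q = r' K_j r / (2 s2^2)` and its null distribution is the weighted sum
#' of chi-square(1) variables with weights the nonzero eigenvalues of
#' `P0 K_j P0 / (2 s2)` (`P0` the fixed-effects residual projector). The
#' p-value comes from [davies_pvalue()].
#'
#' @param d Phenotype (`distance_set` or numeric vector).
#' @param kernel An `epistatic_kernel` (or plain PSD matrix).
#' @param X Fixed-effects design matrix; defaults to intercept plus the
#'   focal dosage when `x_j` is supplied.
#' @param x_j Optional focal-marker dosage used as a covariate.
#' @return An object of class `score_test_result`: list with `marker`, `q`,
#'   `weights`, `p_davies`.
#' @export
variance_component_score_test <- function(d, kernel, X = NULL, x_j = NULL) {
  y <- distance_values(d)
  n <- length(y)
  Kj <- if (inherits(kernel, "epistatic_kernel")) kernel$K else as.matrix(kernel)
  marker <- if (inherits(kernel, "epistatic_kernel")) kernel$marker else NA_character_
  if (nrow(Kj) != n) abort("Kernel and phenotype are not aligned.")
  if (is.null(X)) {
    X <- if (!is.null(x_j) && sd(x_j) > 0) cbind(1, x_j) else cbind(rep(1, n))
  }
  X <- as.matrix(X)
  fit <- lm.fit(X, y)
  r <- fit$residuals
  p_fixed <- fit$rank
  s2 <- sum(r^2) / (n - p_fixed)

  if (all(abs(Kj) < .Machine$double.eps)) {
    return(structure(list(marker = marker, q = 0, weights = numeric(),
                          p_davies = 1),
                     class = "score_test_result"))
  }
  qstat <- as.numeric(crossprod(r, Kj %*% r)) / (2 * s2^2)
  if (!is.finite(qstat)) {
    abort(sprintf("Non-finite score statistic (s2 = %.3g, kernel norm = %.3g).",
                  s2, norm(Kj, "F")))
  }
  # P0 K P0 via residualising the kernel on the fixed effects
  Qx <- qr.Q(qr(X))
  KP <- Kj - Qx %*% crossprod(Qx, Kj)
  PKP <- KP - (KP %*% Qx) %*% t(Qx)
  ev <- eigen((PKP + t(PKP)) / 2, symmetric = TRUE, only.values = TRUE)$values
  wts <- ev[abs(ev) > 1e-10 * max(abs(ev))] / (2 * s2)
  pval <- if (length(wts) == 0L) 1 else davies_pvalue(qstat, wts)
  structure(list(marker = marker, q = qstat, weights = wts, p_davies = pval),
            class = "score_test_result")
}

#' @export
print.score_test_result <- function(x, ...) {
  cat(sprintf("<score_test_result> marker %s: q = %.4g, p = %.3g\n",
              x$marker, x$q, x$p_davies))
  invisible(x)
}

#' Genome-wide marginal-epistasis screen
#'
#' Runs [variance_component_score_test()] for every marker against the
#' distance phenotype (conventionally Mahalanobis distances from the overall
#' mean shape at this stage). No population-structure correction is applied.
#'
#' @param d Phenotype (`distance_set` or numeric vector).
#' @param dosages A `dosage_matrix` or matrix.
#' @param markers Optional subset of marker names/indices to test.
#' @return Tibble with columns `marker`, `q`, `p_davies`.
#' @export
epistasis_screen <- function(d, dosages, markers = NULL) {
  basis <- epistasis_basis(dosages)
  y <- distance_values(d)
  idx <- if (is.null(markers)) {
    seq_along(basis$markers)
  } else if (is.character(markers)) {
    match(markers, basis$markers)
  } else {
    as.integer(markers)
  }
  raw <- if (inherits(dosages, "dosage_matrix")) dosages$dosages else as.matrix(dosages)
  res <- purrr::map(idx, function(j) {
    kern <- withCallingHandlers(
      epistatic_kernel(j, basis),
      warning = function(w) invokeRestart("muffleWarning"))
    st <- variance_component_score_test(y, kern, x_j = raw[, j])
    tibble(marker = basis$markers[j], q = st$q, p_davies = st$p_davies)
  })
  dplyr::bind_rows(res)
}

#' Select screening candidates
#'
#' @param results Tibble from [epistasis_screen()] (columns `marker`,
#'   `p_davies`).
#' @param threshold Screening p-value threshold (default 1e-6).
#' @return The subset with `p_davies < threshold`, ordered by p-value.
#' @export
screen_markers <- function(results, threshold = 1e-6) {
  if (nrow(results) == 0L) abort("Empty screening results.")
  dplyr::arrange(dplyr::filter(results, .data$p_davies < threshold),
                 .data$p_davies)
}

#' Pairwise epistatic follow-up on residual distances
#'
#' For every unordered pair of candidate markers, fits the multivariate mean
#' model with terms `a_j`, `a_k` and `a_j * a_k` on the shape scores,
#' computes residual Mahalanobis distances from the pair-specific residual
#' covariance, and tests the interaction term of the linear model
#' `d ~ a_j + a_k + a_j:a_k`. Pairs with nearly collinear dosages
#' (`r^2 > 0.99`) are skipped and flagged.
#'
#' @param Y Symmetric shape scores (individuals x dimensions).
#' @param candidates Character or integer vector of at least two distinct
#'   candidate markers.
#' @param dosages A `dosage_matrix`.
#' @param alpha Significance level for flagging interactions (default
#'   0.001).
#' @param metric `"mahalanobis"` (default) or `"euclidean"` distances.
#' @return Tibble of class `interaction_table` with columns `marker_j`,
#'   `marker_k`, `estimate`, `p`, `significant`, `skipped`.
#' @export
pairwise_interaction_scan <- function(Y, candidates, dosages, alpha = 0.001,
                                      metric = c("mahalanobis", "euclidean")) {
  metric <- match.arg(metric)
  Y <- as.matrix(Y)
  x <- if (inherits(dosages, "dosage_matrix")) dosages$dosages else as.matrix(dosages)
  nm <- colnames(x) %||% sprintf("m%d", seq_len(ncol(x)))
  if (is.character(candidates)) candidates <- match(candidates, nm)
  candidates <- as.integer(candidates)
  if (anyDuplicated(candidates)) {
    abort("Self-interaction requested: candidate markers must be distinct.")
  }
  if (length(candidates) < 2L) abort("Need at least 2 candidate markers.")
  pairs <- combn(candidates, 2L)
  rows <- purrr::map(seq_len(ncol(pairs)), function(i) {
    j <- pairs[1L, i]
    k <- pairs[2L, i]
    aj <- x[, j]
    ak <- x[, k]
    if (sd(aj) == 0 || sd(ak) == 0 || cor(aj, ak)^2 > 0.99) {
      return(tibble(marker_j = nm[j], marker_k = nm[k],
                    estimate = NA_real_, p = NA_real_,
                    significant = FALSE, skipped = TRUE))
    }
    X <- cbind(1, aj, ak, aj * ak)
    mfit <- lm.fit(X, Y)
    # studentize: high-leverage genotype combinations otherwise get
    # systematically shrunken residual distances, inflating the interaction
    lev <- rowSums(qr.Q(qr(X))^2)
    rstd <- mfit$residuals / sqrt(pmax(1 - lev, .Machine$double.eps))
    model <- structure(list(mu = mfit$coefficients[1L, ], alpha = NULL,
                            fitted = X %*% mfit$coefficients,
                            residuals = rstd, a = NULL),
                       class = "marker_mean_model")
    D <- if (metric == "mahalanobis") residual_covariance(model = model) else NULL
    dset <- residual_distance(Y, model, D = D)
    fit <- lm(d ~ aj + ak + aj:ak, data = data.frame(d = dset$d, aj = aj, ak = ak))
    sm <- summary(fit)$coefficients
    row <- sm[rownames(sm) == "aj:ak", , drop = FALSE]
    est <- if (nrow(row)) row[1L, 1L] else NA_real_
    pv <- if (nrow(row)) row[1L, 4L] else NA_real_
    tibble(marker_j = nm[j], marker_k = nm[k], estimate = est, p = pv,
           significant = !is.na(pv) && pv < alpha, skipped = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("interaction_table", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Write screening / interaction tables as TSV
#' @param x Tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
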