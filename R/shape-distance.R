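#' Genotype-conditional mean-shape model
#'
#' Fits the multivariate linear model `y_i = mu + a_i * alpha + error` by
#' least squares, where `y_i` is an individual's symmetric shape (tangent
#' coordinates or PC scores) and `a_i` its allele dosage at a focal marker.
#' With `a = NULL` the model is intercept-only and the fitted mean is the
#' column-mean shape. Conditioning on the marker's mean effect is what keeps
#' the downstream residual-distance statistics from mistaking a mean shift
#' of an unbalanced genotype class for excess variance.
#'
#' @param Y Numeric matrix (individuals x shape dimensions).
#' @param a Optional allele-dosage vector (values in `[0, 2]`, continuous
#'   dosages accepted).
#' @return An object of class `marker_mean_model`: list with `mu`, `alpha`
#'   (NULL for intercept-only), `fitted`, `residuals`, `a`.
#' @export
fit_marker_mean_model <- function(Y, a = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (!is.null(a)) {
    if (length(a) != n) abort("Length of `a` must match rows of `Y`.")
    if (sd(a) == 0) abort("Constant dosage vector: model is collinear.")
    X <- cbind(1, a)
    fit <- lm.fit(X, Y)
    coefs <- fit$coefficients
    mu <- coefs[1L, ]
    alpha <- coefs[2L, ]
    fitted <- X %*% coefs
  } else {
    mu <- colMeans(Y)
    alpha <- NULL
    fitted <- matrix(mu, n, ncol(Y), byrow = TRUE)
  }
  structure(
    list(mu = mu, alpha = alpha, fitted = fitted,
         residuals = Y - fitted, a = a),
    class = "marker_mean_model"
  )
}

#' @export
print.marker_mean_model <- function(x, ...) {
  kind <- if (is.null(x$alpha)) "intercept-only" else "additive marker"
  cat(sprintf("<marker_mean_model> %s, %d individuals, %d dimensions\n",
              kind, nrow(x$residuals), ncol(x$residuals)))
  invisible(x)
}

#' Residual covariance matrix of a mean-shape model
#'
#' `S[j, k] = sum_i (y_ij - m_ij) (y_ik - m_ik) / (n - 1)` over the model's
#' residuals.
#'
#' @param Y Data matrix used to fit `model` (optional; residuals are taken
#'   from the model).
#' @param model A `marker_mean_model`.
#' @return An object of class `residual_covariance`: list with `S`, `rank`
#'   and the eigen decomposition used for inversion.
#' @export
residual_covariance <- function(Y = NULL, model) {
  stopifnot(inherits(model, "marker_mean_model"))
  r <- model$residuals
  n <- nrow(r)
  if (n < 2L) abort("Need at least 2 individuals to estimate a covariance.")
  S <- crossprod(r) / (n - 1)
  new_residual_covariance(S)
}

new_residual_covariance <- function(S) {
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  lead <- max(eig$values, 0)
  rank <- sum(eig$values > 1e-8 * max(lead, .Machine$double.eps))
  structure(list(S = S, rank = rank, eigenvalues = eig$values,
                 eigenvectors = eig$vectors),
            class = "residual_covariance")
}

#' @export
print.residual_covariance <- function(x, ...) {
  cat(sprintf("<residual_covariance> %d x %d, rank %d\n",
              nrow(x$S), ncol(x$S), x$rank))
  invisible(x)
}

# Inverse (or pseudo/ridge inverse) action of D on residual rows.
apply_inverse_metric <- function(r, D, inverse_mode, ridge = 1e-4) {
  eig_vals <- D$eigenvalues
  lead <- max(eig_vals, .Machine$double.eps)
  if (inverse_mode == "full") {
    if (D$rank < length(eig_vals)) {
      abort(sprintf(
        "Covariance is singular (rank %d of %d); use inverse_mode 'pseudo' or 'ridge'.",
        D$rank, length(eig_vals)))
    }
    inv <- 1 / eig_vals
  } else if (inverse_mode == "pseudo") {
    keep <- eig_vals > 1e-8 * lead
    inv <- ifelse(keep, 1 / eig_vals, 0)
  } else {
    inv <- 1 / (eig_vals + ridge * lead)
  }
  proj <- r %*% D$eigenvectors
  rowSums(sweep(proj^2, 2L, inv, "*"))
}

#' Residual shape distances (canalization statistic)
#'
#' Per-individual distance `d_i = (y_i - m_i)' D^{-1} (y_i - m_i)` between
#' each shape and its genotype-conditional predicted mean. With `D` the
#' identity this is the (squared) Euclidean distance; with `D` the residual
#' covariance it is the Mahalanobis distance, which up-weights deviations in
#' directions of low population variance. The default returns the square
#' root (a true distance); `squared = TRUE` returns the quadratic form as
#' printed.
#'
#' @param Y Data matrix used to fit `model`.
#' @param model A `marker_mean_model`.
#' @param D A `residual_covariance`, or `NULL` for the Euclidean metric.
#' @param squared Return the quadratic form instead of its square root.
#' @param inverse_mode How to invert `D`: `"full"` (error if singular),
#'   `"pseudo"` (PC-truncated pseudo-inverse, default) or `"ridge"`.
#' @return An object of class `distance_set`: tibble with columns `id`, `d`,
#'   plus attributes `metric`, `squared`, `model_tag`.
#' @export
residual_distance <- function(Y = NULL, model, D = NULL, squared = FALSE,
                              inverse_mode = c("pseudo", "full", "ridge")) {
  stopifnot(inherits(model, "marker_mean_model"))
  inverse_mode <- match.arg(inverse_mode)
  r <- model$residuals
  if (is.null(D)) {
    d2 <- rowSums(r^2)
    metric <- "euclidean"
  } else {
    stopifnot(inherits(D, "residual_covariance"))
    if (ncol(D$S) != ncol(r)) abort("Metric dimension does not match residuals.")
    d2 <- apply_inverse_metric(r, D, inverse_mode)
    metric <- "mahalanobis"
  }
  d2 <- pmax(d2, 0)
  tag <- if (is.null(model$alpha)) "intercept" else "marker"
  new_distance_set(sqrt_or_not(d2, squared),
                   ids = rownames(r) %||% sprintf("ind_%d", seq_len(nrow(r))),
                   metric = metric, squared = squared, model_tag = tag)
}

sqrt_or_not <- function(d2, squared) if (squared) d2 else sqrt(d2)

new_distance_set <- function(d, ids, metric, squared, model_tag) {
  out <- tibble(id = ids, d = as.numeric(d))
  class(out) <- c("distance_set", class(out))
  attr(out, "metric") <- metric
  attr(out, "squared") <- squared
  attr(out, "model_tag") <- model_tag
  out
}

#' Fluctuating-asymmetry distances (developmental-stability statistic)
#'
#' Per-individual distance of the asymmetric (FA) shape component from the
#' mean asymmetry (directional asymmetry), using the same metric machinery
#' as [residual_distance()].
#'
#' @param decomposition A `symmetry_decomposition`.
#' @param metric `"mahalanobis"` (default) or `"euclidean"`.
#' @inheritParams residual_distance
#' @return A `distance_set`.
#' @export
fa_distance <- function(decomposition, metric = c("mahalanobis", "euclidean"),
                        squared = FALSE,
                        inverse_mode = c("pseudo", "full", "ridge")) {
  stopifnot(inherits(decomposition, "symmetry_decomposition"))
  metric <- match.arg(metric)
  inverse_mode <- match.arg(inverse_mode)
  A <- decomposition$asymmetric
  model <- fit_marker_mean_model(A, a = NULL)
  tot <- sum(model$residuals^2)
  if (tot < .Machine$double.eps * length(A)) {
    warn("Zero asymmetric variance: all FA distances are 0.")
    return(new_distance_set(rep(0, nrow(A)),
                            ids = rownames(A) %||% sprintf("ind_%d", seq_len(nrow(A))),
                            metric = metric, squared = squared,
                            model_tag = "fa"))
  }
  D <- if (metric == "mahalanobis") residual_covariance(model = model) else NULL
  out <- residual_distance(A, model, D = D, squared = squared,
                           inverse_mode = inverse_mode)
  attr(out, "model_tag") <- "fa"
  out
}

#' Write a distance set as TSV
#' @param distances A `distance_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_set <- function(distances, path) {
  out <- as_tibble(distances)
  out$metric <- attr(distances, "metric")
  out$model_tag <- attr(distances, "model_tag")
  out$squared <- attr(distances, "squared")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a covariance matrix as square TSV with headers
#' @param S Matrix, `residual_covariance` or `cov_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_covariance_tsv <- function(S, path) {
  m <- if (inherits(S, "residual_covariance")) S$S
       else if (inherits(S, "cov_matrix")) S$matrix
       else as.matrix(S)
  nm <- colnames(m) %||% sprintf("dim%d", seq_len(ncol(m)))
  out <- as_tibble(m, .name_repair = "minimal")
  names(out) <- nm
  readr::write_tsv(dplyr::bind_cols(tibble(.dim = nm), out), path)
  invisible(path)
}
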