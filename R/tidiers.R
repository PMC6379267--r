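#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidiers
#' @title Broom-style tidiers for shaperobust objects
#' @description `tidy()` returns one row per estimated quantity; `glance()`
#'   returns a one-row model summary.
#' @param x A fitted shaperobust object.
#' @param ... Unused.
#' @export
tidy.lmm_null <- function(x, ...) {
  tibble(term = c("sigma_g2", "sigma_e2", "h2"),
         estimate = c(x$sigma_g2, x$sigma_e2, x$h2))
}

#' @rdname tidiers
#' @export
glance.lmm_null <- function(x, ...) {
  tibble(sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2, h2 = x$h2,
         logLik = x$loglik, identifiable = x$identifiable)
}

#' @rdname tidiers
#' @export
tidy.marker_mean_model <- function(x, ...) {
  if (is.null(x$alpha)) {
    tibble(term = "mu", dimension = seq_along(x$mu), estimate = x$mu)
  } else {
    dplyr::bind_rows(
      tibble(term = "mu", dimension = seq_along(x$mu), estimate = x$mu),
      tibble(term = "alpha", dimension = seq_along(x$alpha), estimate = x$alpha)
    )
  }
}

#' @rdname tidiers
#' @export
tidy.score_test_result <- function(x, ...) {
  tibble(marker = x$marker, q = x$q, p_davies = x$p_davies,
         n_weights = length(x$weights))
}

#' @rdname tidiers
#' @export
tidy.krzanowski_subspace <- function(x, ...) {
  ang <- as_tibble(x$delta_angles, .name_repair = "minimal")
  names(ang) <- sprintf("delta_%s", x$labels)
  dplyr::bind_cols(tibble(rank = seq_along(x$Delta), Delta = x$Delta), ang)
}

#' @rdname tidiers
#' @export
glance.krzanowski_subspace <- function(x, ...) {
  tibble(k = x$k, n_matrices = length(x$labels), max_Delta = max(x$Delta),
         trace_H = sum(diag(x$H)))
}

#' @rdname tidiers
#' @export
tidy.threshold_set <- function(x, ...) {
  tibble(level = names(x$thresholds), threshold = unname(x$thresholds))
}

#' @rdname tidiers
#' @export
glance.symmetry_decomposition <- function(x, ...) {
  tibble(n = nrow(x$symmetric), n_landmarks = x$map$n_landmarks,
         n_pairs = nrow(x$map$pairs), n_midline = length(x$map$midline),
         symmetric_variance = sum(apply(x$symmetric, 2L, var)),
         asymmetric_variance = sum(apply(x$asymmetric, 2L, var)),
         n_iter = x$n_iter)
}
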