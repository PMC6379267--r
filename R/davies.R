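#' Tail probability of a weighted sum of chi-square(1) variables
#'
#' Computes `P(sum_i w_i X_i > q)` for independent `X_i ~ chi-square(1)` by
#' numerical inversion of the characteristic function (Imhof's integral),
#' the classic machinery behind Davies-method p-values for variance-component
#' score tests. When the integral cannot resolve a very small tail (below
#' the tolerance floor) a Kuonen saddlepoint approximation is used instead,
#' so p-values never collapse to zero.
#'
#' @param q Observed statistic (scalar).
#' @param weights Numeric vector of weights (mixture eigenvalues); zeros are
#'   dropped, negative weights are allowed.
#' @param tol Absolute accuracy requested from the integration (default
#'   1e-9).
#' @return A probability in (0, 1].
#' @export
davies_pvalue <- function(q, weights, tol = 1e-9) {
  q <- check_number(q, "q")
  weights <- as.numeric(weights)
  big <- max(abs(weights), 0)
  weights <- weights[abs(weights) > 1e-14 * max(big, .Machine$double.eps)]
  if (length(weights) == 0L) {
    abort("All weights are zero: the mixture distribution is degenerate.")
  }
  if (q <= 0 && all(weights > 0)) return(1)

  # Ruben's mixture-of-central-chi-squares series: exact (to `tol`) and fast
  # when all weights are positive with a modest spread; covers the
  # equal-weight case with machine precision.
  if (all(weights > 0) && max(weights) / min(weights) <= 1e3) {
    p <- ruben_pvalue(q, weights, tol = min(tol, 1e-10))
    if (!is.na(p) && p > max(tol, 1e-12)) {
      return(min(max(p, .Machine$double.xmin), 1))
    }
    sp <- saddlepoint_pvalue(q, weights)
    if (!is.na(sp)) return(min(max(sp, .Machine$double.xmin), 1))
  }

  integrand <- function(u) {
    out <- numeric(length(u))
    pos <- u > 0
    if (any(pos)) {
      up <- u[pos]
      theta <- 0.5 * colSums(atan(outer(weights, up))) - 0.5 * q * up
      log_rho <- 0.25 * colSums(log1p(outer(weights^2, up^2)))
      out[pos] <- sin(theta) / (up * exp(log_rho))
    }
    out[!pos] <- 0.5 * (sum(weights) - q)
    out
  }
  p <- tryCatch({
    val <- integrate(integrand, 0, Inf, abs.tol = tol, rel.tol = tol,
                     subdivisions = 2000L, stop.on.error = FALSE)
    0.5 + val$value / pi
  }, error = function(e) NA_real_)

  if (is.na(p) || p < max(tol, 1e-12) || p > 1) {
    sp <- saddlepoint_pvalue(q, weights)
    if (!is.na(sp)) p <- sp
  }
  min(max(p, .Machine$double.xmin), 1)
}

# Ruben (1962) series: with beta = min(lambda), the quadratic form is a
# mixture of central chi-squares with nonnegative mixing weights a_k summing
# to one, so the truncation error is bounded by the unassigned mass.
ruben_pvalue <- function(q, lambda, tol = 1e-10, max_terms = 10000L) {
  h <- length(lambda)
  beta <- min(lambda)
  ratio <- 1 - beta / lambda
  a <- numeric(max_terms + 1L)
  b <- numeric(max_terms)
  a[1L] <- exp(0.5 * sum(log(beta / lambda)))
  pow <- rep(1, h)
  surv <- pchisq(q / beta, df = h, lower.tail = FALSE)
  total_a <- a[1L]
  p <- a[1L] * surv
  for (k in seq_len(max_terms)) {
    pow <- pow * ratio
    b[k] <- sum(pow)
    a[k + 1L] <- sum(b[seq_len(k)] * a[k:1L]) / (2 * k)
    total_a <- total_a + a[k + 1L]
    p <- p + a[k + 1L] * pchisq(q / beta, df = h + 2 * k, lower.tail = FALSE)
    if (1 - total_a < tol) return(min(max(p, 0), 1))
  }
  NA_real_
}

# Kuonen (1999) saddlepoint approximation to the same tail probability.
saddlepoint_pvalue <- function(q, weights) {
  if (q <= 0) return(1)
  mu <- sum(weights)
  if (abs(q - mu) < 1e-10 * max(abs(mu), 1)) return(0.5)
  kprime <- function(z) sum(weights / (1 - 2 * z * weights))
  upper <- if (any(weights > 0)) 1 / (2 * max(weights)) else Inf
  lower <- if (any(weights < 0)) 1 / (2 * min(weights)) else -Inf
  eps <- 1e-10
  lo <- max(lower + eps, -1e6)
  hi <- min(upper - eps, 1e6)
  root <- tryCatch(
    stats::uniroot(function(z) kprime(z) - q, c(lo, hi), tol = 1e-12)$root,
    error = function(e) NA_real_)
  if (is.na(root)) return(NA_real_)
  kval <- -0.5 * sum(log1p(-2 * root * weights))
  kpp <- sum(2 * weights^2 / (1 - 2 * root * weights)^2)
  w <- sign(root) * sqrt(max(2 * (root * q - kval), 0))
  v <- root * sqrt(kpp)
  if (abs(w) < 1e-8 || v == 0) return(0.5)
  pnorm(w + log(v / w) / w, lower.tail = FALSE)
}
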