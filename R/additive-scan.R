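# Vectorised per-marker simple regression with an intercept, on already
# whitened data. `d` may be a matrix (columns = phenotype replicates or
# permutations); returns M x B matrices.
marker_regression <- function(d, ones, X) {
  d <- as.matrix(d)
  n <- nrow(d)
  c0 <- sum(ones^2)
  dres <- d - ones %*% (crossprod(ones, d) / c0)
  Xres <- X - ones %*% (crossprod(ones, X) / c0)
  sxx <- colSums(Xres^2)
  sxy <- crossprod(Xres, dres)            # M x B
  syy <- colSums(dres^2)                  # B
  ok <- sxx > .Machine$double.eps * n
  slope <- sweep(sxy, 1L, ifelse(ok, sxx, NA_real_), "/")
  rss <- pmax(outer(rep(1, length(sxx)), syy) - slope^2 * sxx, 0)
  df <- n - 2L
  se <- sqrt(sweep(rss / df, 1L, ifelse(ok, sxx, NA_real_), "/"))
  tstat <- slope / se
  logp <- (pt(abs(tstat), df, lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
  list(slope = slope, se = se, neg_log10_p = -logp, ok = ok)
}

#' Additive genome scan on a distance phenotype
#'
#' For each chromosome, a leave-one-chromosome-out GRM is built, the null
#' mixed model is fitted to the distances, both phenotype and dosages are
#' whitened by the fitted phenotypic covariance, and every marker on the
#' chromosome is tested by simple linear regression of the corrected
#' distances on the corrected dosage (two-sided t test). This asks whether
#' individuals far from their genotype-conditional mean shape carry
#' particular alleles — i.e. for additive variance-QTL.
#'
#' @param d A `distance_set` or numeric phenotype, aligned with the rows of
#'   the dosage matrix.
#' @param dosages A `dosage_matrix`.
#' @return An object of class `scan_result`: tibble with columns `marker`,
#'   `chrom`, `pos`, `gamma`, `se`, `neg_log10_p`, `monomorphic`. The
#'   whitened per-chromosome data needed by [permutation_thresholds()] are
#'   attached as an attribute.
#' @export
additive_scan <- function(d, dosages) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  y <- distance_values(d)
  if (length(y) != nrow(dosages$dosages)) {
    abort("Phenotype and dosage matrix must cover the same individuals.")
  }
  chroms <- unique(dosages$map$chrom)
  rows <- list()
  corrected <- list()
  for (cc in chroms) {
    idx <- which(dosages$map$chrom == cc)
    K <- genomic_relatedness(dosages, exclude_chromosome = cc)
    null <- fit_lmm_null(y, K)
    wh <- whiten(null$V, y, dosages$dosages[, idx, drop = FALSE])
    reg <- marker_regression(wh$d, wh$ones, wh$X)
    rows[[cc]] <- tibble(
      marker = dosages$map$marker[idx],
      chrom = cc,
      pos = dosages$map$pos[idx],
      gamma = as.numeric(reg$slope),
      se = as.numeric(reg$se),
      neg_log10_p = as.numeric(reg$neg_log10_p),
      monomorphic = !reg$ok
    )
    corrected[[cc]] <- list(d = wh$d, ones = wh$ones, X = wh$X)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scan_result", class(out))
  attr(out, "corrected") <- corrected
  attr(out, "n") <- length(y)
  out
}

#' Genome-wide significance thresholds by phenotype permutation
#'
#' Permutes the whitened residual distances (genotypes, and hence their LD
#' structure, stay fixed), re-runs the per-marker regressions, and records
#' the genome-wide maximum `-log10 p` of every permutation. The thresholds
#' are interpolation-free empirical quantiles of that null distribution.
#'
#' @param scan A `scan_result` from [additive_scan()].
#' @param n_perm Number of permutations (default 1000).
#' @param levels Genome-wide error levels (default 5\% and 10\%).
#' @param seed Optional seed for the permutation stream.
#' @return An object of class `threshold_set`: list with `thresholds` (named
#'   by level), `n_perm` and the vector of permutation maxima.
#' @export
permutation_thresholds <- function(scan, n_perm = 1000L,
                                   levels = c(0.05, 0.10), seed = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  n_perm <- check_count(n_perm, "n_perm", 1L)
  if (n_perm < 20L) abort("Need at least 20 permutations.")
  corrected <- attr(scan, "corrected")
  n <- attr(scan, "n")
  if (!is.null(seed)) set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n))
  maxima <- rep(-Inf, n_perm)
  for (cc in names(corrected)) {
    co <- corrected[[cc]]
    dp <- matrix(co$d[perm_idx], n, n_perm)
    reg <- marker_regression(dp, co$ones, co$X)
    cmax <- apply(reg$neg_log10_p, 2L, max, na.rm = TRUE)
    maxima <- pmax(maxima, cmax)
  }
  # order-statistic quantile: smallest value with >= (1 - level) mass below
  srt <- sort(maxima)
  thresholds <- vapply(levels, function(l) {
    srt[max(1L, ceiling((1 - l) * n_perm))]
  }, numeric(1))
  names(thresholds) <- sprintf("%g%%", 100 * levels)
  structure(list(thresholds = thresholds, n_perm = n_perm, maxima = maxima),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> %d permutations; thresholds: %s\n", x$n_perm,
              paste(sprintf("%s = %.3f", names(x$thresholds), x$thresholds),
                    collapse = ", ")))
  invisible(x)
}

#' Write scan results / thresholds
#' @param scan A `scan_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_result <- function(scan, path) {
  readr::write_tsv(as_tibble(scan), path)
  invisible(path)
}

#' @rdname write_scan_result
#' @param thresholds A `threshold_set`.
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(
    list(n_perm = thresholds$n_perm,
         thresholds = as.list(thresholds$thresholds)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
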