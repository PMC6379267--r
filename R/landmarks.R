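#' Convert landmark data to a p x 3 x n array
#'
#' Accepts the wide table produced by [write_landmarks()] (one row per
#' individual, columns `L{k}_x`, `L{k}_y`, `L{k}_z`), a plain n x 3p matrix in
#' the same column order, or an array already in p x 3 x n layout.
#'
#' @param x Landmark data.
#' @return A numeric array of dimension `c(p, 3, n)` with dimnames on the
#'   individual margin when available.
#' @export
as_landmark_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[2L] != 3L) abort("Landmark array must be p x 3 x n.")
    return(x)
  }
  if (is.data.frame(x)) {
    ids <- if ("id" %in% names(x)) as.character(x$id) else NULL
    x <- as.matrix(x[setdiff(names(x), "id")])
    rownames(x) <- ids
  }
  if (!is.matrix(x)) abort("Cannot interpret `x` as landmark data.")
  if (ncol(x) %% 3L != 0L) abort("Wide landmark matrix needs 3 columns per landmark.")
  p <- ncol(x) %/% 3L
  n <- nrow(x)
  arr <- array(NA_real_, dim = c(p, 3L, n),
               dimnames = list(NULL, c("x", "y", "z"), rownames(x)))
  for (i in seq_len(n)) arr[, , i] <- unvec_config(x[i, ], p)
  arr
}

landmark_colnames <- function(p) {
  as.vector(t(outer(seq_len(p), c("x", "y", "z"),
                    function(k, a) sprintf("L%d_%s", k, a))))
}

#' Read / write wide-format landmark tables
#'
#' One row per individual; columns `id`, then `L{k}_x`, `L{k}_y`, `L{k}_z`
#' for each landmark `k` in order.
#'
#' @param path File path.
#' @return `read_landmarks()` returns a `p x 3 x n` array;
#'   `write_landmarks()` returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  as_landmark_array(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_landmarks
#' @param coords Landmark data accepted by [as_landmark_array()].
#' @export
write_landmarks <- function(coords, path) {
  arr <- as_landmark_array(coords)
  n <- dim(arr)[3L]
  wide <- t(apply(arr, 3L, vec_config))
  colnames(wide) <- landmark_colnames(dim(arr)[1L])
  ids <- dimnames(arr)[[3L]] %||% sprintf("ind_%d", seq_len(n))
  readr::write_csv(dplyr::bind_cols(tibble(id = ids), as_tibble(wide)), path)
  invisible(path)
}

centroid_size <- function(config) {
  centred <- sweep(config, 2L, colMeans(config))
  sqrt(sum(centred^2))
}
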