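#' Describe the bilateral symmetry of a landmark configuration
#'
#' A symmetry map records which landmarks form left/right pairs, which lie on
#' the midsagittal plane, and which coordinate axis is perpendicular to that
#' plane. It is required by every operation that separates symmetric from
#' asymmetric (fluctuating-asymmetry) shape variation.
#'
#' @param pairs Two-column matrix or data frame of landmark indices; first
#'   column left, second column right.
#' @param midline Integer vector of midline landmark indices.
#' @param reflection_axis Index (1, 2 or 3) of the coordinate axis negated by
#'   the mirror reflection, i.e. the axis perpendicular to the midsagittal
#'   plane. Defaults to 1.
#' @param n_landmarks Optional total landmark count; when given, the map must
#'   cover exactly the indices `1:n_landmarks`.
#'
#' @return An object of class `symmetry_map`: a list with elements `pairs`
#'   (integer matrix), `midline` (integer vector), `reflection_axis`,
#'   `n_landmarks`.
#' @export
symmetry_map <- function(pairs, midline = integer(), reflection_axis = 1L,
                         n_landmarks = NULL) {
  if (is.null(pairs) || length(pairs) == 0L) {
    pairs <- matrix(integer(), ncol = 2L)
  } else {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) abort("`pairs` must have two columns (left, right).")
    storage.mode(pairs) <- "integer"
  }
  midline <- as.integer(midline)
  reflection_axis <- check_count(reflection_axis, "reflection_axis", min = 1L)
  if (reflection_axis > 3L) abort("`reflection_axis` must be 1, 2 or 3.")
  idx <- c(as.integer(pairs), midline)
  if (anyDuplicated(idx)) abort("Landmark indices repeated in the symmetry map.")
  if (length(idx) && any(idx < 1L)) abort("Landmark indices must be positive.")
  total <- length(idx)
  if (!is.null(n_landmarks)) {
    n_landmarks <- check_count(n_landmarks, "n_landmarks", min = 1L)
    if (total != n_landmarks || !setequal(idx, seq_len(n_landmarks))) {
      abort("Symmetry map must cover all landmarks exactly once.")
    }
  } else {
    n_landmarks <- total
    if (!setequal(idx, seq_len(total))) {
      abort("Symmetry map indices must cover 1..n_landmarks without gaps.")
    }
  }
  structure(
    list(pairs = pairs, midline = midline,
         reflection_axis = reflection_axis, n_landmarks = n_landmarks),
    class = "symmetry_map"
  )
}

#' @export
print.symmetry_map <- function(x, ...) {
  cat(sprintf("<symmetry_map> %d landmarks: %d pairs, %d midline; axis %d\n",
              x$n_landmarks, nrow(x$pairs), length(x$midline),
              x$reflection_axis))
  invisible(x)
}

#' Default symmetry map for a pairs-then-midline landmark layout
#'
#' Convenience constructor for configurations ordered as (left_1, right_1,
#' ..., left_P, right_P, midline_1, ..., midline_U), the layout produced by
#' [simulate_base_shape()].
#'
#' @param n_pairs Number of bilateral landmark pairs.
#' @param n_midline Number of midline landmarks.
#' @inheritParams symmetry_map
#' @return A `symmetry_map`.
#' @export
default_symmetry_map <- function(n_pairs, n_midline, reflection_axis = 1L) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  n_midline <- check_count(n_midline, "n_midline")
  pairs <- if (n_pairs > 0L) {
    cbind(seq_len(n_pairs) * 2L - 1L, seq_len(n_pairs) * 2L)
  } else {
    matrix(integer(), ncol = 2L)
  }
  midline <- if (n_midline > 0L) 2L * n_pairs + seq_len(n_midline) else integer()
  symmetry_map(pairs, midline, reflection_axis)
}

#' Read a symmetry map from a TSV file
#'
#' Expects columns `index`, `role` (one of `left`, `right`, `midline`) and
#' `partner` (the paired landmark index; ignored for midline rows).
#'
#' @param path File path.
#' @param reflection_axis Axis perpendicular to the midsagittal plane.
#' @return A `symmetry_map`.
#' @export
read_symmetry_map <- function(path, reflection_axis = 1L) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("index", "role")
  if (!all(need %in% names(tab))) {
    abort("Symmetry map file must have columns `index`, `role` (and `partner`).")
  }
  left <- tab$index[tab$role == "left"]
  partner <- tab$partner[tab$role == "left"]
  midline <- tab$index[tab$role == "midline"]
  symmetry_map(cbind(left, partner), midline, reflection_axis)
}

#' Write a symmetry map as TSV
#' @param map A `symmetry_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_symmetry_map <- function(map, path) {
  stopifnot(inherits(map, "symmetry_map"))
  rows <- dplyr::bind_rows(
    tibble(index = map$pairs[, 1L], role = "left", partner = map$pairs[, 2L]),
    tibble(index = map$pairs[, 2L], role = "right", partner = map$pairs[, 1L]),
    tibble(index = map$midline, role = "midline", partner = NA_integer_)
  )
  readr::write_tsv(dplyr::arrange(rows, .data$index), path)
  invisible(path)
}
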