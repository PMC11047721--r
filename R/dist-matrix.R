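# Labelled symmetric distance matrices are the carrier for every pairwise
# quantity in the package: beta-dissimilarity matrices and the geographic,
# elevational and environmental predictor matrices all share this contract.

#' Validate a pairwise distance matrix
#'
#' Checks the contract every pairwise matrix in the package obeys: square,
#' numeric, symmetric, zero diagonal, finite non-negative entries, and unique
#' site labels on both dimensions.
#'
#' @param d A square numeric matrix with site ids as row and column names.
#' @param arg Name used in error messages.
#' @return `d`, invisibly, if valid; otherwise an error is thrown.
#' @export
check_dist_matrix <- function(d, arg = "d") {
  if (!is.matrix(d) || !is.numeric(d)) {
    stop_sb(sprintf("`%s` must be a numeric matrix.", arg), "invalid_dist")
  }
  if (nrow(d) != ncol(d)) {
    stop_sb(sprintf("`%s` must be square.", arg), "invalid_dist")
  }
  if (is.null(rownames(d)) || anyDuplicated(rownames(d))) {
    stop_sb(sprintf("`%s` needs unique row/column site labels.", arg), "invalid_dist")
  }
  if (!identical(rownames(d), colnames(d))) {
    stop_sb(sprintf("`%s` row and column labels differ.", arg), "invalid_dist")
  }
  if (any(!is.finite(d)) || any(d < 0)) {
    stop_sb(sprintf("`%s` has non-finite or negative entries.", arg), "invalid_dist")
  }
  if (any(abs(diag(d)) > 1e-12)) {
    stop_sb(sprintf("`%s` has a nonzero diagonal.", arg), "invalid_dist")
  }
  if (max(abs(d - t(d))) > 1e-8) {
    stop_sb(sprintf("`%s` is not symmetric.", arg), "invalid_dist")
  }
  invisible(d)
}

new_dist_matrix <- function(values, site_ids) {
  dimnames(values) <- list(site_ids, site_ids)
  diag(values) <- 0
  check_dist_matrix(values)
  values
}

check_same_sites <- function(a, b, arg_a = "a", arg_b = "b") {
  if (!identical(rownames(a), rownames(b))) {
    stop_sb(sprintf("`%s` and `%s` must share the same site ordering.", arg_a, arg_b),
            "site_mismatch")
  }
  invisible(NULL)
}

#' Unfold a distance matrix into its lower-triangle vector
#'
#' Extracts the `n(n-1)/2` below-diagonal entries in column-major order —
#' `(2,1), (3,1), ..., (n,n-1)` — the single vectorisation convention used by
#' every Mantel, regression and partitioning routine in the package.
#'
#' @param d A distance matrix (see [check_dist_matrix()]).
#' @return A numeric vector of length `n(n-1)/2` with a `site_ids` attribute.
#' @seealso [refold()] for the inverse, [pair_tbl()] for a tidy view.
#' @export
#' @examples
#' d <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, dimnames = rep(list(letters[1:3]), 2))
#' unfold(d) # 1 2 3
unfold <- function(d) {
  check_dist_matrix(d)
  v <- d[lower.tri(d)]
  attr(v, "site_ids") <- rownames(d)
  v
}

#' Refold an unfolded vector back into a symmetric distance matrix
#'
#' @param v Numeric vector of length `n(n-1)/2`, ordered as produced by
#'   [unfold()].
#' @param site_ids Site labels; defaults to the `site_ids` attribute of `v`.
#' @return A symmetric zero-diagonal matrix.
#' @export
refold <- function(v, site_ids = attr(v, "site_ids")) {
  if (is.null(site_ids)) stop_sb("`site_ids` required to refold.", "invalid_dist")
  n <- length(site_ids)
  if (length(v) != n * (n - 1L) / 2L) {
    stop_sb("Length of `v` does not match `site_ids`.", "invalid_dist")
  }
  m <- matrix(0, n, n, dimnames = list(site_ids, site_ids))
  m[lower.tri(m)] <- v
  m + t(m)
}

#' Tidy view of a distance matrix
#'
#' @param d A distance matrix.
#' @return A tibble with one row per unordered site pair: `site_a`, `site_b`,
#'   `value`, in [unfold()] order.
#' @export
pair_tbl <- function(d) {
  check_dist_matrix(d)
  ij <- lower_pair_index(nrow(d))
  tibble::tibble(
    site_a = rownames(d)[ij$i],
    site_b = rownames(d)[ij$j],
    value = d[cbind(ij$i, ij$j)]
  )
}

#' Write / read a distance matrix as square CSV
#'
#' The CSV carries site ids in the header row and in a leading `site_id`
#' column, so the file round-trips through [read_dist_matrix()] unchanged.
#'
#' @param d A distance matrix.
#' @param path File path.
#' @return `write_dist_matrix()` returns `path` invisibly;
#'   `read_dist_matrix()` returns the matrix.
#' @export
write_dist_matrix <- function(d, path) {
  check_dist_matrix(d)
  out <- tibble::as_tibble(d)
  out <- dplyr::bind_cols(tibble::tibble(site_id = rownames(d)), out)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tb[, -1L, drop = FALSE])
  new_dist_matrix(m, tb[[1L]])
}
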