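# Distance-decay regression: OLS of one unfolded dissimilarity matrix on
# one unfolded explanatory distance. Descriptive by design — site pairs are
# not independent, so the classical slope t-test is reported with a
# pseudo-replication caveat; inferential weight belongs to the Mantel test.

#' Distance-decay linear regression
#'
#' @param d_y Response dissimilarity matrix.
#' @param d_x Explanatory distance matrix (same site ordering).
#' @return A `decay_fit`: `slope`, `intercept`, `r_squared`, `p_slope`
#'   (classical t-test p, flagged `pseudo_replicated = TRUE` because pairs
#'   share sites), `n` (site pairs), and the unfolded data for plotting.
#' @export
distance_decay <- function(d_y, d_x) {
  check_dist_matrix(d_y, "d_y"); check_dist_matrix(d_x, "d_x")
  check_same_sites(d_y, d_x, "d_y", "d_x")
  yv <- unfold(d_y); xv <- unfold(d_x)
  if (sample_sd(xv) == 0) {
    stop_sb("Explanatory matrix has zero variance.", "degenerate")
  }
  fit <- stats::lm(yv ~ xv)
  sm <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = sm$r.squared,
    p_slope = sm$coefficients[2L, 4L],
    pseudo_replicated = TRUE,
    n = length(yv),
    data = tibble::tibble(distance = xv, dissimilarity = yv)
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Distance-decay OLS over %d site pairs\n  slope %.4g, intercept %.4g, R^2 %.3f, slope p %.3g\n",
    x$n, x$slope, x$intercept, x$r_squared, x$p_slope))
  cat("  (pairs share sites: the t-test p is descriptive; use a Mantel test for inference)\n")
  invisible(x)
}

#' Tidy / glance a distance-decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient; `glance()`: one-row model
#'   summary.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "distance"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, p_slope = x$p_slope, n = x$n,
                 pseudo_replicated = x$pseudo_replicated)
}
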