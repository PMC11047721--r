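# Multiple regression on distance matrices (MRM): OLS of one unfolded
# response matrix on several unfolded, standardized explanatory matrices,
# with matrix-permutation inference (simultaneous row/column relabelling of
# the response, predictors held fixed — the Legendre convention).

#' Standardize a distance matrix over its unfolded entries
#'
#' Z-scores the lower-triangle entries (mean 0, sample SD 1) and refolds,
#' preserving the zero diagonal. This is how explanatory matrices are
#' scaled before MRM so coefficients are comparable.
#'
#' Note the standardized matrix is a general symmetric matrix (entries may
#' be negative); it is a regression design object, not a metric distance.
#'
#' @param d A distance matrix with nonconstant off-diagonal entries.
#' @return A symmetric zero-diagonal matrix whose unfolded entries have
#'   mean 0 and sample SD 1.
#' @export
standardize_matrix <- function(d) {
  check_symmetric(d)
  v <- unfold_sym(d)
  s <- sample_sd(v)
  if (!is.finite(s) || s == 0) {
    stop_sb("Constant distance matrix; cannot standardize.", "constant_matrix")
  }
  m <- refold((v - mean(v)) / s, rownames(d))
  diag(m) <- 0
  m
}

# Internal: symmetric matrix that may carry negative entries (standardized
# predictors) — same checks as check_dist_matrix minus non-negativity.
unfold_sym <- function(d) d[lower.tri(d)]

check_symmetric <- function(d, arg = "d") {
  if (!is.matrix(d) || nrow(d) != ncol(d) || any(!is.finite(d)) ||
      max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12)) {
    stop_sb(sprintf("`%s` must be a finite symmetric zero-diagonal matrix.", arg),
            "invalid_dist")
  }
  invisible(d)
}

#' Multiple regression on distance matrices
#'
#' @param d_y Response distance matrix.
#' @param predictors Named list of explanatory matrices sharing `d_y`'s site
#'   ordering.
#' @param n_perm Number of permutations for the p-values (default 9999).
#' @param seed Optional integer seed for reproducible permutations.
#' @param standardize Standardize each explanatory matrix over its unfolded
#'   entries first (default `TRUE`).
#' @param permute `"response"` (default: relabel the response matrix, the
#'   usual convention) or `"predictors"` (relabel all predictors jointly,
#'   for sensitivity analysis).
#' @return An `mrm_result`: `r_squared`, `p_model` (upper-tail permutation p
#'   of R^2), `coefficients` tibble (`term`, `estimate`, `p` — two-tailed
#'   permutation p of |b|), `n_perm`, `seed`, `n_pairs`.
#' @export
mrm <- function(d_y, predictors, n_perm = 9999, seed = NULL,
                standardize = TRUE, permute = c("response", "predictors")) {
  permute <- match.arg(permute)
  check_dist_matrix(d_y, "d_y")
  stopifnot(is.list(predictors), length(predictors) >= 1L)
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    stop_sb("`predictors` must be a fully named list.", "invalid_predictors")
  }
  predictors <- purrr::imap(predictors, function(d, nm) {
    check_symmetric(d, nm)
    check_same_sites(d_y, d, "d_y", nm)
    if (standardize) standardize_matrix(d) else d
  })
  n <- nrow(d_y)
  k <- length(predictors)
  yv <- unfold(d_y)
  m <- length(yv)
  if (m <= k + 1L) {
    stop_sb("Fewer site pairs than predictors + 1; cannot fit MRM.", "too_few_pairs")
  }
  x <- cbind(`(Intercept)` = 1, vapply(predictors, unfold_sym, numeric(m)))
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    drop <- setdiff(colnames(x), colnames(x)[keep])
    stop_sb(sprintf("Rank-deficient design; collinear predictor(s): %s",
                    paste(drop, collapse = ", ")), "rank_deficient")
  }
  coefs <- qr.coef(qr_x, yv)
  resid <- yv - x %*% coefs
  tss <- sum((yv - mean(yv))^2)
  r2 <- 1 - sum(resid^2) / tss

  ij <- lower_pair_index(n)
  one_perm <- function() {
    p <- sample.int(n)
    if (permute == "response") {
      ys <- d_y[cbind(p[ij$i], p[ij$j])]
      b <- qr.coef(qr_x, ys)
      rs <- ys - x %*% b
      c(1 - sum(rs^2) / sum((ys - mean(ys))^2), b[-1L])
    } else {
      xs <- cbind(1, vapply(predictors, function(d) d[cbind(p[ij$i], p[ij$j])],
                            numeric(m)))
      qs <- qr(xs)
      b <- qr.coef(qs, yv)
      rs <- yv - xs %*% b
      c(1 - sum(rs^2) / tss, b[-1L])
    }
  }
  stats_perm <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(kk) one_perm(), numeric(1L + k))
  })
  p_model <- (1 + sum(stats_perm[1L, ] >= r2 - 1e-12)) / (n_perm + 1)
  b_obs <- coefs[-1L]
  p_coef <- vapply(seq_len(k), function(j) {
    (1 + sum(abs(stats_perm[1L + j, ]) >= abs(b_obs[j]) - 1e-12)) / (n_perm + 1)
  }, numeric(1))

  structure(list(
    r_squared = r2,
    p_model = p_model,
    intercept = unname(coefs[1L]),
    coefficients = tibble::tibble(term = names(predictors),
                                  estimate = unname(b_obs),
                                  p = p_coef),
    n_perm = as.integer(n_perm),
    seed = seed,
    n_pairs = m,
    permute = permute
  ), class = "mrm_result")
}

#' @export
print.mrm_result <- function(x, ...) {
  cat(sprintf("MRM over %d site pairs: R^2 = %.3f, model p = %.4g (%d permutations)\n",
              x$n_pairs, x$r_squared, x$p_model, x$n_perm))
  print(x$coefficients, n = nrow(x$coefficients))
  invisible(x)
}

#' Tidy / glance an MRM fit
#'
#' @param x An `mrm_result`.
#' @param ... Unused.
#' @return `tidy()`: per-predictor coefficients and permutation p-values;
#'   `glance()`: one-row model summary.
#' @export
tidy.mrm_result <- function(x, ...) x$coefficients

#' @rdname tidy.mrm_result
#' @export
glance.mrm_result <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, p_model = x$p_model,
                 n_pairs = x$n_pairs, n_perm = x$n_perm)
}
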