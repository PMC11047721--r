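# Hierarchical partitioning of a distance-matrix regression's R^2 into
# per-predictor independent (I) and joint (J) contributions. I_k is the
# average, over all predictor orderings, of the increase in R^2 when
# predictor k is added — computed exactly from the 2^k all-subset fits with
# the Shapley subset weights w(s) = s! (k - s - 1)! / k!, rather than by
# enumerating the k! orderings.

#' Hierarchical partitioning of MRM R-squared
#'
#' Fits all `2^k` subsets of the predictors (OLS R^2 on unfolded vectors)
#' and decomposes the full-model R^2 into independent contributions
#' `I_k = sum over subsets S not containing k of w(|S|) * (R2(S + k) - R2(S))`
#' with `w(s) = s!(k-s-1)!/k!`, plus joint contributions
#' `J_k = R2({k}) - I_k`. Two identities are self-checked on every run:
#' `sum(I) == R2(full)` and `I_k + J_k == R2({k})` for every predictor.
#'
#' Negative `I_k` (possible with suppressor predictors) are reported as-is
#' with a warning, and `independent_pct` scales by `sum(I)` including any
#' negatives.
#'
#' @param d_y Response distance matrix.
#' @param predictors Named list of explanatory matrices (at most 16, since
#'   `2^k` subset fits are performed).
#' @param standardize Standardize each predictor matrix first (default
#'   `TRUE`; R^2 values are scale-invariant, so this only guards rank
#'   checks).
#' @return A `hier_part_result`: `contributions` tibble (`term`,
#'   `independent`, `joint`, `independent_pct`), `r_squared` (full model),
#'   `gof_cache` tibble of all subset fits, `n_pairs`.
#' @export
hier_part <- function(d_y, predictors, standardize = TRUE) {
  check_dist_matrix(d_y, "d_y")
  stopifnot(is.list(predictors), length(predictors) >= 1L)
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    stop_sb("`predictors` must be a fully named list.", "invalid_predictors")
  }
  k <- length(predictors)
  if (k > 16L) {
    stop_sb("More than 16 predictors: 2^k subset fits are infeasible; screen predictors first.",
            "too_many_predictors")
  }
  predictors <- purrr::imap(predictors, function(d, nm) {
    check_symmetric(d, nm)
    check_same_sites(d_y, d, "d_y", nm)
    if (standardize) standardize_matrix(d) else d
  })
  yv <- unfold(d_y)
  m <- length(yv)
  if (m <= k + 1L) {
    stop_sb("Fewer site pairs than predictors + 1.", "too_few_pairs")
  }
  x <- vapply(predictors, unfold_sym, numeric(m))
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- yv - mean(yv)
  g <- crossprod(xc)
  v <- crossprod(xc, yc)
  tss <- sum(yc^2)
  if (tss == 0) stop_sb("Response matrix has zero variance.", "degenerate")

  n_sub <- 2L^k
  r2 <- numeric(n_sub)            # r2[mask + 1], mask over predictors
  for (mask in seq_len(n_sub - 1L)) {
    s <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    sol <- tryCatch(solve(g[s, s, drop = FALSE], v[s, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(sol)) {
      stop_sb(sprintf("Rank-deficient predictor subset: %s",
                      paste(names(predictors)[s], collapse = ", ")),
              "rank_deficient")
    }
    r2[mask + 1L] <- drop(crossprod(v[s, , drop = FALSE], sol)) / tss
  }

  # w[s + 1] is the Shapley weight for subsets of size s = 0..k-1
  w <- factorial(0:(k - 1L)) * factorial(k - 1L - (0:(k - 1L))) / factorial(k)
  sizes <- vapply(0:(n_sub - 1L), function(mask) sum(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) != 0L), integer(1))
  indep <- numeric(k)
  bits <- bitwShiftL(1L, seq_len(k) - 1L)
  for (mask in 0:(n_sub - 1L)) {
    s <- sizes[mask + 1L]
    for (j in seq_len(k)) {
      if (bitwAnd(mask, bits[j]) == 0L) {
        indep[j] <- indep[j] + w[s + 1L] * (r2[bitwOr(mask, bits[j]) + 1L] - r2[mask + 1L])
      }
    }
  }
  uni <- r2[bits + 1L]
  joint <- uni - indep
  full <- r2[n_sub]

  if (abs(sum(indep) - full) > 1e-8) {
    stop_sb("Partition self-check failed: sum(I) != full-model R^2 (internal).",
            "internal")
  }
  if (any(abs(indep + joint - uni) > 1e-8)) {
    stop_sb("Partition self-check failed: I + J != univariate R^2 (internal).",
            "internal")
  }
  if (any(indep < 0)) {
    rlang::warn("Negative independent contribution(s) (suppressor predictor); reported as-is.",
                class = "streambeta_negative_I")
  }

  gof <- tibble::tibble(
    subset = vapply(0:(n_sub - 1L), function(mask) {
      paste(names(predictors)[bitwAnd(mask, bits) != 0L], collapse = "+")
    }, character(1)),
    size = sizes,
    r_squared = r2
  )

  structure(list(
    contributions = tibble::tibble(
      term = names(predictors),
      independent = indep,
      joint = joint,
      independent_pct = 100 * indep / sum(indep)
    ),
    r_squared = full,
    gof_cache = gof,
    n_pairs = m
  ), class = "hier_part_result")
}

#' @export
print.hier_part_result <- function(x, ...) {
  cat(sprintf("Hierarchical partitioning of R^2 = %.3f (%d site pairs)\n",
              x$r_squared, x$n_pairs))
  print(x$contributions, n = nrow(x$contributions))
  invisible(x)
}

#' Tidy / glance a hierarchical partitioning result
#'
#' @param x A `hier_part_result`.
#' @param ... Unused.
#' @return `tidy()`: per-predictor independent/joint contributions;
#'   `glance()`: one-row summary.
#' @export
tidy.hier_part_result <- function(x, ...) x$contributions

#' @rdname tidy.hier_part_result
#' @export
glance.hier_part_result <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_pairs = x$n_pairs,
                 n_predictors = nrow(x$contributions))
}
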