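# Mantel permutation test between two distance matrices. The statistic is
# the Pearson correlation of the lower-triangle vectors; the null is built
# by simultaneously permuting rows and columns of the response matrix (site
# relabelling), never by shuffling unfolded entries independently.

# All n! permutations of 1..n, one per row (n <= 7 guards the 5040 cap).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                 sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

# Correlations of x with the unfolded response under a set of site
# relabellings. `perms` is a matrix with one permutation per row.
perm_correlations <- function(d_y, xv, perms, ij) {
  apply(perms, 1L, function(p) {
    stats::cor(d_y[cbind(p[ij$i], p[ij$j])], xv)
  })
}

#' Mantel test between two distance matrices
#'
#' @param d_y Response distance matrix (relabelled under the null).
#' @param d_x Explanatory distance matrix (held fixed).
#' @param n_perm Number of random permutations (default 9999), or `"exact"`
#'   to enumerate all `n!` site relabellings (allowed for up to 7 sites).
#' @param seed Optional integer seed; identical seeds give identical
#'   p-values.
#' @param tail `"greater"` (default; the distance-decay alternative of
#'   positive matrix correlation) or `"two-sided"`.
#' @return A `mantel_result`: `r` (Pearson correlation of unfolded
#'   matrices), `p`, `n_perm`, `tail`, `seed`, `exact`, `n_sites`. Random
#'   permutations use the add-one estimator `p = (1 + #{r* >= r}) /
#'   (n_perm + 1)`, so `p` is never zero; exact mode uses the proportion of
#'   all relabellings (identity included) with `r* >= r`.
#' @export
mantel <- function(d_y, d_x, n_perm = 9999, seed = NULL,
                   tail = c("greater", "two-sided")) {
  tail <- match.arg(tail)
  check_dist_matrix(d_y, "d_y"); check_dist_matrix(d_x, "d_x")
  check_same_sites(d_y, d_x, "d_y", "d_x")
  n <- nrow(d_y)
  yv <- unfold(d_y); xv <- unfold(d_x)
  if (sample_sd(yv) == 0) stop_sb("Response matrix has zero variance.", "degenerate")
  if (sample_sd(xv) == 0) stop_sb("Explanatory matrix has zero variance.", "degenerate")
  r_obs <- stats::cor(yv, xv)
  ij <- lower_pair_index(n)

  exceeds <- function(rs) {
    if (tail == "greater") rs >= r_obs - 1e-12 else abs(rs) >= abs(r_obs) - 1e-12
  }

  if (identical(n_perm, "exact")) {
    if (n > 7L) {
      stop_sb("Exact enumeration supported for up to 7 sites.", "too_many_sites")
    }
    perms <- all_permutations(n)
    rs <- perm_correlations(d_y, xv, perms, ij)
    p <- mean(exceeds(rs))
    n_used <- nrow(perms)
    exact <- TRUE
  } else {
    if (!is_whole(n_perm) || n_perm < 1) {
      stop_sb("`n_perm` must be a positive integer or \"exact\".", "invalid_nperm")
    }
    rs <- with_seed_if(seed, {
      vapply(seq_len(n_perm), function(k) {
        p <- sample.int(n)
        stats::cor(d_y[cbind(p[ij$i], p[ij$j])], xv)
      }, numeric(1))
    })
    p <- (1 + sum(exceeds(rs))) / (n_perm + 1)
    n_used <- as.integer(n_perm)
    exact <- FALSE
  }

  structure(list(r = r_obs, p = p, n_perm = n_used, tail = tail,
                 seed = seed, exact = exact, n_sites = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %s%d permutations, n = %d sites)\n",
              x$r, x$p, x$tail, if (x$exact) "exact, " else "", x$n_perm, x$n_sites))
  invisible(x)
}

#' Tidy / glance a Mantel result
#'
#' @param x A `mantel_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(r = x$r, p = x$p, n_perm = x$n_perm, tail = x$tail,
                 exact = x$exact, n_sites = x$n_sites)
}

#' @rdname tidy.mantel_result
#' @export
glance.mantel_result <- function(x, ...) tidy.mantel_result(x, ...)

#' Mantel tests of all beta components against all explanatory distances
#'
#' Runs the full grid of Mantel tests — each beta-diversity matrix against
#' each explanatory distance — with one seed fanned out into independent
#' per-test substreams, so results do not depend on grid order.
#'
#' @param beta Named list of response matrices (default names `total`,
#'   `turnover`, `nestedness`, as from [beta_matrices()] via
#'   `setNames(bm, c("total","turnover","nestedness"))`).
#' @param predictors Named list of explanatory matrices (e.g. `geography`,
#'   `elevation`, `environment`).
#' @param n_perm,seed,tail Passed to [mantel()].
#' @return A `mantel_table` tibble: one row per (predictor, component) with
#'   `r` and `p`.
#' @export
mantel_table <- function(beta, predictors, n_perm = 9999, seed = NULL,
                         tail = "greater") {
  stopifnot(is.list(beta), is.list(predictors))
  if (is.null(names(beta))) names(beta) <- c("total", "turnover", "nestedness")[seq_along(beta)]
  if (is.null(names(predictors))) {
    names(predictors) <- paste0("predictor_", seq_along(predictors))
  }
  grid <- tidyr::expand_grid(predictor = names(predictors),
                             component = names(beta))
  seeds <- if (is.null(seed)) rep(list(NULL), nrow(grid)) else
    as.list(derive_seeds(seed, nrow(grid)))
  res <- purrr::pmap_dfr(
    list(grid$predictor, grid$component, seeds),
    function(pr, cmp, sd) {
      m <- mantel(beta[[cmp]], predictors[[pr]], n_perm = n_perm,
                  seed = sd, tail = tail)
      tibble::tibble(predictor = pr, component = cmp, r = m$r, p = m$p)
    }
  )
  res$component <- factor(res$component, levels = names(beta))
  res$predictor <- factor(res$predictor, levels = names(predictors))
  res <- res[order(res$predictor, res$component), ]
  class(res) <- c("mantel_table", class(tibble::tibble()))
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  res
}
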