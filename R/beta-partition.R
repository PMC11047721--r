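# Pairwise partition of total beta diversity (Sorensen dissimilarity) into
# spatial turnover (Simpson dissimilarity) and the nestedness-resultant
# component, following Baselga's incidence-based decomposition:
#
#   beta_sor = (b + c) / (2a + b + c)
#   beta_sim = min(b, c) / (a + min(b, c))
#   beta_sne = beta_sor - beta_sim
#            = |b - c| / (2a + b + c) * a / (a + min(b, c))
#
# with a = species shared by the two sites, b and c = species exclusive to
# each site. beta_sne is evaluated through its direct product form and
# checked against the difference, so the partition identity holds to
# floating tolerance on every pair.

#' Shared / exclusive species counts for a site pair
#'
#' @param x,y Binary incidence vectors of equal length (one site each).
#' @return A named list: `a` shared, `b` only in `x`, `c` only in `y`.
#' @export
#' @examples
#' pair_counts(c(1, 1, 1, 1), c(1, 1, 0, 0)) # a = 2, b = 2, c = 0
pair_counts <- function(x, y) {
  if (length(x) != length(y)) stop_sb("Rows differ in length.", "invalid_pair")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    stop_sb("Rows must be binary.", "invalid_pair")
  }
  if (sum(x) == 0 || sum(y) == 0) {
    stop_sb("Empty site reached pair_counts(); run drop_empty_sites() first.",
            "empty_site")
  }
  a <- sum(x == 1 & y == 1)
  list(a = a, b = sum(x) - a, c = sum(y) - a)
}

#' Partition one pair's dissimilarity into turnover and nestedness
#'
#' @param pc A list with counts `a`, `b`, `c` (see [pair_counts()]).
#' @return A named list: `beta_sor`, `beta_sim`, `beta_sne`, each in
#'   `[0, 1]` with `beta_sor == beta_sim + beta_sne`.
#' @export
#' @examples
#' beta_pair(list(a = 1, b = 2, c = 1)) # sor 0.6, sim 0.5, sne 0.1
beta_pair <- function(pc) {
  a <- pc$a; b <- pc$b; cc <- pc$c
  stopifnot(a >= 0, b >= 0, cc >= 0)
  if (a + b < 1 || a + cc < 1) {
    stop_sb("Degenerate pair (an empty site); run drop_empty_sites() first.",
            "empty_site")
  }
  mn <- min(b, cc)
  sor <- (b + cc) / (2 * a + b + cc)
  sim <- if (a == 0 && mn == 0) {
    stop_sb("Degenerate pair: no shared and no exclusive species on one side.",
            "empty_site")
  } else {
    mn / (a + mn)
  }
  sne <- abs(b - cc) / (2 * a + b + cc) * a / (a + mn)
  if (abs(sne - (sor - sim)) > 1e-12) {
    stop_sb("Partition identity violated beyond tolerance (internal).", "internal")
  }
  list(beta_sor = sor, beta_sim = sim, beta_sne = sne)
}

#' Pairwise beta-diversity matrices of an occurrence table
#'
#' Computes the three pairwise dissimilarity matrices (total, turnover,
#' nestedness) over all site pairs of an occurrence table with no empty
#' sites.
#'
#' @param occ An occurrence tibble with >= 2 sites, all non-empty.
#' @return A named list of three distance matrices: `sor`, `sim`, `sne`,
#'   sharing site ordering, with `sor == sim + sne` elementwise.
#' @export
beta_matrices <- function(occ) {
  m <- incidence_matrix(occ)
  if (nrow(m) < 2L) stop_sb("Need at least two sites.", "too_few_sites")
  if (any(rowSums(m) == 0L)) {
    stop_sb("Empty site(s) present; run drop_empty_sites() first.", "empty_site")
  }
  rich <- rowSums(m)
  a <- m %*% t(m)                       # shared species per pair
  b <- matrix(rich, nrow(m), nrow(m)) - a        # exclusive to row site
  cc <- t(b)                                     # exclusive to column site
  mn <- pmin(b, cc)
  denom <- 2 * a + b + cc
  sor <- (b + cc) / denom
  sim <- mn / (a + mn)
  sne <- abs(b - cc) / denom * a / (a + mn)
  ids <- rownames(m)
  out <- list(
    sor = new_dist_matrix(sor, ids),
    sim = new_dist_matrix(sim, ids),
    sne = new_dist_matrix(sne, ids)
  )
  if (max(abs(out$sor - out$sim - out$sne)) > 1e-12) {
    stop_sb("Partition identity violated beyond tolerance (internal).", "internal")
  }
  out
}

#' Summarise pairwise beta diversity and classify the dominant component
#'
#' Averages the three dissimilarities over all site pairs (mean and sample
#' SD over the lower triangle) and computes the beta-ratio
#' `beta_sne / beta_sor` per pair: a mean ratio below 0.5 indicates that
#' total dissimilarity is dominated by turnover, above 0.5 by nestedness.
#' Pairs with `beta_sor == 0` (identical communities) carry no ratio and are
#' excluded from the ratio statistics with a warning; they still count in
#' the dissimilarity means.
#'
#' @param bm Either the list returned by [beta_matrices()], or the `sor`
#'   matrix with `sim` and `sne` supplied separately.
#' @param sim,sne Optional matrices when `bm` is the `sor` matrix.
#' @param ratio_method `"per_pair"` (default: average of per-pair ratios, so
#'   the ratio has a pairwise distribution and an SD) or `"of_means"`
#'   (`mean_sne / mean_sor`, reported with `sd_ratio = NA`).
#' @return A `beta_summary` object; see [tidy.beta_summary()].
#' @export
beta_summary <- function(bm, sim = NULL, sne = NULL,
                         ratio_method = c("per_pair", "of_means")) {
  ratio_method <- match.arg(ratio_method)
  if (is.list(bm) && is.null(sim)) {
    sor <- bm$sor; sim <- bm$sim; sne <- bm$sne
  } else {
    sor <- bm
  }
  check_dist_matrix(sor, "sor"); check_dist_matrix(sim, "sim"); check_dist_matrix(sne, "sne")
  check_same_sites(sor, sim, "sor", "sim")
  check_same_sites(sor, sne, "sor", "sne")
  v_sor <- unfold(sor); v_sim <- unfold(sim); v_sne <- unfold(sne)

  zero <- v_sor == 0
  if (all(zero)) {
    stop_sb("All site pairs are identical; beta-ratio undefined.", "degenerate")
  }
  if (any(zero)) {
    rlang::warn(sprintf(
      "%d pair(s) with beta_sor = 0 excluded from ratio statistics.", sum(zero)
    ), class = "streambeta_zero_sor")
  }
  ratios <- v_sne[!zero] / v_sor[!zero]
  if (ratio_method == "per_pair") {
    mean_ratio <- mean(ratios)
    sd_ratio <- sample_sd(ratios)
  } else {
    mean_ratio <- mean(v_sne) / mean(v_sor)
    sd_ratio <- NA_real_
  }

  structure(list(
    mean_sor = mean(v_sor), sd_sor = sample_sd(v_sor),
    mean_sim = mean(v_sim), sd_sim = sample_sd(v_sim),
    mean_sne = mean(v_sne), sd_sne = sample_sd(v_sne),
    mean_ratio = mean_ratio, sd_ratio = sd_ratio,
    ratio_method = ratio_method,
    n_pairs = length(v_sor),
    n_zero_sor = sum(zero),
    dominant_component = if (mean_ratio < 0.5) "turnover" else "nestedness"
  ), class = "beta_summary")
}

#' @export
print.beta_summary <- function(x, ...) {
  cat("Pairwise beta-diversity summary (", x$n_pairs, " pairs)\n", sep = "")
  cat(sprintf("  total (Sorensen)     : %.3f +/- %.3f\n", x$mean_sor, x$sd_sor))
  cat(sprintf("  turnover (Simpson)   : %.3f +/- %.3f\n", x$mean_sim, x$sd_sim))
  cat(sprintf("  nestedness-resultant : %.3f +/- %.3f\n", x$mean_sne, x$sd_sne))
  if (is.na(x$sd_ratio)) {
    cat(sprintf("  beta-ratio (of means): %.3f\n", x$mean_ratio))
  } else {
    cat(sprintf("  beta-ratio           : %.3f +/- %.3f\n", x$mean_ratio, x$sd_ratio))
  }
  cat("  dominant component   :", x$dominant_component, "\n")
  if (x$n_zero_sor > 0) {
    cat("  (", x$n_zero_sor, " identical pair(s) excluded from ratio)\n", sep = "")
  }
  invisible(x)
}

#' Tidy a beta-diversity summary
#'
#' @param x A `beta_summary`.
#' @param ... Unused.
#' @return One row per index (`sor`, `sim`, `sne`, `ratio`) with `mean` and
#'   `sd` columns.
#' @export
tidy.beta_summary <- function(x, ...) {
  tibble::tibble(
    index = c("sor", "sim", "sne", "ratio"),
    mean = c(x$mean_sor, x$mean_sim, x$mean_sne, x$mean_ratio),
    sd = c(x$sd_sor, x$sd_sim, x$sd_sne, x$sd_ratio)
  )
}

#' @rdname tidy.beta_summary
#' @export
glance.beta_summary <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs,
    n_zero_sor = x$n_zero_sor,
    mean_ratio = x$mean_ratio,
    dominant_component = x$dominant_component,
    ratio_method = x$ratio_method
  )
}
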