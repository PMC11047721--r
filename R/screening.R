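# Pre-analysis variable screening: Shapiro-Wilk normality (informational;
# no transformation is applied) and pairwise Spearman rank correlations with
# rule-based removal of one variable from each collinear pair.

#' Screen variables for normality and rank-correlation collinearity
#'
#' Runs a Shapiro-Wilk test per variable (reported but never used for
#' exclusion) and the full Spearman rank-correlation matrix. Pairs with
#' `|rho| >= threshold` are flagged; from each flagged pair, the variable
#' ranked lower in the priority order is removed. Flagged pairs are resolved
#' in order of decreasing `|rho|`, skipping pairs in which one member was
#' already removed, so the outcome is deterministic given `threshold` and
#' `priority`.
#'
#' Include the gradient variable (e.g. `elevation`) in `data` and put it
#' first in `priority` to reproduce the common screening decision of
#' dropping water temperature when it tracks elevation.
#'
#' @param data A tibble: `site_id` plus numeric variable columns.
#' @param threshold Absolute Spearman rho at or above which a pair is
#'   flagged; must lie in (0, 1). Default 0.7.
#' @param priority Character vector of variables to keep preferentially, in
#'   order; unlisted variables rank after listed ones, in column order.
#' @return A `screening_report`: `normality` (tibble of W and p per
#'   variable), `spearman_rho` (matrix), `flagged` (tibble of flagged
#'   pairs), `removed`, `kept`, `threshold`, `priority`.
#' @export
screen_variables <- function(data, threshold = 0.7, priority = character()) {
  check_env_table(data)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop_sb("`threshold` must lie strictly between 0 and 1.", "invalid_threshold")
  }
  vars <- names(data)[-1L]
  x <- as.matrix(data[, vars, drop = FALSE])
  if (nrow(x) < 4L) stop_sb("Need at least 4 sites to screen variables.", "too_few_sites")

  normality <- purrr::map_dfr(vars, function(v) {
    sw <- tryCatch(stats::shapiro.test(x[, v]),
                   error = function(e) list(statistic = NA_real_, p.value = NA_real_))
    tibble::tibble(variable = v,
                   shapiro_w = unname(sw$statistic),
                   shapiro_p = unname(sw$p.value))
  })

  rho <- stats::cor(x, method = "spearman")

  ut <- which(upper.tri(rho), arr.ind = TRUE)
  flagged <- tibble::tibble(
    var_a = vars[ut[, 1L]],
    var_b = vars[ut[, 2L]],
    rho = rho[ut]
  )
  flagged <- flagged[abs(flagged$rho) >= threshold, , drop = FALSE]
  flagged <- flagged[order(-abs(flagged$rho)), , drop = FALSE]

  rank_of <- function(v) {
    p <- match(v, priority)
    ifelse(is.na(p), length(priority) + match(v, vars), p)
  }
  removed <- character()
  for (k in seq_len(nrow(flagged))) {
    a <- flagged$var_a[k]; b <- flagged$var_b[k]
    if (a %in% removed || b %in% removed) next
    removed <- c(removed, if (rank_of(a) <= rank_of(b)) b else a)
  }

  structure(list(
    normality = normality,
    spearman_rho = rho,
    flagged = flagged,
    removed = removed,
    kept = setdiff(vars, removed),
    threshold = threshold,
    priority = priority
  ), class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Variable screening (|Spearman rho| >= ", x$threshold, ")\n", sep = "")
  if (nrow(x$flagged) == 0L) {
    cat("  no collinear pairs flagged\n")
  } else {
    for (k in seq_len(nrow(x$flagged))) {
      cat(sprintf("  %s ~ %s: rho = %.2f\n",
                  x$flagged$var_a[k], x$flagged$var_b[k], x$flagged$rho[k]))
    }
    cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  }
  cat("  kept:", paste(x$kept, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a screening report
#'
#' @param x A `screening_report`.
#' @param ... Unused.
#' @return One row per variable: Shapiro statistics and the keep/remove
#'   decision.
#' @export
tidy.screening_report <- function(x, ...) {
  dplyr::mutate(x$normality, removed = .data$variable %in% x$removed)
}
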