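# Combined MRM + hierarchical-partitioning report over the three beta
# components, laid out with the conventional predictor abbreviations
# (Geo, Ele, pH, Con, Do, Rw, Wd, Cv, chl.a, TN, NN, TP, Sub).

# Map pipeline variable names to report abbreviations.
predictor_abbrev <- c(
  geography = "Geo", elevation = "Ele", ph = "pH", conductivity = "Con",
  dissolved_oxygen = "Do", river_width = "Rw", water_depth = "Wd",
  current_velocity = "Cv", chl_a = "chl.a", total_n = "TN",
  ammonium_n = "NN", total_p = "TP", substrate = "Sub"
)

abbreviate_predictors <- function(x) {
  unname(ifelse(x %in% names(predictor_abbrev), predictor_abbrev[x], x))
}

#' MRM and hierarchical partitioning for every beta component
#'
#' For each response matrix (total, turnover, nestedness) fits the full MRM
#' on all predictor matrices and partitions its R^2 into per-predictor
#' independent contributions. One master seed fans out into independent
#' per-response substreams.
#'
#' @param beta Named list of three response matrices (default names
#'   `total`, `turnover`, `nestedness`).
#' @param predictors Named list of explanatory distance matrices; names in
#'   `names(predictor_abbrev)` are abbreviated in the tidy output.
#' @param n_perm,seed Passed to [mrm()].
#' @return A `partition_table`: per component, the `mrm_result` and
#'   `hier_part_result`; see [tidy.partition_table()].
#' @export
partition_table <- function(beta, predictors, n_perm = 9999, seed = NULL) {
  stopifnot(is.list(beta), is.list(predictors))
  if (is.null(names(beta))) names(beta) <- c("total", "turnover", "nestedness")[seq_along(beta)]
  seeds <- if (is.null(seed)) rep(list(NULL), length(beta)) else
    as.list(derive_seeds(seed, length(beta)))
  fits <- purrr::map2(beta, seeds, function(d_y, sd) {
    list(
      mrm = mrm(d_y, predictors, n_perm = n_perm, seed = sd),
      hier = hier_part(d_y, predictors)
    )
  })
  structure(list(fits = fits, n_perm = n_perm, seed = seed,
                 predictors = names(predictors)),
            class = "partition_table")
}

#' @export
print.partition_table <- function(x, ...) {
  for (nm in names(x$fits)) {
    cat("==", nm, "==\n")
    print(x$fits[[nm]]$mrm)
    print(x$fits[[nm]]$hier)
  }
  invisible(x)
}

#' Tidy a combined partition table
#'
#' @param x A `partition_table`.
#' @param ... Unused.
#' @return A long tibble: one row per (component, predictor) with the MRM
#'   coefficient and permutation p, the independent and joint contribution,
#'   and the independent contribution as a percentage.
#' @export
tidy.partition_table <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, nm) {
    co <- tidy(fit$mrm)
    hp <- tidy(fit$hier)
    tibble::tibble(
      component = nm,
      predictor = abbreviate_predictors(co$term),
      estimate = co$estimate,
      p = co$p,
      independent = hp$independent,
      joint = hp$joint,
      independent_pct = hp$independent_pct
    )
  })
}

#' @rdname tidy.partition_table
#' @export
glance.partition_table <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, nm) {
    dplyr::mutate(glance(fit$mrm), component = nm, .before = 1L)
  })
}
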