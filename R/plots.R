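# ggplot2 views of the main result types: beta-index summary bars,
# distance-decay scatter panels, and hierarchical-partitioning bars.

#' Plot a beta-diversity summary
#'
#' Bar chart of the mean pairwise total, turnover and nestedness
#' dissimilarities with +/- 1 SD error bars.
#'
#' @param object A `beta_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.beta_summary <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$index != "ratio", ]
  df$index <- factor(df$index, levels = c("sor", "sim", "sne"),
                     labels = c("total", "turnover", "nestedness"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                        ymax = pmin(.data$mean + .data$sd, 1)),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "pairwise dissimilarity") +
    ggplot2::theme_minimal()
}

#' Plot one distance-decay fit
#'
#' Scatter of unfolded dissimilarity against distance with the OLS line;
#' the line is drawn solid when `significant` (typically the matching
#' Mantel test at 0.05), dashed otherwise.
#'
#' @param object A `decay_fit`.
#' @param significant Draw the fit solid (`TRUE`) or dashed (`FALSE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decay_fit <- function(object, significant = TRUE, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$distance, y = .data$dissimilarity)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = if (significant) "solid" else "dashed") +
    ggplot2::labs(x = "distance", y = "dissimilarity") +
    ggplot2::theme_minimal()
}

#' Distance-decay panel grid for a full report
#'
#' All nine component-by-predictor decay fits, faceted; lines are solid
#' where the matching Mantel test is significant at `alpha`.
#'
#' @param report A `beta_report`.
#' @param alpha Mantel significance level deciding solid vs dashed lines.
#' @return A ggplot.
#' @export
plot_decay_panels <- function(report, alpha = 0.05) {
  stopifnot(inherits(report, "beta_report"))
  mant <- tibble::as_tibble(report$mantel)
  df <- purrr::imap_dfr(report$decay, function(f, nm) {
    parts <- strsplit(nm, "~", fixed = TRUE)[[1L]]
    dplyr::mutate(f$data, component = parts[1L], predictor = parts[2L],
                  slope = f$slope, intercept = f$intercept)
  })
  df <- dplyr::left_join(df,
                         dplyr::mutate(mant,
                                       component = as.character(.data$component),
                                       predictor = as.character(.data$predictor),
                                       significant = .data$p < alpha),
                         by = c("component", "predictor"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$dissimilarity)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      linetype = .data$significant)) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid", `FALSE` = "dashed"),
                                   guide = "none") +
    ggplot2::facet_grid(component ~ predictor, scales = "free_x") +
    ggplot2::labs(x = "distance", y = "dissimilarity") +
    ggplot2::theme_minimal()
}

#' Plot hierarchical-partitioning contributions
#'
#' @param object A `hier_part_result`.
#' @param ... Unused.
#' @return A ggplot of per-predictor independent contributions (% of total
#'   explained variance).
#' @export
autoplot.hier_part_result <- function(object, ...) {
  df <- tidy(object)
  df$term <- stats::reorder(df$term, df$independent_pct)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$independent_pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "independent contribution (%)") +
    ggplot2::theme_minimal()
}

#' Independent-contribution bars for every beta component
#'
#' @param x A `partition_table`.
#' @return A faceted ggplot of independent contributions per predictor and
#'   component.
#' @export
plot_partition <- function(x) {
  stopifnot(inherits(x, "partition_table"))
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predictor, y = .data$independent_pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = NULL, y = "independent contribution (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
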