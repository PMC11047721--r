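# Explanatory distance matrices: great-circle geographic distance from
# coordinates, elevational differences, and Euclidean environmental distance
# over standardized microhabitat variables.

#' Great-circle geographic distance between transects
#'
#' Haversine distance on a sphere of radius 6,378,137 m (the geosphere
#' default), computed from decimal-degree WGS84 coordinates. Distances are
#' returned in metres.
#'
#' @param meta A transect metadata tibble ([check_transect_meta()]).
#' @return A distance matrix in metres, sites ordered as in `meta`.
#' @export
geographic_distance <- function(meta) {
  check_transect_meta(meta)
  m <- geosphere::distm(cbind(meta$longitude, meta$latitude),
                        fun = geosphere::distHaversine)
  new_dist_matrix(m, meta$site_id)
}

#' Elevational distance between transects
#'
#' Absolute pairwise elevation differences, in metres.
#'
#' @param meta A transect metadata tibble.
#' @return A distance matrix in metres.
#' @export
elevational_distance <- function(meta) {
  check_transect_meta(meta)
  m <- abs(outer(meta$elevation, meta$elevation, "-"))
  new_dist_matrix(m, meta$site_id)
}

#' Standardize environment variables to zero mean and unit SD
#'
#' Z-scores every variable column (sample SD). Constant columns cannot be
#' standardized and raise an error naming the column.
#'
#' @param env An environment tibble (`site_id` + numeric columns).
#' @param vars Variables to standardize; default all non-id columns.
#' @return The tibble with the chosen columns z-scored.
#' @export
standardize_env <- function(env, vars = NULL) {
  check_env_table(env)
  vars <- vars %||% names(env)[-1L]
  for (v in vars) {
    s <- sample_sd(env[[v]])
    if (!is.finite(s) || s == 0) {
      stop_sb(sprintf("Variable '%s' is constant; cannot standardize.", v),
              "constant_column")
    }
    env[[v]] <- (env[[v]] - mean(env[[v]])) / s
  }
  env
}

#' Pooled environmental distance
#'
#' Euclidean distance between sites over (by default, standardized)
#' environmental variables — the multivariate microhabitat distance used in
#' Mantel tests and distance-decay fits.
#'
#' @param env An environment tibble.
#' @param vars Variable columns to use; default all non-id columns. Pass the
#'   post-screening kept set to mirror collinearity-screened analyses.
#' @param standardize Z-score the columns first (default `TRUE`).
#' @return A distance matrix.
#' @export
environmental_distance <- function(env, vars = NULL, standardize = TRUE) {
  check_env_table(env)
  vars <- vars %||% names(env)[-1L]
  if (!all(vars %in% names(env))) {
    stop_sb(sprintf("Unknown variable(s): %s",
                    paste(setdiff(vars, names(env)), collapse = ", ")), "unknown_var")
  }
  if (standardize) env <- standardize_env(env, vars)
  m <- as.matrix(stats::dist(as.matrix(env[, vars, drop = FALSE]),
                             method = "euclidean"))
  new_dist_matrix(m, env$site_id)
}

# Substrate proportion columns, by naming convention of the generator and
# bundled fixtures.
substrate_cols <- function(env) grep("^sub_", names(env), value = TRUE)

#' Per-variable distance matrix
#'
#' Absolute pairwise difference of one standardized variable — the form in
#' which each microhabitat variable enters MRM and hierarchical
#' partitioning. The composite variable `"substrate"` is handled specially:
#' with `substrate = "proportions"` (default) it is the Euclidean distance
#' between the per-site substrate-category proportion vectors (columns
#' `sub_*`); with `"dominant"` it is a 0/1 mismatch of the dominant
#' category.
#'
#' @param env An environment tibble.
#' @param var A variable name, or `"substrate"`.
#' @param substrate Encoding for the composite substrate variable.
#' @return A distance matrix.
#' @export
single_variable_distance <- function(env, var,
                                     substrate = c("proportions", "dominant")) {
  check_env_table(env)
  substrate <- match.arg(substrate)
  if (identical(var, "substrate")) {
    sc <- substrate_cols(env)
    if (length(sc) == 0L) {
      stop_sb("No substrate proportion columns (sub_*) found.", "unknown_var")
    }
    p <- as.matrix(env[, sc, drop = FALSE])
    m <- if (substrate == "proportions") {
      as.matrix(stats::dist(p, method = "euclidean"))
    } else {
      dom <- apply(p, 1L, which.max)
      1 - outer(dom, dom, "==")
    }
    return(new_dist_matrix(m, env$site_id))
  }
  if (!var %in% names(env)[-1L]) {
    stop_sb(sprintf("Unknown variable '%s'.", var), "unknown_var")
  }
  z <- standardize_env(env, var)[[var]]
  new_dist_matrix(abs(outer(z, z, "-")), env$site_id)
}
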