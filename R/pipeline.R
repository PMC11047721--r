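# End-to-end analysis chain: data hygiene -> variable screening -> beta
# partition -> Mantel grid -> distance-decay panels -> MRM + hierarchical
# partitioning, with a JSON-serialisable run manifest.

# Microhabitat variables that enter MRM individually; substrate enters as
# one composite predictor built from its proportion columns.
mrm_env_vars <- function(env, removed = character()) {
  singles <- setdiff(names(env)[-1L], c(substrate_cols(env), removed))
  list(singles = singles,
       substrate = length(substrate_cols(env)) > 0L &&
         !"substrate" %in% removed)
}

#' Run the full beta-diversity analysis chain
#'
#' Executes, in order: survey merging (if several occurrence tables are
#' given), empty-site exclusion, collinearity screening of elevation plus
#' the environment variables, construction of geographic / elevational /
#' environmental distances, the pairwise beta partition and its summary,
#' the Mantel grid, the nine distance-decay fits, and MRM plus hierarchical
#' partitioning on the per-variable predictor set. One master seed fans out
#' into independent per-stage substreams, so reruns with the same seed are
#' identical.
#'
#' @param occurrence An occurrence tibble, or a list of them (merged by
#'   union). Ignored when `scenario` is given.
#' @param meta,env Transect metadata and environment tibbles.
#' @param scenario Optional `scenario_config`: generate the inputs instead
#'   of supplying them.
#' @param n_perm Permutations for every permutation test. Default 9999.
#' @param seed Master seed (required for reproducibility; default 1).
#' @param collinearity_threshold Absolute Spearman rho for screening.
#'   Default 0.7.
#' @param priority Keep-priority for screening. Default `"elevation"`.
#' @param substrate Substrate encoding for its single-variable distance;
#'   see [single_variable_distance()].
#' @param tail Mantel alternative. Default `"greater"`.
#' @return A `beta_report` list: `summary`, `screening`, `beta` (three
#'   matrices), `distances` (three explanatory matrices), `mantel`,
#'   `decay` (list of `decay_fit`s named `component~predictor`),
#'   `partition`, and `manifest` (seed, permutations, excluded sites,
#'   removed variables, thresholds, package version).
#' @export
run_full_analysis <- function(occurrence = NULL, meta = NULL, env = NULL,
                              scenario = NULL, n_perm = 9999, seed = 1,
                              collinearity_threshold = 0.7,
                              priority = "elevation",
                              substrate = c("proportions", "dominant"),
                              tail = "greater") {
  substrate <- match.arg(substrate)
  truth <- NULL
  if (!is.null(scenario)) {
    gen_seed <- derive_seeds(seed, 3)[3L]
    gen <- generate_scenario(scenario, seed = gen_seed)
    occurrence <- gen$occurrence; meta <- gen$meta; env <- gen$env
    truth <- gen$truth
  }
  if (is.null(occurrence) || is.null(meta) || is.null(env)) {
    stop_sb("Provide occurrence, meta and env tables, or a scenario config.",
            "invalid_input")
  }
  if (is.data.frame(occurrence)) occurrence <- list(occurrence)
  occ <- merge_surveys(occurrence)
  check_transect_meta(meta); check_env_table(env)

  dropped <- drop_empty_sites(occ)
  occ <- dropped$occurrence
  sites <- occ$site_id
  meta <- align_sites(meta, sites, "meta")
  env <- align_sites(env, sites, "env")

  # Screening covers elevation plus the scalar microhabitat variables.
  # Substrate enters the analysis as one composite variable, so its
  # compositional proportion columns (which inter-correlate by construction)
  # are not screened individually.
  scalars <- setdiff(names(env)[-1L], substrate_cols(env))
  screen_tbl <- dplyr::bind_cols(
    env[, 1L, drop = FALSE],
    tibble::tibble(elevation = meta$elevation),
    env[, scalars, drop = FALSE]
  )
  screening <- screen_variables(screen_tbl, threshold = collinearity_threshold,
                                priority = priority)
  kept_env <- c(setdiff(screening$kept, "elevation"), substrate_cols(env))

  d_geo <- geographic_distance(meta)
  d_ele <- elevational_distance(meta)
  d_env <- environmental_distance(env, vars = kept_env)
  predictors3 <- list(geography = d_geo, elevation = d_ele, environment = d_env)

  bm <- beta_matrices(occ)
  summary <- beta_summary(bm)
  beta3 <- list(total = bm$sor, turnover = bm$sim, nestedness = bm$sne)

  stage_seeds <- derive_seeds(seed, 2)
  mant <- mantel_table(beta3, predictors3, n_perm = n_perm,
                       seed = stage_seeds[1L], tail = tail)

  decay <- purrr::imap(predictors3, function(dx, pnm) {
    purrr::imap(beta3, function(dy, bnm) distance_decay(dy, dx))
  })
  decay <- purrr::flatten(purrr::imap(decay, function(l, pnm) {
    setNames(l, paste0(names(l), "~", pnm))
  }))

  ev <- mrm_env_vars(env, removed = screening$removed)
  mrm_predictors <- c(
    list(geography = d_geo, elevation = d_ele),
    setNames(lapply(ev$singles, function(v) single_variable_distance(env, v)),
             ev$singles)
  )
  if (ev$substrate) {
    mrm_predictors$substrate <-
      single_variable_distance(env, "substrate", substrate = substrate)
  }
  partition <- partition_table(beta3, mrm_predictors, n_perm = n_perm,
                               seed = stage_seeds[2L])

  manifest <- list(
    package_version = as.character(utils::packageVersion("streambeta")),
    seed = seed,
    n_perm = n_perm,
    n_sites_input = length(sites) + length(dropped$removed),
    n_sites_retained = length(sites),
    excluded_sites = dropped$removed,
    removed_variables = screening$removed,
    kept_env_variables = kept_env,
    collinearity_threshold = collinearity_threshold,
    beta_ratio_rule = 0.5,
    substrate_encoding = substrate,
    mantel_tail = tail
  )

  structure(list(summary = summary, screening = screening, beta = beta3,
                 distances = predictors3, mantel = mant, decay = decay,
                 partition = partition, manifest = manifest, truth = truth),
            class = "beta_report")
}

#' @export
print.beta_report <- function(x, ...) {
  cat("Beta-diversity analysis report\n")
  cat("  sites retained:", x$manifest$n_sites_retained, "of",
      x$manifest$n_sites_input, "\n")
  if (length(x$manifest$excluded_sites)) {
    cat("  excluded (empty):", paste(x$manifest$excluded_sites, collapse = ", "), "\n")
  }
  if (length(x$manifest$removed_variables)) {
    cat("  variables removed by screening:",
        paste(x$manifest$removed_variables, collapse = ", "), "\n")
  }
  print(x$summary)
  cat("Mantel grid:\n")
  print(tibble::as_tibble(x$mantel), n = nrow(x$mantel))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits CSVs for the beta matrices, explanatory distances, summary,
#' screening decisions, Mantel grid, decay fits and partition table, plus a
#' JSON run manifest. Output is deterministic given the report, so reruns
#' with the same seed produce byte-identical bundles.
#'
#' @param report A `beta_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "beta_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  for (nm in names(report$beta)) {
    write_dist_matrix(report$beta[[nm]], p(paste0("beta_", nm, ".csv")))
  }
  for (nm in names(report$distances)) {
    write_dist_matrix(report$distances[[nm]], p(paste0("distance_", nm, ".csv")))
  }
  readr::write_csv(tidy(report$summary), p("beta_summary.csv"))
  readr::write_csv(tidy(report$screening), p("screening.csv"))
  readr::write_csv(tibble::as_tibble(report$mantel), p("mantel_table.csv"))
  decay_tbl <- purrr::imap_dfr(report$decay, function(f, nm) {
    dplyr::mutate(glance(f), pair = nm,
                  slope = f$slope, intercept = f$intercept, .before = 1L)
  })
  readr::write_csv(decay_tbl, p("distance_decay.csv"))
  readr::write_csv(tidy(report$partition), p("partition_table.csv"))
  readr::write_csv(glance(report$partition), p("mrm_models.csv"))
  jsonlite::write_json(report$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
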