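# Readers, validators and data-hygiene rules for the three input tables:
# site-by-species occurrences, transect metadata and environment variables.
# All three are plain tibbles with a leading `site_id` column.

detect_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a site-by-species occurrence table
#'
#' Reads a CSV/TSV with a header row and a leading site-id column. Cells may
#' be 0/1 incidences or abundance counts; counts are binarised on read
#' (`> 0` becomes 1) because all downstream dissimilarity statistics are
#' incidence-based.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A tibble: `site_id` plus one integer 0/1 column per species, in
#'   file order.
#' @export
read_occurrence <- function(path, delim = NULL) {
  if (!file.exists(path)) stop_sb(sprintf("File not found: %s", path), "io")
  tb <- readr::read_delim(path, delim = detect_delim(path, delim),
                          col_types = readr::cols(.default = readr::col_character()),
                          show_col_types = FALSE, progress = FALSE)
  names(tb)[1L] <- "site_id"
  for (col in names(tb)[-1L]) {
    vals <- suppressWarnings(as.numeric(tb[[col]]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1L]
      stop_sb(sprintf("Cell (%s, %s) = '%s' is not numeric.",
                      tb$site_id[bad], col, tb[[col]][bad]), "parse")
    }
    tb[[col]] <- as.integer(vals > 0)
  }
  check_occurrence(tb)
  tb
}

#' Write an occurrence table to CSV
#'
#' @param occ An occurrence tibble (see [read_occurrence()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrence <- function(occ, path) {
  check_occurrence(occ)
  readr::write_csv(occ, path)
  invisible(path)
}

#' Validate an occurrence table
#'
#' @param occ A tibble: `site_id` plus binary species columns.
#' @return `occ`, invisibly.
#' @export
check_occurrence <- function(occ) {
  if (!is.data.frame(occ) || ncol(occ) < 2L) {
    stop_sb("Occurrence table needs a site_id column plus species columns.",
            "invalid_occurrence")
  }
  ids <- occ[[1L]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_sb(sprintf("Duplicate site id(s): %s", paste(dup, collapse = ", ")),
            "invalid_occurrence")
  }
  if (anyDuplicated(names(occ))) {
    stop_sb("Duplicate species column names.", "invalid_occurrence")
  }
  m <- as.matrix(occ[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || !all(m %in% c(0, 1))) {
    stop_sb("All occurrence entries must be 0 or 1.", "invalid_occurrence")
  }
  invisible(occ)
}

#' Incidence matrix of an occurrence table
#'
#' @param occ An occurrence tibble.
#' @return An integer 0/1 matrix, sites in rows (named), species in columns.
#' @export
incidence_matrix <- function(occ) {
  check_occurrence(occ)
  m <- as.matrix(occ[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- occ[[1L]]
  m
}

#' Merge repeat surveys of the same transects
#'
#' Combines surveys of one site set from different years (or visits) by set
#' union: a species is present at a site if it was recorded there in any
#' survey. Species sets may differ between surveys; the merged table carries
#' the union of species, in order of first appearance.
#'
#' @param surveys A list of occurrence tibbles sharing the same site set
#'   (order may differ).
#' @return One occurrence tibble with sites ordered as in the first survey.
#' @export
merge_surveys <- function(surveys) {
  stopifnot(is.list(surveys), length(surveys) >= 1L)
  purrr::walk(surveys, check_occurrence)
  sites <- surveys[[1L]][[1L]]
  for (s in surveys[-1L]) {
    if (!setequal(s[[1L]], sites) || length(s[[1L]]) != length(sites)) {
      stop_sb("All surveys must cover the same set of sites.", "site_mismatch")
    }
  }
  species <- unique(unlist(lapply(surveys, function(s) names(s)[-1L])))
  acc <- matrix(0L, length(sites), length(species),
                dimnames = list(sites, species))
  for (s in surveys) {
    m <- incidence_matrix(s)
    acc[rownames(m), colnames(m)] <- acc[rownames(m), colnames(m)] | m
  }
  storage.mode(acc) <- "integer"
  dplyr::bind_cols(tibble::tibble(site_id = sites),
                   tibble::as_tibble(acc))
}

#' Exclude sites where no individuals were recorded
#'
#' Dissimilarity between an empty site and anything is undefined, so
#' all-zero rows are removed before any beta-diversity statistic. The
#' exclusion is explicit: removed site ids are returned (and logged in the
#' pipeline manifest), and metadata/environment tables must be subset to the
#' retained sites downstream.
#'
#' @param occ An occurrence tibble.
#' @return A list with `occurrence` (retained rows, untouched) and `removed`
#'   (character vector of excluded site ids, possibly empty).
#' @export
drop_empty_sites <- function(occ) {
  check_occurrence(occ)
  m <- incidence_matrix(occ)
  empty <- rowSums(m) == 0L
  if (all(empty)) stop_sb("Every site is empty; nothing to analyse.", "all_empty")
  list(
    occurrence = occ[!empty, , drop = FALSE],
    removed = rownames(m)[empty]
  )
}

#' Validate transect metadata
#'
#' @param meta A tibble with columns `site_id`, `latitude`, `longitude`
#'   (decimal degrees WGS84) and `elevation` (metres).
#' @return `meta`, invisibly.
#' @export
check_transect_meta <- function(meta) {
  need <- c("site_id", "latitude", "longitude", "elevation")
  if (!all(need %in% names(meta))) {
    stop_sb(sprintf("Metadata needs columns: %s.", paste(need, collapse = ", ")),
            "invalid_meta")
  }
  if (anyDuplicated(meta$site_id)) stop_sb("Duplicate site ids in metadata.", "invalid_meta")
  with(meta, {
    if (any(!is.finite(latitude)) || any(latitude < -90 | latitude > 90)) {
      stop_sb("Latitude out of [-90, 90].", "invalid_meta")
    }
    if (any(!is.finite(longitude)) || any(longitude < -180 | longitude > 180)) {
      stop_sb("Longitude out of [-180, 180].", "invalid_meta")
    }
    if (any(!is.finite(elevation))) stop_sb("Non-finite elevation.", "invalid_meta")
  })
  invisible(meta)
}

#' Read transect metadata / environment tables
#'
#' Both are delimited text with a header and a leading `site_id` column;
#' delimiters are auto-detected as in [read_occurrence()].
#'
#' @param path Path to a delimited text file.
#' @param delim Optional delimiter override.
#' @return A tibble.
#' @export
read_transect_meta <- function(path, delim = NULL) {
  tb <- readr::read_delim(path, delim = detect_delim(path, delim),
                          show_col_types = FALSE, progress = FALSE)
  names(tb)[1L] <- "site_id"
  check_transect_meta(tb)
  tb
}

#' @rdname read_transect_meta
#' @export
read_env_table <- function(path, delim = NULL) {
  tb <- readr::read_delim(path, delim = detect_delim(path, delim),
                          show_col_types = FALSE, progress = FALSE)
  names(tb)[1L] <- "site_id"
  check_env_table(tb)
  tb
}

#' Validate an environment table
#'
#' @param env A tibble: `site_id` plus numeric microhabitat columns.
#' @return `env`, invisibly.
#' @export
check_env_table <- function(env) {
  if (!is.data.frame(env) || ncol(env) < 2L) {
    stop_sb("Environment table needs site_id plus at least one variable.",
            "invalid_env")
  }
  if (anyDuplicated(env$site_id %||% env[[1L]])) {
    stop_sb("Duplicate site ids in environment table.", "invalid_env")
  }
  if (anyDuplicated(names(env))) stop_sb("Duplicate variable names.", "invalid_env")
  vals <- as.matrix(env[, -1L, drop = FALSE])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop_sb("All environment values must be finite numerics.", "invalid_env")
  }
  invisible(env)
}

# Subset meta/env tables to a retained site set, preserving that set's order.
align_sites <- function(tb, site_ids, arg = "table") {
  if (!all(site_ids %in% tb[[1L]])) {
    missing <- setdiff(site_ids, tb[[1L]])
    stop_sb(sprintf("%s lacks site(s): %s", arg, paste(missing, collapse = ", ")),
            "site_mismatch")
  }
  tb[match(site_ids, tb[[1L]]), , drop = FALSE]
}
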