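#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
NULL

np_schemas <- list(
  samples = c("sample_id", "latitude", "longitude", "depth", "age"),
  env = c("sample_id", "latitude", "sst", "sss", "po4", "ta", "dic",
          "d13c_dic", "mld", "sst_anomaly"),
  census = c("sample_id", "taxon", "count", "n_fov", "fov_area",
             "deposition_area", "sediment_mass"),
  morpho = c("sample_id", "taxon", "length", "width", "area", "mass")
)

check_rows <- function(df, what, cond, message) {
  bad <- which(!cond)
  if (length(bad)) {
    stop(what, ": ", message, " at row(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  }
  invisible(df)
}

#' Read and validate one pipeline table
#'
#' Reads a CSV against one of the four shared schemas (`samples`, `env`,
#' `census`, `morpho`), checking headers (case-sensitive) and the row-level
#' invariants of the schema; violations are reported with row numbers.
#'
#' @param path CSV path.
#' @param schema One of `"samples"`, `"env"`, `"census"`, `"morpho"`.
#' @return Validated tibble.
#' @export
read_table <- function(path, schema = c("samples", "env", "census", "morpho")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  missing <- setdiff(np_schemas[[schema]], names(df))
  if (length(missing)) {
    stop(schema, " table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_table(df, schema)
}

#' Validate an in-memory pipeline table
#'
#' @param df Tibble with the schema's columns.
#' @param schema Schema name as in [read_table()].
#' @return The validated tibble, invisibly usable downstream.
#' @export
validate_table <- function(df, schema = c("samples", "env", "census", "morpho")) {
  schema <- match.arg(schema)
  switch(schema,
    census = {
      check_rows(df, "census", df$count >= 0, "negative count")
      check_rows(df, "census", df$n_fov >= 1, "n_fov < 1")
      check_rows(df, "census", df$fov_area > 0, "non-positive fov_area")
      check_rows(df, "census", df$deposition_area > 0,
                 "non-positive deposition_area")
      check_rows(df, "census", df$sediment_mass > 0,
                 "non-positive sediment_mass")
    },
    morpho = {
      check_rows(df, "morpho", df$length > 0, "non-positive length")
      check_rows(df, "morpho", df$width > 0, "non-positive width")
      check_rows(df, "morpho", df$width <= df$length,
                 "width > length (violates W <= L)")
      check_rows(df, "morpho", df$area > 0, "non-positive area")
      check_rows(df, "morpho", df$mass > 0, "non-positive mass")
    },
    env = {
      check_rows(df, "env", df$ta > 0, "non-positive TA")
      check_rows(df, "env", df$dic > 0, "non-positive DIC")
    },
    samples = {
      check_rows(df, "samples", is.finite(df$latitude), "non-finite latitude")
      check_rows(df, "samples", df$depth > 0, "non-positive depth")
    }
  )
  df
}

#' Write the four pipeline tables to a directory
#'
#' Plain UTF-8 CSV with a header row, period decimal separator, 10
#' significant digits (write-then-read is identity on values at that
#' precision).
#'
#' @param tables Named list with any of `samples`, `env`, `census`,
#'   `morpho` (e.g. a [generate_transect()] result).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- intersect(names(np_schemas), names(tables))
  paths <- vapply(nm, function(x) {
    p <- file.path(dir, paste0(x, ".csv"))
    df <- tables[[x]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 10)
    utils::write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    p
  }, character(1))
  invisible(paths)
}

#' Run the whole reconstruction pipeline
#'
#' Chains census accounting, morphometric indices, growth-rate estimation,
#' environmental derivation, calcite production, boundary detection and the
#' proxy-environment correlation screen over the four input tables, and
#' returns every stage plus a machine-readable summary.
#'
#' @param samples,env,census,morpho The four validated input tables (see
#'   [read_table()] for schemas).
#' @param mu_cfg Growth-rate configuration, see [mu_config()].
#' @param alpha Significance threshold for the correlation screen.
#' @param window Boundary smoothing window.
#' @param size_threshold Gephyrocapsa small/large threshold, um.
#' @param taxonomy Taxonomy table.
#' @return List of class `"np_pipeline"`: `abundances`, `indices`, `fits`,
#'   `mu`, `env_state`, `production`, `groups`, `boundary`, `boundary_env`,
#'   `correlations`, `validation`, `summary` (list ready for JSON export,
#'   with a config hash and coefficient provenance).
#' @export
run_pipeline <- function(samples, env, census, morpho,
                         mu_cfg = mu_config(), alpha = 0.05, window = 1,
                         size_threshold = 3.0,
                         taxonomy = default_taxonomy()) {
  validate_table(samples, "samples"); validate_table(env, "env")
  validate_table(census, "census"); validate_table(morpho, "morpho")

  env_state <- derive_env_state(
    dplyr::left_join(env, samples[, c("sample_id", "depth")],
                     by = "sample_id"))
  abund <- census_abundances(census, taxonomy)
  morph <- morphometric_indices(morpho)
  mu_tab <- mu_size_profile(morph$indices, mu_cfg) |>
    dplyr::left_join(env_state[, c("sample_id", "po4", "sst", "co2")],
                     by = "sample_id") |>
    dplyr::mutate(
      mu_po4 = mu_from_po4(.data$po4, mu_cfg),
      mu_sst = mu_from_env(.data$sst, "sst", mu_cfg),
      mu_co2 = mu_from_env(.data$co2, "co2", mu_cfg)
    )
  prod <- production_summary(abund, morph$indices, samples,
                             env = env_state, window = window)

  validation <- samples |>
    dplyr::left_join(
      dplyr::summarise(census, total_count = sum(.data$count),
                       .by = "sample_id"),
      by = "sample_id") |>
    dplyr::left_join(env_state[, c("sample_id", "omega_calcite_depth")],
                     by = "sample_id")
  validation$flags <- vapply(seq_len(nrow(validation)), function(i) {
    paste(validate_sample(validation$depth[i],
                          validation$omega_calcite_depth[i],
                          validation$age[i], validation$total_count[i]),
          collapse = ";")
  }, character(1))

  proxies <- morph$indices |>
    dplyr::filter(!.data$flag_insufficient) |>
    dplyr::select(dplyr::all_of(c("sample_id", "taxon", "sn_thickness"))) |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "sn_thickness",
                       names_prefix = "sn_")
  envnum <- env_state[, c("sample_id", "sst", "sss", "po4", "d13c_dic",
                          "co2", "hco3", "dic_ta")]
  correlations <- correlation_matrix(proxies, envnum, alpha = alpha)

  cfg_hash <- rlang::hash(list(mu_cfg = unclass(mu_cfg), alpha = alpha,
                               window = window,
                               size_threshold = size_threshold,
                               taxonomy = taxonomy))
  summary <- list(
    config_hash = cfg_hash,
    provenance = mu_cfg$provenance,
    constants_dialect = env_state$constants_dialect[1],
    n_samples = nrow(samples),
    boundary_latitude = prod$boundary$primary,
    boundary_crossings = prod$boundary$crossings,
    boundary_env = prod$boundary_env,
    group_production = prod$groups[, c("sample_id", "latitude", "cp_low",
                                       "cp_high", "pct_low", "pct_high")],
    significant_correlations =
      correlations[correlations$significant,
                   c("proxy", "env", "n", "r", "p")],
    validation_flags = validation[nzchar(validation$flags),
                                  c("sample_id", "flags")]
  )
  structure(
    list(abundances = abund, indices = morph$indices, fits = morph$fits,
         mu = mu_tab, env_state = env_state, production = prod$taxon,
         groups = prod$groups, boundary = prod$boundary,
         boundary_env = prod$boundary_env, correlations = correlations,
         validation = validation, summary = summary),
    class = "np_pipeline"
  )
}

#' Export the pipeline summary as JSON
#'
#' @param pipeline A [run_pipeline()] result.
#' @param path Output path for the JSON summary.
#' @return Invisibly, `path`.
#' @export
write_summary_json <- function(pipeline, path) {
  stopifnot(inherits(pipeline, "np_pipeline"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(pipeline$summary, path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}
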