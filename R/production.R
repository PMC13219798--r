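#' Taxon-level calcite production per gram of sediment
#'
#' CP = N x mean coccolith mass: the coccolithophore-related calcite
#' concentration in sediment contributed by one taxon, in pg CaCO3 per gram
#' of dry sediment. The mean coccolith mass is per sample per taxon, never a
#' global mean.
#'
#' @param N Absolute abundance, coccoliths per g (>= 0; vectorised).
#' @param mean_mass Mean coccolith mass, pg CaCO3 (> 0, or NA for missing).
#' @return CP, pg CaCO3 per g sediment (NA where mass is missing).
#' @export
taxon_production <- function(N, mean_mass) {
  if (any(N < 0)) stop("`N` must be non-negative", call. = FALSE)
  if (any(mean_mass <= 0, na.rm = TRUE)) {
    stop("`mean_mass` must be positive where present", call. = FALSE)
  }
  N * mean_mass
}

#' Per-sample group production and relative contributions
#'
#' Sums taxon calcite production into the low and high PIC/POC groups and
#' expresses each group's share of the coccolithophore calcite production as
#' a percentage. Taxa with abundance but no usable mean mass are excluded
#' from the group sums with a warning.
#'
#' @param production Tibble with `sample_id`, `taxon`, `pic_poc_group`
#'   (`"low"`/`"high"`), `cp` (pg CaCO3/g; NA allowed).
#' @return Tibble with one row per sample: `cp_low`, `cp_high`, `cp_total`,
#'   `pct_low`, `pct_high`.
#' @export
group_contributions <- function(production) {
  stopifnot(all(c("sample_id", "taxon", "pic_poc_group", "cp")
                %in% names(production)))
  dropped <- production$cp
  if (anyNA(dropped)) {
    warning(sum(is.na(dropped)),
            " sample-taxon cells lack a usable mean mass and are excluded ",
            "from group production sums")
  }
  out <- production |>
    dplyr::summarise(
      cp_low = sum(.data$cp[.data$pic_poc_group == "low"], na.rm = TRUE),
      cp_high = sum(.data$cp[.data$pic_poc_group == "high"], na.rm = TRUE),
      .by = "sample_id"
    ) |>
    dplyr::mutate(cp_total = .data$cp_low + .data$cp_high)
  if (any(out$cp_total <= 0)) {
    stop("all-zero calcite production in sample(s): ",
         paste(out$sample_id[out$cp_total <= 0], collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(out,
                pct_low = 100 * .data$cp_low / .data$cp_total,
                pct_high = 100 * .data$cp_high / .data$cp_total)
}

#' Locate the low/high PIC/POC dominance boundary along the transect
#'
#' Works on the deviation D = pct_high - 50 of the high-group contribution
#' from the 50% crossover, ordered by latitude (optionally smoothed with a
#' centred moving average). Every sign change is located by linear
#' interpolation to D = 0; samples sitting exactly at 50% are themselves
#' crossings. The primary boundary is the crossing whose bracketing pair has
#' the largest |change in D| — a declared heuristic for noisy transects with
#' multiple crossings.
#'
#' @param latitudes Sample latitudes, decimal degrees (north positive).
#' @param pct_high High PIC/POC group contribution, percent.
#' @param window Odd moving-average window (default 1: no smoothing).
#' @return List of class `"boundary_result"`: `crossings` (degrees,
#'   descending latitude order), `primary` (degrees, or NA if no crossing).
#' @export
#' @examples
#' detect_boundary(c(50, 45, 35, 30), c(70, 60, 40, 30))
detect_boundary <- function(latitudes, pct_high, window = 1) {
  if (length(latitudes) != length(pct_high)) {
    stop("latitudes and pct_high differ in length", call. = FALSE)
  }
  if (length(latitudes) < 3) stop("need >= 3 samples", call. = FALSE)
  if (window %% 2 != 1 || window < 1) {
    stop("smoothing window must be odd and >= 1", call. = FALSE)
  }
  ord <- order(latitudes, decreasing = TRUE)
  lat <- latitudes[ord]
  if (anyDuplicated(lat)) {
    stop("latitudes must be strictly ordered after sorting", call. = FALSE)
  }
  d <- pct_high[ord] - 50
  if (window > 1) {
    d <- stats::filter(d, rep(1 / window, window), sides = 2)
    keep <- !is.na(d)
    lat <- lat[keep]; d <- as.numeric(d[keep])
  }
  crossings <- numeric(0)
  gaps <- numeric(0)
  for (i in seq_len(length(d) - 1)) {
    if (d[i] == 0) { crossings <- c(crossings, lat[i]); gaps <- c(gaps, abs(d[i + 1] - d[i])) }
    else if (d[i] * d[i + 1] < 0) {
      lat0 <- lat[i] + (0 - d[i]) * (lat[i + 1] - lat[i]) / (d[i + 1] - d[i])
      crossings <- c(crossings, lat0)
      gaps <- c(gaps, abs(d[i + 1] - d[i]))
    }
  }
  if (length(d) >= 1 && d[length(d)] == 0) {
    crossings <- c(crossings, lat[length(d)])
    gaps <- c(gaps, abs(d[length(d)] - d[length(d) - 1]))
  }
  primary <- if (length(crossings)) crossings[which.max(gaps)] else NA_real_
  structure(list(crossings = crossings, primary = primary),
            class = "boundary_result")
}

#' Environmental state interpolated at the dominance boundary
#'
#' Piecewise-linear interpolation of each environmental field to the
#' boundary latitude. Extrapolation outside the sampled latitude range is
#' refused.
#'
#' @param boundary Boundary latitude, degrees.
#' @param env Tibble with `latitude` plus numeric field columns.
#' @param fields Character vector of columns to interpolate; defaults to the
#'   fields characterized at the boundary (SST, phosphate, CO2, DIC/TA,
#'   d13C of DIC) intersected with what is present.
#' @return Named list of interpolated values.
#' @export
characterize_boundary <- function(boundary, env,
                                  fields = intersect(
                                    c("sst", "po4", "co2", "dic_ta",
                                      "d13c_dic"),
                                    names(env))) {
  stopifnot("latitude" %in% names(env), length(fields) > 0)
  lat <- env$latitude
  if (is.na(boundary) || boundary < min(lat) || boundary > max(lat)) {
    stop("boundary latitude outside the sampled range; extrapolation refused",
         call. = FALSE)
  }
  out <- lapply(fields, function(f) {
    stats::approx(lat, env[[f]], xout = boundary, ties = mean)$y
  })
  stats::setNames(out, fields)
}

#' Full production table for a transect
#'
#' Joins abundances and morphometric indices, computes taxon production and
#' group contributions, and locates/characterizes the dominance boundary.
#'
#' @param abundances Output of [census_abundances()].
#' @param indices Morphometric index tibble (needs `mean_mass`).
#' @param samples Tibble with `sample_id`, `latitude`.
#' @param env Optional environmental table for boundary characterization
#'   (needs `latitude` and fields).
#' @param window Smoothing window for [detect_boundary()].
#' @return List: `taxon` (per sample x taxon CP), `groups` (per sample
#'   contributions with latitude), `boundary` (boundary_result),
#'   `boundary_env` (named list or NULL).
#' @export
production_summary <- function(abundances, indices, samples, env = NULL,
                               window = 1) {
  prod <- abundances |>
    dplyr::left_join(indices[, c("sample_id", "taxon", "mean_mass")],
                     by = c("sample_id", "taxon")) |>
    dplyr::mutate(cp = taxon_production(.data$N, .data$mean_mass))
  groups <- group_contributions(prod) |>
    dplyr::left_join(samples[, c("sample_id", "latitude")], by = "sample_id")
  boundary <- detect_boundary(groups$latitude, groups$pct_high, window)
  boundary_env <- if (!is.null(env) && !is.na(boundary$primary)) {
    characterize_boundary(boundary$primary, env)
  } else NULL
  list(taxon = prod, groups = groups, boundary = boundary,
       boundary_env = boundary_env)
}
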