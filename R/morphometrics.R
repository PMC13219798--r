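#' Mean coccolith thickness from mass and area
#'
#' Thickness is the calcite mass spread over the imaged coccolith area at
#' calcite density: T = m / (rho * A).
#'
#' @param m Coccolith calcite mass, pg (vectorised).
#' @param A Coccolith area, um^2.
#' @param rho_calcite Calcite density, pg/um^3.
#' @return Mean thickness, um.
#' @export
#' @examples
#' mean_thickness(2.7, 1)   # 1 um
mean_thickness <- function(m, A, rho_calcite = np_constants[["rho_calcite"]]) {
  if (any(m <= 0) || any(A <= 0) || rho_calcite <= 0) {
    stop("mass, area and density must be positive", call. = FALSE)
  }
  m / (rho_calcite * A)
}

#' Fit the thickness-length allometry for one taxon
#'
#' Ordinary least squares of log mean thickness on log length,
#' ln T = ln t0 + beta * ln L, giving the allometric exponent used to
#' size-normalize thickness. The reference length is the geometric mean
#' length of the fitting set.
#'
#' @param length Coccolith lengths, um (>= 10 records).
#' @param thickness Mean thicknesses, um, same length.
#' @return List of class `"allometry_fit"`: `beta`, `ln_t0`, `L_ref` (um),
#'   `n`, `r_squared`.
#' @export
#' @examples
#' L <- seq(2, 4, length.out = 20)
#' fit_allometry(L, 0.1 * L^0.7)
fit_allometry <- function(length, thickness) {
  ok <- is.finite(length) & is.finite(thickness) & length > 0 & thickness > 0
  length <- length[ok]; thickness <- thickness[ok]
  if (length(length) < 10) {
    stop("at least 10 coccoliths with positive L and thickness are needed ",
         "for an allometry fit", call. = FALSE)
  }
  lL <- log(length)
  if (stats::sd(lL) == 0) {
    stop("zero variance in length: allometry exponent is unidentifiable",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, lL), log(thickness))
  res <- fit$residuals
  tss <- sum((log(thickness) - mean(log(thickness)))^2)
  structure(
    list(beta = unname(fit$coefficients[2]),
         ln_t0 = unname(fit$coefficients[1]),
         L_ref = exp(mean(lL)),
         n = length(length),
         r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_),
    class = "allometry_fit"
  )
}

#' Size-normalized (SN) thickness
#'
#' Rescales a coccolith's mean thickness to the taxon reference length with
#' the fitted allometric exponent, SN = T * (L_ref / L)^beta, removing the
#' size trend so residual thickness variability reads as calcification
#' intensity. At L = L_ref the index equals the raw thickness; with beta = 0
#' no normalization is applied.
#'
#' @param thickness Mean thickness, um (vectorised).
#' @param length Coccolith length, um.
#' @param fit An [fit_allometry()] result (or any list with `beta`, `L_ref`).
#' @return SN thickness, um.
#' @export
sn_thickness <- function(thickness, length, fit) {
  if (any(length <= 0)) stop("`length` must be positive", call. = FALSE)
  stopifnot(is.finite(fit$beta), fit$L_ref > 0)
  thickness * (fit$L_ref / length)^fit$beta
}

#' Elliptical shape factor kse
#'
#' The minimal elliptical generalization of the classic cubic shape factor:
#' kse = m / (rho * L^2 * W). It reduces to m / (rho * L^3) for circular
#' coccoliths (W = L) and is invariant under uniform magnification
#' (L, W, m) -> (sL, sW, s^3 m).
#'
#' @param m Coccolith mass, pg.
#' @param length Major axis, um.
#' @param width Minor axis, um.
#' @param rho_calcite Calcite density, pg/um^3.
#' @return Dimensionless shape factor.
#' @export
#' @examples
#' elliptical_shape_factor(162, 9, 8)
elliptical_shape_factor <- function(m, length, width,
                                    rho_calcite = np_constants[["rho_calcite"]]) {
  if (any(length <= 0) || any(width <= 0) || any(m <= 0)) {
    stop("axes and mass must be positive", call. = FALSE)
  }
  m / (rho_calcite * length^2 * width)
}

#' Cell diameter from coccolith length
#'
#' Linear dimensional relationship d = alpha + beta * L mapping coccolith
#' length to cell diameter. The coefficients are configuration values to be
#' transcribed from a culture-calibrated source; the defaults are
#' placeholder-scale values (provenance recorded in the config).
#'
#' @param length Coccolith length, um.
#' @param coeffs Named list/vector with `alpha` (um) and `beta`
#'   (dimensionless slope).
#' @return Cell diameter, um.
#' @export
cell_diameter_from_coccolith <- function(length, coeffs = list(alpha = 0, beta = 2)) {
  if (any(length <= 0)) stop("`length` must be positive", call. = FALSE)
  if (coeffs$beta == 0) {
    warning("beta = 0: cell diameter is constant in coccolith length")
  }
  d <- coeffs$alpha + coeffs$beta * length
  if (any(d <= 0)) stop("derived cell diameter is non-positive", call. = FALSE)
  d
}

#' Morphometric cellular PIC/POC quota
#'
#' PIC per cell is the mean coccolith calcite mass times coccoliths per cell
#' times the carbon mass fraction of CaCO3; POC per cell follows the
#' allometric carbon-volume scaling POC = a * V^b with V = (pi/6) d^3 from
#' the cell diameter. Their ratio is the morphometric PIC/POC index used for
#' the low PIC/POC group.
#'
#' @param mean_mass Mean coccolith mass, pg CaCO3.
#' @param coccoliths_per_cell Number of coccoliths per coccosphere (> 0).
#' @param cell_diameter Cell diameter, um.
#' @param poc_coeffs Named list with `a` (pg C um^-3b) and `b`; calibration
#'   constants of the carbon-volume scaling.
#' @param carbon_fraction Carbon mass fraction of CaCO3.
#' @return Tibble with `pic_pg_c`, `poc_pg_c`, `pic_poc`.
#' @export
#' @examples
#' cellular_pic_poc(1.5, 15, 5)
cellular_pic_poc <- function(mean_mass, coccoliths_per_cell, cell_diameter,
                             poc_coeffs = list(a = 0.216, b = 0.939),
                             carbon_fraction = np_constants[["caco3_carbon_fraction"]]) {
  if (any(coccoliths_per_cell <= 0)) {
    stop("`coccoliths_per_cell` must be positive", call. = FALSE)
  }
  if (any(mean_mass <= 0) || any(cell_diameter <= 0)) {
    stop("`mean_mass` and `cell_diameter` must be positive", call. = FALSE)
  }
  volume <- pi / 6 * cell_diameter^3
  pic <- mean_mass * coccoliths_per_cell * carbon_fraction
  poc <- poc_coeffs$a * volume^poc_coeffs$b
  tibble::tibble(pic_pg_c = pic, poc_pg_c = poc, pic_poc = pic / poc)
}

#' Per-sample, per-taxon morphometric indices
#'
#' Aggregates individual coccolith measurements into the per-sample indices
#' used downstream: mean length, mean mass, mean thickness, SN thickness and
#' kse. The allometry is fitted per taxon over the whole dataset (one global
#' reference length per taxon); sample-taxon cells with fewer than
#' `min_coccoliths` measurements are flagged and their indices reported as
#' missing.
#'
#' @param morpho Per-coccolith table with columns `sample_id`, `taxon`,
#'   `length`, `width`, `area`, `mass`.
#' @param min_coccoliths Minimum measured coccoliths per sample-taxon cell.
#' @param rho_calcite Calcite density, pg/um^3.
#' @return List with `indices` (tibble: sample_id, taxon, n, mean_length,
#'   mean_mass, mean_thickness, sn_thickness, kse, flag_insufficient) and
#'   `fits` (named list of per-taxon [fit_allometry()] results).
#' @export
morphometric_indices <- function(morpho, min_coccoliths = 10,
                                 rho_calcite = np_constants[["rho_calcite"]]) {
  stopifnot(all(c("sample_id", "taxon", "length", "width", "area", "mass")
                %in% names(morpho)))
  if (any(morpho$width > morpho$length)) {
    stop("width exceeds length for some records; invalid morphometry",
         call. = FALSE)
  }
  morpho <- morpho |>
    dplyr::mutate(thickness = mean_thickness(.data$mass, .data$area,
                                             rho_calcite))
  # proportional normalization (beta = 1) when the taxon-level fit is
  # unusable (too few coccoliths or degenerate lengths)
  fits <- lapply(split(morpho, morpho$taxon), function(d) {
    tryCatch(fit_allometry(d$length, d$thickness), error = function(e) {
      structure(list(beta = 1, ln_t0 = NA_real_,
                     L_ref = exp(mean(log(d$length))), n = nrow(d),
                     r_squared = NA_real_, fallback = TRUE),
                class = "allometry_fit")
    })
  })
  morpho <- morpho |>
    dplyr::mutate(
      sn = sn_thickness(.data$thickness, .data$length,
                        fits[[.data$taxon[1]]]),
      kse = elliptical_shape_factor(.data$mass, .data$length, .data$width,
                                    rho_calcite),
      .by = "taxon"
    )
  indices <- morpho |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_length = mean(.data$length),
      mean_mass = mean(.data$mass),
      mean_thickness = mean(.data$thickness),
      sn_thickness = mean(.data$sn),
      kse = mean(.data$kse),
      .by = c("sample_id", "taxon")
    ) |>
    dplyr::mutate(flag_insufficient = .data$n < min_coccoliths) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(c("mean_length", "mean_mass", "mean_thickness",
                      "sn_thickness", "kse")),
      ~ ifelse(.data$flag_insufficient, NA_real_, .x)
    ))
  list(indices = indices, fits = fits)
}
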