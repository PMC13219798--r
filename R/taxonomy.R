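#' Physical constants used throughout the package
#'
#' Density of calcite in pg per cubic micron and the carbon mass fraction of
#' CaCO3 (12.011 / 100.087). Both are exposed so alternative dialects can be
#' passed explicitly to the morphometric functions.
#'
#' @format Named numeric vector with elements `rho_calcite` (pg/um^3) and
#'   `caco3_carbon_fraction` (dimensionless).
#' @export
np_constants <- c(
  rho_calcite = 2.7,
  caco3_carbon_fraction = 12.011 / 100.087
)

#' Default taxonomy of the five target taxa
#'
#' The dominant modern-to-Holocene Atlantic coccolithophore taxa considered by
#' the pipeline, with their functional-group membership: *Gephyrocapsa* taxa
#' (small and large) form the low PIC/POC group; *Helicosphaera* spp.,
#' *Calcidiscus* spp. and *Coccolithus pelagicus* form the high PIC/POC group.
#'
#' @return A tibble with columns `taxon`, `size_class` (`"small"`, `"large"`
#'   or `NA` for taxa where the size split does not apply) and
#'   `pic_poc_group` (`"low"` or `"high"`).
#' @export
#' @examples
#' default_taxonomy()
default_taxonomy <- function() {
  tibble::tibble(
    taxon = c("small Gephyrocapsa", "large Gephyrocapsa",
              "Helicosphaera spp.", "Calcidiscus spp.",
              "Coccolithus pelagicus"),
    size_class = c("small", "large", NA, NA, NA),
    pic_poc_group = c("low", "low", "high", "high", "high")
  )
}

#' Assign a Gephyrocapsa coccolith to the small or large size class
#'
#' Applies the ~3/3.5 um size threshold conventional in sedimentary
#' nannofossil work. A coccolith exactly at the threshold is classed large.
#'
#' @param length Coccolith major-axis length in um (vectorised).
#' @param threshold Size threshold in um; the conventional choices are 3.0
#'   (default) and 3.5.
#' @return Character vector, `"small"` or `"large"`.
#' @export
#' @examples
#' assign_gephyrocapsa_size_class(c(2.8, 3.0, 4.0))
assign_gephyrocapsa_size_class <- function(length, threshold = 3.0) {
  if (!is.numeric(length) || any(!is.finite(length)) || any(length <= 0)) {
    stop("`length` must be finite and positive (um)", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold) ||
      threshold <= 0) {
    stop("`threshold` must be a single positive number (um)", call. = FALSE)
  }
  ifelse(length < threshold, "small", "large")
}

#' Assign a taxon to the low or high PIC/POC functional group
#'
#' Deterministic lookup against a taxonomy table. Unknown taxa raise an error
#' naming the offending taxon; they are never silently dropped.
#'
#' @param taxon Character vector of taxon names.
#' @param taxonomy Taxonomy table as returned by [default_taxonomy()].
#' @return Character vector of group labels, `"low"` or `"high"`.
#' @export
#' @examples
#' assign_pic_poc_group(c("small Gephyrocapsa", "Coccolithus pelagicus"))
assign_pic_poc_group <- function(taxon, taxonomy = default_taxonomy()) {
  idx <- match(taxon, taxonomy$taxon)
  if (anyNA(idx)) {
    bad <- unique(taxon[is.na(idx)])
    stop("unknown taxon (not in the configured taxonomy): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  taxonomy$pic_poc_group[idx]
}
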