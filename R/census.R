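#' Absolute abundance of coccoliths per gram of dry sediment
#'
#' Converts raw census counts obtained on a settling slide into coccoliths per
#' gram of sediment, following the areal-density accounting of the standard
#' settling technique: the counted fields of view sample a known fraction of
#' the deposition area, over which a known mass of dry sediment was settled,
#'
#' \deqn{N = \frac{count \times deposition\_area}{n\_fov \times fov\_area
#'   \times sediment\_mass}}
#'
#' All geometry is explicit so any dilution protocol can be expressed through
#' `sediment_mass` (mass settled over the deposition area).
#'
#' @param count Specimens counted (non-negative; vectorised).
#' @param n_fov Number of fields of view counted (>= 1).
#' @param fov_area Area of one field of view, mm^2.
#' @param deposition_area Area over which the suspension settled, mm^2.
#' @param sediment_mass Dry sediment mass settled over `deposition_area`, g.
#' @return Numeric, coccoliths per gram of dry sediment.
#' @export
#' @examples
#' absolute_abundance(300, n_fov = 50, fov_area = 0.02,
#'                    deposition_area = 1000, sediment_mass = 5e-4)
absolute_abundance <- function(count, n_fov, fov_area, deposition_area,
                               sediment_mass) {
  if (any(count < 0)) stop("`count` must be non-negative", call. = FALSE)
  if (any(n_fov < 1)) stop("`n_fov` must be >= 1", call. = FALSE)
  if (any(fov_area <= 0) || any(deposition_area <= 0) ||
      any(sediment_mass <= 0)) {
    stop("slide geometry (`fov_area`, `deposition_area`, `sediment_mass`) ",
         "must be positive", call. = FALSE)
  }
  count * deposition_area / (n_fov * fov_area * sediment_mass)
}

#' Relative abundance of taxa within one sample
#'
#' @param counts Named or unnamed non-negative numeric vector of counts for
#'   one sample; the total must be positive.
#' @return Numeric vector of fractions in \[0, 1\] summing to 1, with the
#'   names of `counts`.
#' @export
#' @examples
#' relative_abundance(c(A = 240, B = 60))
relative_abundance <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("all-zero sample: cannot form fractions", call. = FALSE)
  counts / total
}

#' Validate a sample against the study's inclusion criteria
#'
#' Flags (never aborts on) samples outside the conditions under which
#' sedimentary coccolith assemblages are treated as representative of surface
#' production: water depth below 3000 m, calcite saturation at the seafloor
#' at or below 1 (dissolution-prone), ages older than the late Holocene
#' (>= 3000 yr BP), and census totals under the 300-specimen minimum.
#'
#' @param depth Water depth, m (positive down).
#' @param omega_at_depth Calcite saturation state at the sample depth.
#' @param age Sample age, years BP.
#' @param total_count Total specimens counted in the census.
#' @return Character vector of raised flags, possibly empty; a subset of
#'   `c("depth", "omega", "age", "count")`.
#' @export
#' @examples
#' validate_sample(2500, 1.6, 2000, 320)  # character(0): passes
#' validate_sample(3200, 0.9, 2000, 250)
validate_sample <- function(depth, omega_at_depth, age, total_count) {
  stopifnot(is.finite(depth), is.finite(omega_at_depth), is.finite(age),
            is.finite(total_count))
  flags <- character(0)
  if (depth >= 3000) flags <- c(flags, "depth")
  if (omega_at_depth <= 1) flags <- c(flags, "omega")
  if (age >= 3000) flags <- c(flags, "age")
  if (total_count < 300) flags <- c(flags, "count")
  flags
}

#' Census accounting for a whole transect
#'
#' Applies [absolute_abundance()] and [relative_abundance()] per sample x
#' taxon and attaches the functional-group assignment.
#'
#' @param census Census table with columns `sample_id`, `taxon`, `count`,
#'   `n_fov`, `fov_area`, `deposition_area`, `sediment_mass`.
#' @param taxonomy Taxonomy table, see [default_taxonomy()].
#' @return Tibble with one row per sample x taxon: `count`, `N` (coccoliths
#'   per g), `rel_abundance`, `pic_poc_group`.
#' @export
census_abundances <- function(census, taxonomy = default_taxonomy()) {
  stopifnot(all(c("sample_id", "taxon", "count", "n_fov", "fov_area",
                  "deposition_area", "sediment_mass") %in% names(census)))
  census |>
    dplyr::mutate(
      N = absolute_abundance(.data$count, .data$n_fov, .data$fov_area,
                             .data$deposition_area, .data$sediment_mass),
      pic_poc_group = assign_pic_poc_group(.data$taxon, taxonomy)
    ) |>
    dplyr::mutate(
      rel_abundance = relative_abundance(.data$count),
      .by = "sample_id"
    ) |>
    dplyr::select(dplyr::all_of(c("sample_id", "taxon", "pic_poc_group",
                                  "count", "N", "rel_abundance")))
}
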