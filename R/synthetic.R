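#' Default per-taxon generator parameters
#'
#' Niche, growth and morphometry parameters for the five target taxa. Mean
#' lengths and shape factors are calibrated so per-coccolith mass ratios are
#' of the observed order (C. pelagicus carries roughly 80 times the calcite
#' of a small Gephyrocapsa coccolith); thermal optima follow the groups'
#' biogeography (C. pelagicus subpolar, Gephyrocapsa temperate-subtropical).
#' `gamma` encodes the opposite growth-calcification coupling of the two
#' functional groups: positive for the low PIC/POC taxa (thickness rises
#' with growth rate) and negative for the high PIC/POC taxa.
#'
#' @return Tibble of per-taxon parameters.
#' @export
default_taxon_params <- function() {
  tibble::tibble(
    taxon = c("small Gephyrocapsa", "large Gephyrocapsa",
              "Helicosphaera spp.", "Calcidiscus spp.",
              "Coccolithus pelagicus"),
    pic_poc_group = c("low", "low", "high", "high", "high"),
    sst_opt = c(18, 21, 17, 13, 8),       # degC
    sst_width = c(9, 7, 6, 6, 5),          # degC
    k_po4 = c(0.08, 0.12, 0.30, 0.35, 0.40),  # umol/L
    w_max = c(1.00, 0.35, 0.018, 0.030, 0.32),  # max relative weight
    mu_max = c(1.20, 1.00, 0.55, 0.50, 0.45), # div/day
    mean_length = c(2.5, 4.0, 9.0, 7.0, 9.5), # um
    sdlog_length = c(0.12, 0.12, 0.10, 0.10, 0.10),
    wl_ratio = c(0.80, 0.80, 0.78, 0.90, 0.85),
    t0 = c(0.060, 0.060, 0.050, 0.100, 0.062),  # um at L = 1 um
    beta_true = c(1.0, 1.0, 0.9, 1.0, 1.0),
    gamma = c(0.5, 0.5, -0.5, -0.5, -0.5),   # per (div/day)
    size_mu_slope = c(0.20, 0.20, 0.20, 0.20, 0.20)
  )
}

#' Generator configuration for a synthetic meridional transect
#'
#' Bundles the study conditions emulated by the generator: 19 samples
#' spanning 60 N to 30 S, at least 300 specimens counted per sample
#' (default 320), 35 coccoliths measured per taxon per sample, settling-
#' slide geometry, smooth latitudinal environmental curves plus noise, and
#' the per-taxon niche/morphometry parameters of [default_taxon_params()].
#'
#' @param n_samples Number of samples along the transect (>= 3).
#' @param lat_range Latitude span, degrees (north positive), default
#'   `c(60, -30)`.
#' @param seed Integer seed; same config + seed gives identical tables.
#' @param total_count Specimens counted per sample (>= 300).
#' @param n_measure Coccoliths measured per taxon per sample.
#' @param taxa Per-taxon parameter tibble, see [default_taxon_params()].
#' @param deposition_area,fov_area Slide geometry, mm^2.
#' @param sediment_mass Dry sediment settled, g.
#' @param abundance_floor Minimum relative weight preventing zero-probability
#'   multinomials.
#' @param n_scale Overall abundance scale, coccoliths per g at unit
#'   growth-weighted niche.
#' @param noise_sd Named numeric vector of environmental noise standard
#'   deviations (`sst`, `po4`, `ta`, `dic`, `sss`, `d13c`, `mld`).
#' @return List of class `"transect_config"`.
#' @export
transect_config <- function(n_samples = 19, lat_range = c(60, -30),
                            seed = 1L, total_count = 320, n_measure = 35,
                            taxa = default_taxon_params(),
                            deposition_area = 1000, fov_area = 0.02,
                            sediment_mass = 5e-4, abundance_floor = 1e-4,
                            n_scale = 4e8,
                            noise_sd = c(sst = 0.3, po4 = 0.04, ta = 8,
                                         dic = 8, sss = 0.1, d13c = 0.06,
                                         mld = 10)) {
  stopifnot(n_samples >= 3, total_count >= 300, n_measure >= 10,
            all(taxa$sst_width > 0), all(taxa$k_po4 > 0),
            all(noise_sd >= 0), abundance_floor > 0)
  low <- taxa$pic_poc_group == "low"
  if (!all(taxa$gamma[low] > 0) || !all(taxa$gamma[!low] < 0)) {
    stop("gamma must be > 0 for low PIC/POC taxa and < 0 for high PIC/POC ",
         "taxa (opposite growth-calcification coupling)", call. = FALSE)
  }
  structure(
    list(n_samples = n_samples, lat_range = lat_range, seed = as.integer(seed),
         total_count = total_count, n_measure = n_measure, taxa = taxa,
         deposition_area = deposition_area, fov_area = fov_area,
         sediment_mass = sediment_mass, abundance_floor = abundance_floor,
         n_scale = n_scale, noise_sd = noise_sd),
    class = "transect_config"
  )
}

#' Ecological niche weight of a taxon
#'
#' Gaussian thermal niche times Michaelis-Menten nutrient limitation:
#' w = exp(-(sst - opt)^2 / (2 sigma^2)) * po4 / (po4 + K), in \[0, 1\],
#' maximal at the thermal optimum and saturating in phosphate.
#'
#' @param sst Sea surface temperature, degC.
#' @param po4 Surface phosphate, umol/L.
#' @param sst_opt,sst_width Thermal optimum and niche width, degC (> 0).
#' @param k_po4 Phosphate half-saturation, umol/L (> 0).
#' @return Dimensionless weight in \[0, 1\].
#' @export
#' @examples
#' niche_weight(20, 0.1, sst_opt = 20, sst_width = 5, k_po4 = 0.1)  # 0.5
niche_weight <- function(sst, po4, sst_opt, sst_width, k_po4) {
  if (any(!is.finite(sst)) || any(!is.finite(po4))) {
    stop("non-finite niche inputs", call. = FALSE)
  }
  stopifnot(all(sst_width > 0), all(k_po4 > 0))
  exp(-(sst - sst_opt)^2 / (2 * sst_width^2)) * po4 / (po4 + k_po4)
}

# Smooth (noise-free) environmental curves along latitude. Calibrated so the
# dominance crossover sits near 40 N with SST ~15 degC, [PO4] ~0.5 umol/L,
# DIC/TA ~0.9 and [CO2] ~13 umol/kg there.
smooth_env_fields <- function(lat) {
  al <- abs(lat) / 60
  po4 <- 0.15 + 1.3 * pmax(0, (lat - 25) / 35)^1.5 +
    0.9 * pmax(0, (-lat - 20) / 40)^1.5 + 0.25 * exp(-(lat / 12)^2)
  ta <- 2400 - 110 * al^2.2
  ratio <- 0.862 + 0.056 * al^1.3
  sst <- 27.5 - 22.5 * al^1.5
  # surface d13C of DIC enrichment follows photosynthetic carbon
  # utilisation by the dominant temperate producers: heavy where their
  # growth peaks, light toward the nutrient-rich, weakly utilised subpolar
  # surface
  util <- exp(-(sst - 18)^2 / (2 * 81)) * po4 / (po4 + 0.08)
  tibble::tibble(
    latitude = lat,
    sst = sst,
    po4 = po4,
    ta = ta,
    dic = ratio * ta,
    sss = 35.2 + 1.3 * exp(-((abs(lat) - 28) / 15)^2) - 1.2 * al^3,
    d13c_dic = 0.5 + 1.5 * util,
    mld = 30 + 270 * al^2.5,
    sst_anomaly = 0.7 + 0.2 * lat / 60
  )
}

# Expected (true) mean coccolith mass for one sample-taxon cell, from the
# lognormal length distribution and the multiplicative noise terms:
# m = rho * 0.8 * wl * t0 * c * L^(2+beta) * exp(eps_w + eps_t).
true_mean_mass <- function(p, ln_mean_length, coupling,
                           sd_w = 0.03, sd_t = 0.08,
                           rho = np_constants[["rho_calcite"]]) {
  q <- 2 + p$beta_true
  rho * 0.8 * p$wl_ratio * p$t0 * coupling *
    exp(q * ln_mean_length + q^2 * p$sdlog_length^2 / 2) *
    exp(sd_w^2 / 2) * exp(sd_t^2 / 2)
}

#' Generate a synthetic meridional transect
#'
#' Draws a complete four-table dataset (sample metadata, environment,
#' census, per-coccolith morphometry) with the statistical structure the
#' downstream pipeline assumes, plus a truth record for parameter-recovery
#' tests. Counts are multinomial over growth-weighted niche abundances;
#' lengths are lognormal per taxon; thickness follows the taxon allometry
#' modulated by the group-specific growth-calcification coupling
#' (`1 + gamma * (mu - mu_ref)`), so low PIC/POC thickness rises with
#' growth rate and high PIC/POC thickness falls; mass is calcite density
#' times area times thickness.
#'
#' @param config A [transect_config()].
#' @return List: `samples` (sample_id, latitude, longitude, depth, age),
#'   `env` (raw environmental table), `census`, `morpho`, and `truth`
#'   (list with per sample x taxon `mu_true`, `rel_abundance_true`,
#'   `mean_mass_true`, `N_true`, and the transect-level
#'   `crossover_latitude`).
#' @export
#' @examples
#' tr <- generate_transect(transect_config(seed = 42))
#' head(tr$census)
generate_transect <- function(config = transect_config()) {
  stopifnot(inherits(config, "transect_config"))
  set.seed(config$seed)
  n <- config$n_samples
  taxa <- config$taxa
  nt <- nrow(taxa)
  lat <- seq(config$lat_range[1], config$lat_range[2], length.out = n)
  sm <- smooth_env_fields(lat)
  ns <- config$noise_sd
  env <- sm |>
    dplyr::mutate(
      sample_id = sprintf("S%02d", seq_len(n)),
      sst = .data$sst + stats::rnorm(n, 0, ns[["sst"]]),
      po4 = pmax(0.01, .data$po4 + stats::rnorm(n, 0, ns[["po4"]])),
      ta = .data$ta + stats::rnorm(n, 0, ns[["ta"]]),
      dic = .data$dic + stats::rnorm(n, 0, ns[["dic"]]),
      sss = .data$sss + stats::rnorm(n, 0, ns[["sss"]]),
      d13c_dic = .data$d13c_dic + stats::rnorm(n, 0, ns[["d13c"]]),
      mld = pmax(10, .data$mld + stats::rnorm(n, 0, ns[["mld"]]))
    ) |>
    dplyr::select(dplyr::all_of(c("sample_id", "latitude", "sst", "sss",
                                  "po4", "ta", "dic", "d13c_dic", "mld",
                                  "sst_anomaly")))
  samples <- tibble::tibble(
    sample_id = env$sample_id,
    latitude = lat,
    longitude = -25 + stats::runif(n, -8, 8),
    depth = stats::runif(n, 1500, 2900),
    age = stats::runif(n, 500, 2500)
  )

  census_rows <- list(); morpho_rows <- list(); truth_rows <- list()
  degenerate <- numeric(0)
  for (i in seq_len(n)) {
    w <- niche_weight(env$sst[i], env$po4[i], taxa$sst_opt, taxa$sst_width,
                      taxa$k_po4)
    mu_true <- taxa$mu_max * w
    a <- pmax(taxa$w_max * w, config$abundance_floor)
    if (all(taxa$w_max * w < config$abundance_floor)) {
      degenerate <- c(degenerate, round(lat[i], 1))
    }
    N_taxon <- config$n_scale * a * mu_true / taxa$mu_max
    N_taxon <- pmax(N_taxon, config$n_scale * config$abundance_floor)
    N_total <- sum(N_taxon)
    p <- N_taxon / N_total
    counts <- as.integer(stats::rmultinom(1, config$total_count, p))
    n_fov <- max(1L, as.integer(round(
      config$total_count * config$deposition_area /
        (config$fov_area * config$sediment_mass * N_total))))
    census_rows[[i]] <- tibble::tibble(
      sample_id = env$sample_id[i], taxon = taxa$taxon, count = counts,
      n_fov = n_fov, fov_area = config$fov_area,
      deposition_area = config$deposition_area,
      sediment_mass = config$sediment_mass
    )
    mu_ref <- taxa$mu_max / 2
    coupling <- pmax(0.1, 1 + taxa$gamma * (mu_true - mu_ref))
    ln_mean_L <- log(taxa$mean_length) -
      taxa$size_mu_slope * (mu_true / taxa$mu_max - 0.5)
    taxon_morpho <- lapply(seq_len(nt), function(j) {
      m <- config$n_measure
      L <- stats::rlnorm(m, ln_mean_L[j], taxa$sdlog_length[j])
      W <- pmin(taxa$wl_ratio[j] * L * exp(stats::rnorm(m, 0, 0.03)),
                0.999 * L)
      A <- 0.8 * L * W
      Th <- taxa$t0[j] * L^taxa$beta_true[j] * coupling[j] *
        exp(stats::rnorm(m, 0, 0.08))
      tibble::tibble(sample_id = env$sample_id[i], taxon = taxa$taxon[j],
                     length = L, width = W, area = A,
                     mass = np_constants[["rho_calcite"]] * A * Th)
    })
    morpho_rows[[i]] <- dplyr::bind_rows(taxon_morpho)
    truth_rows[[i]] <- tibble::tibble(
      sample_id = env$sample_id[i], latitude = lat[i], taxon = taxa$taxon,
      pic_poc_group = taxa$pic_poc_group,
      mu_true = mu_true, rel_abundance_true = p, N_true = N_taxon,
      mean_mass_true = vapply(seq_len(nt), function(j) {
        true_mean_mass(taxa[j, ], ln_mean_L[j], coupling[j])
      }, numeric(1))
    )
  }
  if (length(degenerate)) {
    warning("degenerate niche at latitude(s) ",
            paste(degenerate, collapse = ", "),
            ": all weights at the abundance floor; sample(s) emitted with ",
            "uniform floor abundances")
  }
  truth_tab <- dplyr::bind_rows(truth_rows) |>
    dplyr::mutate(cp_true = .data$N_true * .data$mean_mass_true)
  truth_groups <- truth_tab |>
    dplyr::summarise(
      cp_high = sum(.data$cp_true[.data$pic_poc_group == "high"]),
      cp_total = sum(.data$cp_true),
      .by = c("sample_id", "latitude")
    ) |>
    dplyr::mutate(pct_high = 100 * .data$cp_high / .data$cp_total)
  truth_boundary <- detect_boundary(truth_groups$latitude,
                                    truth_groups$pct_high)

  list(samples = samples, env = env,
       census = dplyr::bind_rows(census_rows),
       morpho = dplyr::bind_rows(morpho_rows),
       truth = list(table = truth_tab, groups = truth_groups,
                    crossover_latitude = truth_boundary$primary))
}
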