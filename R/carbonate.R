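#' Equilibrium constants of the seawater carbonate system
#'
#' Computes the dissociation constants needed to speciate the TA-DIC pair:
#' K1, K2 of carbonic acid (Lueker et al. 2000, total pH scale), KB of boric
#' acid (Dickson 1990), KW of water (Millero 1995), the calcite solubility
#' product (Mucci 1983) and total boron and calcium from salinity. Pressure
#' dependence follows the Millero (1995) molal-volume corrections, so the
#' same dialect serves surface speciation and saturation state at depth.
#'
#' @param temperature Temperature, degC (-2 to 40).
#' @param salinity Practical salinity (0 to 45).
#' @param pressure Pressure, dbar (0 at surface).
#' @param dialect Constants dialect label recorded in provenance; only
#'   `"Lueker00"` is implemented.
#' @return Named list: `K1`, `K2`, `KB`, `KW`, `Ksp_calcite` (mol/kg scale),
#'   `BT`, `Ca` (mol/kg), plus the inputs and `dialect`.
#' @export
carbonate_constants <- function(temperature, salinity, pressure = 0,
                                dialect = "Lueker00") {
  stopifnot(dialect == "Lueker00")
  if (temperature < -2 || temperature > 40) {
    stop("temperature outside oceanographic range [-2, 40] degC", call. = FALSE)
  }
  if (salinity < 0 || salinity > 45) {
    stop("salinity outside range [0, 45]", call. = FALSE)
  }
  TK <- temperature + 273.15
  S <- salinity

  # Lueker et al. (2000), total scale, pK = a/TK + b + c ln TK + dS + eS^2
  pK1 <- 3633.86 / TK - 61.2172 + 9.6777 * log(TK) -
    0.011555 * S + 0.0001152 * S^2
  pK2 <- 471.78 / TK + 25.929 - 3.16967 * log(TK) -
    0.01781 * S + 0.0001122 * S^2
  K1 <- 10^(-pK1)
  K2 <- 10^(-pK2)

  # Dickson (1990) boric acid, total scale
  lnKB <- (-8966.90 - 2890.53 * sqrt(S) - 77.942 * S +
             1.728 * S^1.5 - 0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqrt(S) + 1.62142 * S +
    (-24.4344 - 25.085 * sqrt(S) - 0.2474 * S) * log(TK) +
    0.053105 * sqrt(S) * TK
  KB <- exp(lnKB)

  # Millero (1995) water dissociation
  lnKW <- 148.9802 - 13847.26 / TK - 23.6521 * log(TK) +
    (118.67 / TK - 5.977 + 1.0495 * log(TK)) * sqrt(S) - 0.01615 * S
  KW <- exp(lnKW)

  # Mucci (1983) calcite stoichiometric solubility product
  log10Ksp <- -171.9065 - 0.077993 * TK + 2839.319 / TK +
    71.595 * log10(TK) +
    (-0.77712 + 0.0028426 * TK + 178.34 / TK) * sqrt(S) -
    0.07711 * S + 0.0041249 * S^1.5
  Ksp <- 10^log10Ksp

  # Uppstrom (1974) total boron; Riley & Tongudai (1967) calcium
  BT <- 0.000416 * S / 35
  Ca <- 0.02128 / 40.087 * S / 1.80655

  if (pressure > 0) {
    Pbar <- pressure / 10
    Tc <- temperature
    Rgas <- 83.131  # cm^3 bar mol^-1 K^-1
    pcorr <- function(K, a0, a1, a2, b0, b1) {
      dV <- a0 + a1 * Tc + a2 * Tc^2
      dK <- (b0 + b1 * Tc) / 1000
      K * exp((-dV + 0.5 * dK * Pbar) * Pbar / (Rgas * TK))
    }
    K1 <- pcorr(K1, -25.50, 0.1271, 0, -3.08, 0.0877)
    K2 <- pcorr(K2, -15.82, -0.0219, 0, 1.13, -0.1475)
    KB <- pcorr(KB, -29.48, 0.1622, -0.002608, -2.84, 0)
    KW <- pcorr(KW, -20.02, 0.1119, -0.001409, -5.13, 0.0794)
    Ksp <- pcorr(Ksp, -48.76, 0.5304, 0, -11.76, 0.3692)
  }

  list(K1 = K1, K2 = K2, KB = KB, KW = KW, Ksp_calcite = Ksp,
       BT = BT, Ca = Ca,
       temperature = temperature, salinity = salinity, pressure = pressure,
       dialect = dialect)
}

#' Speciate the carbonate system from total alkalinity and DIC
#'
#' Solves the proton balance TA = [HCO3-] + 2[CO3^2-] + [B(OH)4-] + [OH-] -
#' [H+] for [H+] by safeguarded root finding over pH 2-12, then partitions
#' DIC into [CO2], [HCO3-] and [CO3^2-] and evaluates the calcite saturation
#' state Omega = [Ca^2+][CO3^2-] / Ksp. Nutrient alkalinity is neglected,
#' which is adequate for the open-ocean surface samples this package
#' targets.
#'
#' @param TA Total alkalinity, umol/kg (500-4000).
#' @param DIC Dissolved inorganic carbon, umol/kg (500-4000).
#' @param temperature Temperature, degC.
#' @param salinity Practical salinity.
#' @param pressure Pressure, dbar.
#' @param dialect Constants dialect, see [carbonate_constants()].
#' @return Tibble (vectorised over inputs) with `co2`, `hco3`, `co3`
#'   (umol/kg), `ph` (total scale), `omega_calcite`, and the `dialect`
#'   recorded for provenance.
#' @export
#' @examples
#' solve_carbonate(2300, 2100, 15, 35)
solve_carbonate <- function(TA, DIC, temperature, salinity, pressure = 0,
                            dialect = "Lueker00") {
  n <- max(length(TA), length(DIC), length(temperature), length(salinity),
           length(pressure))
  TA <- rep_len(TA, n); DIC <- rep_len(DIC, n)
  temperature <- rep_len(temperature, n); salinity <- rep_len(salinity, n)
  pressure <- rep_len(pressure, n)
  if (any(TA < 500 | TA > 4000) || any(DIC < 500 | DIC > 4000)) {
    stop("TA and DIC must lie in [500, 4000] umol/kg", call. = FALSE)
  }
  out <- lapply(seq_len(n), function(i) {
    k <- carbonate_constants(temperature[i], salinity[i], pressure[i], dialect)
    ta <- TA[i] * 1e-6
    dic <- DIC[i] * 1e-6
    resid <- function(h) {
      denom <- h^2 + k$K1 * h + k$K1 * k$K2
      ac <- dic * (k$K1 * h + 2 * k$K1 * k$K2) / denom
      ac + k$BT * k$KB / (k$KB + h) + k$KW / h - h - ta
    }
    lo <- 10^-12; hi <- 10^-2
    if (resid(lo) * resid(hi) > 0) {
      stop("no alkalinity root in pH [2, 12] for TA = ", TA[i],
           ", DIC = ", DIC[i], call. = FALSE)
    }
    h <- stats::uniroot(resid, c(lo, hi), tol = 1e-20)$root
    denom <- h^2 + k$K1 * h + k$K1 * k$K2
    co2 <- dic * h^2 / denom
    hco3 <- dic * k$K1 * h / denom
    co3 <- dic * k$K1 * k$K2 / denom
    c(co2 = co2 * 1e6, hco3 = hco3 * 1e6, co3 = co3 * 1e6,
      ph = -log10(h), omega_calcite = k$Ca * co3 / k$Ksp_calcite)
  })
  out <- do.call(rbind, out)
  tibble::tibble(co2 = unname(out[, "co2"]), hco3 = unname(out[, "hco3"]),
                 co3 = unname(out[, "co3"]), ph = unname(out[, "ph"]),
                 omega_calcite = unname(out[, "omega_calcite"]),
                 dialect = dialect)
}

#' Ratio of dissolved inorganic carbon to total alkalinity
#'
#' @param DIC,TA Same units (umol/kg); TA > 0.
#' @return Dimensionless DIC/TA.
#' @export
dic_ta_ratio <- function(DIC, TA) {
  if (any(TA <= 0)) stop("TA must be positive", call. = FALSE)
  DIC / TA
}

#' Correct a modern SST to preindustrial values
#'
#' Subtracts the regional industrial SST anomaly from the modern annual SST.
#'
#' @param sst_modern Modern SST, degC.
#' @param anomaly Industrial-era SST anomaly at that location, degC.
#' @return Preindustrial SST, degC.
#' @export
preindustrial_sst <- function(sst_modern, anomaly) {
  stopifnot(all(is.finite(sst_modern)), all(is.finite(anomaly)))
  sst_modern - anomaly
}

#' Derive the environmental state table
#'
#' Augments a raw per-sample environmental table with carbonate speciation
#' at the surface (the standardized extraction depth), the DIC/TA ratio,
#' preindustrial SST, and the calcite saturation state at the sample's water
#' depth (approximating in-situ temperature at depth with the surface value,
#' a conservative choice for these shallow-to-intermediate depths).
#'
#' @param env Tibble with `sample_id`, `latitude`, `sst`, `sss`, `po4`,
#'   `ta`, `dic`, `d13c_dic`, `mld`, `sst_anomaly` and (for Omega at depth)
#'   `depth`.
#' @param dialect Constants dialect.
#' @return The input with `co2`, `hco3`, `co3`, `ph`, `dic_ta`,
#'   `sst_preindustrial` and `omega_calcite_depth` appended.
#' @export
derive_env_state <- function(env, dialect = "Lueker00") {
  stopifnot(all(c("sample_id", "sst", "sss", "po4", "ta", "dic",
                  "sst_anomaly") %in% names(env)))
  spec <- solve_carbonate(env$ta, env$dic, env$sst, env$sss,
                          pressure = 0, dialect = dialect)
  omega_depth <- if ("depth" %in% names(env)) {
    solve_carbonate(env$ta, env$dic, env$sst, env$sss,
                    pressure = env$depth, dialect = dialect)$omega_calcite
  } else NA_real_
  env |>
    dplyr::mutate(
      co2 = spec$co2, hco3 = spec$hco3, co3 = spec$co3, ph = spec$ph,
      dic_ta = dic_ta_ratio(.data$dic, .data$ta),
      sst_preindustrial = preindustrial_sst(.data$sst, .data$sst_anomaly),
      omega_calcite_depth = omega_depth,
      constants_dialect = dialect
    )
}
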