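# Independent oracles used to cross-check the package implementations.
# These are deliberately coded along different routes than the package.

# Brute-force Pearson R and two-sided p: explicit product-moment sums and
# the t cumulative distribution, no call into the package or cor().
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Independent carbonate-system reference: solves the same alkalinity balance
# by bisection on pH (not [H+]) with its own speciation expressions written
# in terms of pH and alpha fractions.
oracle_carbonate <- function(TA, DIC, temperature, salinity, pressure = 0) {
  k <- nannoproxy::carbonate_constants(temperature, salinity, pressure)
  ta <- TA * 1e-6; dic <- DIC * 1e-6
  alk_resid <- function(ph) {
    h <- 10^(-ph)
    a0 <- 1 / (1 + k$K1 / h + k$K1 * k$K2 / h^2)   # CO2 fraction
    a1 <- 1 / (h / k$K1 + 1 + k$K2 / h)            # HCO3 fraction
    a2 <- 1 / (h^2 / (k$K1 * k$K2) + h / k$K2 + 1) # CO3 fraction
    dic * (a1 + 2 * a2) + k$BT / (1 + h / k$KB) + k$KW / h - h - ta
  }
  lo <- 2; hi <- 12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (alk_resid(lo) * alk_resid(mid) <= 0) hi <- mid else lo <- mid
  }
  ph <- (lo + hi) / 2
  h <- 10^(-ph)
  a0 <- 1 / (1 + k$K1 / h + k$K1 * k$K2 / h^2)
  a1 <- 1 / (h / k$K1 + 1 + k$K2 / h)
  a2 <- 1 / (h^2 / (k$K1 * k$K2) + h / k$K2 + 1)
  list(co2 = dic * a0 * 1e6, hco3 = dic * a1 * 1e6, co3 = dic * a2 * 1e6,
       ph = ph, omega_calcite = k$Ca * dic * a2 / k$Ksp_calcite)
}

# Small default transect shared across tests.
make_transect <- function(seed = 1, ...) {
  generate_transect(transect_config(seed = seed, ...))
}
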