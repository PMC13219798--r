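#!/usr/bin/env Rscript
# Growth-rate profiles: the size-based estimate (coccolith length -> cell
# diameter -> volume -> inverse size-growth law) compared against the
# independent nutrient, SST and CO2 parametrizations.

suppressMessages({library(nannoproxy); library(dplyr)})

samples <- read_table("results/transect/samples.csv", "samples")
env <- read_table("results/transect/env.csv", "env")
indices <- read.csv("results/morphometric_indices.csv")

cfg <- mu_config()
env_state <- derive_env_state(left_join(env, samples[, c("sample_id", "depth")],
                                        by = "sample_id"))
mu <- mu_size_profile(tibble::as_tibble(indices), cfg) |>
  left_join(env_state[, c("sample_id", "po4", "sst", "co2")],
            by = "sample_id") |>
  mutate(mu_po4 = mu_from_po4(po4, cfg),
         mu_sst = mu_from_env(sst, "sst", cfg),
         mu_co2 = mu_from_env(co2, "co2", cfg))
write.csv(mu, "results/mu_profiles.csv", row.names = FALSE)

for (tx in unique(mu$taxon)) {
  d <- mu[mu$taxon == tx, ]
  cmp <- compare_mu_profiles(d$mu_size, d$mu_po4)
  cat(sprintf("%-22s R(mu_size, mu_po4) = %5.2f (p = %.3g, rank R = %5.2f)\n",
              tx, cmp$pearson_r, cmp$p_value, cmp$rank_r))
}
cat("growth-rate coefficients:", cfg$provenance, "\n")
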