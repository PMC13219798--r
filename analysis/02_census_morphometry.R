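#!/usr/bin/env Rscript
# Census accounting and coccolith morphometry: absolute abundances N per
# gram of sediment, relative abundances, and the per-sample calcification
# indices (mean thickness, SN thickness, kse) with per-taxon allometry fits.

suppressMessages({library(nannoproxy); library(dplyr)})

census <- read_table("results/transect/census.csv", "census")
morpho <- read_table("results/transect/morpho.csv", "morpho")

ab <- census_abundances(census)
mi <- morphometric_indices(morpho)

dir.create("results", showWarnings = FALSE)
write.csv(ab, "results/abundances.csv", row.names = FALSE)
write.csv(mi$indices, "results/morphometric_indices.csv", row.names = FALSE)

cat("N spans", format(min(ab$N[ab$N > 0]), digits = 3), "to",
    format(max(ab$N), digits = 3), "coccoliths per g\n")
for (tx in names(mi$fits)) {
  f <- mi$fits[[tx]]
  cat(sprintf("allometry %-22s beta = %.2f (R2 %.2f, n %d)\n",
              tx, f$beta, f$r_squared, f$n))
}
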