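#!/usr/bin/env Rscript
# Inter-coder agreement: Fleiss' kappa per flight-parameter combination and
# thermal-contrast zone, Landis-Koch bands, and per-band shares.

library(tirsurvey)

coders <- read_coder_table("results/coders.csv")
design <- read_count_table("results/counts.csv")

agr <- agreement_summary(coders, design)
write_table_csv(agr$cells, "results/agreement_cells.csv")
jsonlite::write_json(list(zone_shares = agr$zone_shares,
                          marginal_shares = agr$marginal_shares,
                          band_convention = agr$band_convention),
                     "results/agreement.json", auto_unbox = TRUE, digits = NA)
print(agr)

for (z in c("high", "low")) {
  zs <- agr$zone_shares[agr$zone_shares$zone == z, ]
  hi <- 100 * sum(zs$share[zs$band %in% c("substantial", "almost perfect")])
  cat(sprintf("%s-contrast zones: substantial or better in %.0f%% of combinations\n",
              z, hi))
}
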