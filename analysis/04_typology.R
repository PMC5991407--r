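#!/usr/bin/env Rscript
# Stage 4: improvement typology.
#
# Maps each evaluated project's four effectiveness flags to the seven
# improvement types (EI, SI, PI, II, SPI, SII, OI), in the default
# inclusive reading ("at least these indicators effective"); the literal
# exclusive label is kept alongside. Requires results/indicators.csv from
# stage 3.

library(fcndvi)

ind_path <- "results/indicators.csv"
if (!file.exists(ind_path)) stop("run analysis/03_indicators.R first: ",
                                 ind_path, " not found")
indicators <- read.csv(ind_path)
typed <- assign_types_cohort(indicators)
write.csv(typed, "results/typology.csv", row.names = FALSE)

rates <- effectiveness_rates(typed)
cat("former-cohort improvement-type rates (inclusive mode):\n")
for (ty in improvement_types())
  cat(sprintf("  %-4s %6.2f%%  (%d projects)\n", ty,
              rates[[paste0("rate_", ty)]], rates[[paste0("count_", ty)]]))
cat(sprintf("identity check: EI rate %.2f%% == upgraded-PL rate %.2f%%\n",
            rates$rate_EI, rates$rate_effective_pl))
cat("exclusive labels:\n")
print(table(typed$exclusive_label))
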