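#!/usr/bin/env Rscript
## Cytogenetic coordination: RNA-FISH signal counts and cis/trans scoring
## of the focal probe against a known random-monoallelic reference probe
## (coordination in nearly all cells = random monoallelic expression under
## chromosome-wide control; ~50% cis would have indicated imprinting), and
## ReTiSH replication-asynchrony aggregation.

source("analysis/00_config.R")

fish <- read.delim(file.path(SIM_DIR, "fish_cells.tsv"))
cnts <- summarize_fish_counts(fish, "vlinc273")
coord <- score_cis_trans(fish, c("vlinc273", "KCNQ5"))
print(coord)

## imprinting model for contrast: homologs drawn independently
imp <- simulate_fish_table("imprinted", 400, detection_rate = 0.9,
                           seed = child_seed(MASTER_SEED, 8))
imp_coord <- score_cis_trans(imp, c("vlinc273", "KCNQ5"))

retish <- read.delim(file.path(SIM_DIR, "retish_cells.tsv"))
rt <- aggregate_retish(retish, "ASAR6", "vlinc273")

tsv(data.frame(
  metric = c("single_signal_fraction", "two_signal_fraction",
             "cis_fraction", "coordination_p", "classification",
             "imprinted_model_cis_fraction",
             "retish_cis_fraction", "retish_informative_cells"),
  value = c(cnts$fractions[["1"]], cnts$fractions[["2"]],
            coord$cis_fraction, coord$p_value, coord$classification,
            imp_coord$cis_fraction, rt$cis_fraction, rt$n_informative)),
  "results/coordination.tsv")
message(sprintf(
  "FISH: %.0f%% single-signal cells; %.0f%% cis (p = %.2g) vs %.0f%% under the imprinting model",
  100 * cnts$monoallelic_fraction, 100 * coord$cis_fraction,
  coord$p_value, 100 * imp_coord$cis_fraction))
message(sprintf("ReTiSH: cis fraction %.2f over %d informative cells",
                rt$cis_fraction, rt$n_informative))
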