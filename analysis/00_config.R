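## Shared configuration for the analysis scripts. Every script sources this
## file, seeds all randomness from MASTER_SEED via child_seed(), and writes
## its outputs under results/.
##
## The simulated system mirrors the study conditions: a 6 Mb chromosome-6
## analog carrying a cluster of six intergenic vlinc-like windows inside a
## 1 Mb region, of which only the sixth (185 kb, L1 fraction 0.29 vs the
## 13% autosomal background) is expressed; nuclear retention >100-fold;
## monoallelic expression from homolog B phased by mono-chromosomal hybrid
## genotypes; FISH/ReTiSH coordination; BrdU homolog ratios of 1.0 (intact
## and silent-allele deletion) vs 2.0 (expressed-allele deletion).

suppressMessages({
  library(asarscan)
  library(GenomicRanges)
})

MASTER_SEED <- 20200601L

GENOME <- c(chr6S = 6e6)
CLUSTER <- GRanges("chr6S",
                   IRanges(c(2000001, 2250001, 2400001, 2520001, 2650001,
                             2800001),
                           width = c(80000, 60000, 55000, 52000, 70000,
                                     185000)))
CLUSTER$l1_target <- c(rep(0.13, 5), 0.29)
CLUSTER$name <- c("vlinc271s", "vlinc1010s", "vlinc1011s", "vlinc1012s",
                  "vlinc272s", "vlinc273s")
FOCAL <- CLUSTER[6]

SIM_DIR <- "results/sim"
dir.create(SIM_DIR, showWarnings = FALSE, recursive = TRUE)

tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
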