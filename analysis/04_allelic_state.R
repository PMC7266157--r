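#!/usr/bin/env Rscript
## Allelic state of the focal domain from RNA allele counts at heterozygous
## SNPs, homolog assignment via the mono-chromosomal hybrid genotypes, and
## nuclear retention from the two coverage fractions.

source("analysis/00_config.R")

counts <- read_allele_counts(file.path(SIM_DIR, "allele_counts.tsv"))
hybrids <- read.delim(file.path(SIM_DIR, "hybrid_genotypes.tsv"))
calls <- assign_expressed_homolog(call_snp_allelic(counts), hybrids)
tsv(calls, "results/snp_calls.tsv")
loc <- locus_allelic_call(calls)
print(loc)

nuclear <- read_coverage(file.path(SIM_DIR, "nuclear.bedGraph"),
                         genome = GENOME)
cyto <- read_coverage(file.path(SIM_DIR, "cytoplasmic.bedGraph"),
                      genome = GENOME)
dom <- read.delim("results/domains.tsv")
focal <- GRanges(dom$chrom[1], IRanges(dom$start[1], dom$end[1]))
fold <- nuclear_enrichment(mean_depth_over(nuclear, focal),
                           mean_depth_over(cyto, focal),
                           pseudocount = 1 / width(focal))
tsv(data.frame(locus = "focal", state = loc$state,
               expressed_homolog = loc$expressed_homolog,
               n_informative_snps = loc$n_informative_snps,
               major_allele_fraction = loc$major_allele_fraction,
               nuclear_fold = fold),
    "results/allelic_state.tsv")
message(sprintf("nuclear retention: %.0f-fold", fold))
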