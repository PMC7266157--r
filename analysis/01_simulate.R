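#!/usr/bin/env Rscript
## Generate the synthetic study system and write it in the standard formats
## the rest of the analysis consumes (BED / bedGraph / TSV + a JSON
## manifest), so scripts 02-07 never touch the simulator objects directly.

source("analysis/00_config.R")

message("Simulating annotation (genes, exons, repeats) ...")
ann <- simulate_annotation(GENOME, planted_windows = CLUSTER,
                           seed = child_seed(MASTER_SEED, 1))
genes <- ann[mcols(ann)$kind %in% c("gene", "exon")]
reps <- ann[mcols(ann)$kind == "repeat"]
write_features_bed(genes[mcols(genes)$kind == "gene"],
                   file.path(SIM_DIR, "genes.bed"))
tsv(as.data.frame(ann), file.path(SIM_DIR, "annotation.tsv"))
write_features_bed(reps, file.path(SIM_DIR, "repeats.bed"))

message("Simulating nuclear and cytoplasmic coverage ...")
expr <- granges(CLUSTER)
expr$depth <- c(rep(0.2, 5), 20)      # only the focal window is expressed
nuclear <- simulate_coverage(expr, GENOME, noise = "poisson",
                             seed = child_seed(MASTER_SEED, 2))
cyto_dom <- granges(FOCAL)
cyto_dom$depth <- 0.1                 # ~200x nuclear retention
cyto <- simulate_coverage(cyto_dom, GENOME, noise = "poisson",
                          seed = child_seed(MASTER_SEED, 3))
write_coverage_bedgraph(nuclear, file.path(SIM_DIR, "nuclear.bedGraph"))
write_coverage_bedgraph(cyto, file.path(SIM_DIR, "cytoplasmic.bedGraph"))

message("Simulating allele counts, FISH, ReTiSH ...")
counts <- simulate_allele_counts("monoallelic", 3, 50, 0.01,
                                 expressed_homolog = "B", chrom = "chr6S",
                                 region = c(start(FOCAL), end(FOCAL)),
                                 seed = child_seed(MASTER_SEED, 4))
tsv(counts, file.path(SIM_DIR, "allele_counts.tsv"))
tsv(hybrid_table(counts), file.path(SIM_DIR, "hybrid_genotypes.tsv"))
tsv(simulate_fish_table("coordinated_cis", 100, detection_rate = 0.9,
                        miscall_rate = 0.02, biallelic_rate = 0.02,
                        seed = child_seed(MASTER_SEED, 5)),
    file.path(SIM_DIR, "fish_cells.tsv"))
tsv(simulate_retish_table("async_cis", 60,
                          seed = child_seed(MASTER_SEED, 6)),
    file.path(SIM_DIR, "retish_cells.tsv"))

manifest <- list(master_seed = MASTER_SEED, genome = as.list(GENOME),
                 cluster = as.data.frame(CLUSTER),
                 expressed_depth = 20, background_l1 = 0.13,
                 focal_l1 = 0.29)
jsonlite::write_json(manifest, file.path(SIM_DIR, "manifest.json"),
                     auto_unbox = TRUE, digits = NA)
message("Inputs written under ", SIM_DIR)
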