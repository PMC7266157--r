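# asarscan

Screening chromosomes for **ASAR** lncRNA candidates.

ASARs ("ASynchronous replication and Autosomal RNA" genes) are very long
noncanonical lncRNA genes whose expressed allele controls the replication
timing of its whole chromosome in cis: deleting the expressed — but not the
silent — allele delays replication of the entire homolog. Known ASARs look
like vlincRNAs (>50 kb of contiguous, nonspliced, nonpolyadenylated,
non-genic transcription), are strongly nuclear-retained, are rich in
antisense LINE-1 sequence, and show random monoallelic expression with
chromosome-wide coordinated asynchronous replication.

`asarscan` is an R package for geneticists and genome biologists who want
to find and characterize loci with this profile. It implements, as tested
reusable functions plus a numbered analysis workflow:

1. **Transcribed-domain calling** — maximal runs of coverage `>= min_cov`,
   gaps `<= max_gap` bridged, spans `>= 50 kb` kept, protein-coding
   overlaps removed (`call_transcribed_domains`, `filter_protein_coding`).
2. **L1 composition and enrichment** — the L1-covered fraction of an
   interval, tested against an intron-resampling null: replicate intronic
   segments of the domain's length *L* are drawn (whole introns
   concatenated, the last trimmed to the exact remainder), a beta law
   Beta(α, β) is fitted to the replicate fractions by the method of
   moments (c = m(1−m)/v − 1, α = mc, β = (1−m)c), and the p-value is the
   beta upper tail P(X ≥ observed), with the empirical rank p-value
   (r+1)/(n+1) alongside (`l1_fraction`, `build_intron_set`,
   `sample_intron_null`, `l1_enrichment_pvalue`).
3. **Allelic state** — per-SNP monoallelic/biallelic calls from RNA allele
   counts at heterozygous SNPs (major fraction ≥ 0.95 at depth ≥ 20),
   expressed-homolog assignment via mono-chromosomal hybrid genotypes, and
   nuclear/cytoplasmic enrichment ratios (`call_snp_allelic`,
   `assign_expressed_homolog`, `locus_allelic_call`,
   `nuclear_enrichment`).
4. **Cytogenetic coordination** — RNA-FISH signal-count summaries and the
   exact two-sided binomial test of cis vs trans configuration against
   p = 0.5 (the random-vs-imprinted logic: ~50% cis in a non-clonal
   population indicates imprinting, near-total coordination indicates
   random monoallelic expression under chromosome-wide control), plus
   ReTiSH early/late-allele classification with centromere QC
   (`score_cis_trans`, `classify_retish_cell`, `aggregate_retish`).
5. **Replication timing** — metaphase image quantification (Otsu
   segmentation, homolog identification by centromere size, total BrdU =
   mean intensity × area per homolog), per-cell 6B/6A ratios, and
   tie-corrected Kruskal–Wallis group comparison with an optional
   permutation p (`brdu_ratio_image`, `brdu_ratio_table`,
   `kruskal_wallis`).
6. **The screen** — `run_screen()` conjoins the criteria (length,
   noncoding, nuclear fold ≥ 5, monoallelic, L1 p < 0.05) into a flagged,
   fully traceable candidate report.

A first-class **synthetic-data module** (`simulate_annotation`,
`simulate_coverage`, `simulate_allele_counts`, `simulate_fish_table`,
`simulate_retish_table`, `simulate_brdu_image`) generates data with the
statistical structure of the motivating study system — a 185 kb focal
domain at 29% L1 inside a six-domain cluster against a 13% autosomal
background, >100× nuclear retention, monoallelic expression from one of
two separable homologs — so every stage is testable without downloads.
See the methods vignette (`vignettes/asar-candidate-screen.Rmd`) for the
models, parameter rationale, and limitations.

## Worked example

The `analysis/` scripts run the whole study on simulated data
(`Rscript analysis/01_simulate.R` … `07_screen.R`; outputs under
`results/`). The core of it, interactively:

```r
library(asarscan)
library(GenomicRanges)

## a 6 Mb chromosome analog with a gene-free 185 kb window at 29% L1
win <- GRanges("chr6S", IRanges(2000001, 2185000), l1_target = 0.29)
ann <- simulate_annotation(c(chr6S = 6e6), planted_windows = win, seed = 42)

## nuclear coverage: the window expressed at depth 20 over zero background
dom <- granges(win); dom$depth <- 20
trk <- simulate_coverage(dom, c(chr6S = 6e6), noise = "poisson", seed = 7)

called <- call_transcribed_domains(trk, min_cov = 5, max_gap = 100)
width(called)
#> [1] 185000

comp <- l1_fraction(called, ann)
comp$l1_fraction
#> [1] 0.29

introns <- build_intron_set(ann)
null <- sample_intron_null(introns, ann, L = width(called),
                           n_reps = 10000, seed = 11)
null
#> resampling_null: 10000 replicates of length 185000; mean fraction 0.1301;
#> beta(16.92, 113.11)
l1_enrichment_pvalue(null, comp$l1_fraction, "beta_tail")
#> [1] 5.68e-06
l1_enrichment_pvalue(null, comp$l1_fraction, "empirical")
#> [1] 9.999e-05
```

Reading: the called domain spans 185 kb; 29% of it is L1-covered, while
same-length intronic segments average ~13% (the autosomal background), so
both the beta-tail and the empirical p call the L1 content significantly
enriched. On a *real* genome the null is wider (L1 clusters), so real
p-values are larger; the synthetic run validates the machinery, not a
specific published p. Downstream, the same simulated system gives a
monoallelic locus call on homolog B at a major-allele fraction of 0.99, a
~200-fold nuclear enrichment, a FISH cis fraction of 0.99 (coordination
p ≈ 3e-20, vs ~0.5 under the imprinting model), a ReTiSH cis fraction of
1.0, and BrdU group medians of 1.00 / 1.00 / 2.00 for intact /
silent-deleted / expressed-deleted cells (Kruskal–Wallis p ≈ 6e-05) — the
full ASAR signature, recovered by `run_screen()` as exactly one flagged
candidate.

A small **synthetic** RepeatMasker-format annotation of a 185 kb window
(`inst/extdata/vlinc273_region_rmsk_synthetic.out`, see the README there)
exercises the `.out` reader and the composition path:

```r
reps <- read_features(system.file("extdata",
          "vlinc273_region_rmsk_synthetic.out", package = "asarscan"),
          "rmsk_out")
l1_fraction(GRanges("chr6", IRanges(140730001, 140915000)), reps,
            transcription_strand = "+")
#> repeat_composition chr6:140730001-140915000  L1 fraction 0.290  (antisense 0.202)
```

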