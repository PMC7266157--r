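---
title: "Methods: screening for ASAR lncRNA candidates"
author: "asarscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for ASAR lncRNA candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The biological problem

ASARs ("ASynchronous replication and Autosomal RNA" genes) are a class of
very long, noncanonical lncRNA genes with a striking cis-acting function:
deleting the *expressed* allele — but not the silent one — delays the
replication timing of the entire chromosome that carries it. Known ASARs
share a recognizable profile:

* they look like vlincRNAs — contiguous, nonspliced, nonpolyadenylated
  transcription over more than 50 kb, outside protein-coding genes;
* the RNA is strongly retained in the nucleus, associated with the
  chromosome territory that transcribes it;
* the transcribed sequence is rich in LINE-1 (L1) elements, particularly
  in the antisense orientation;
* expression is subject to programmed random monoallelic expression
  (PRME): one allele per clone, chosen at random, coordinated with other
  random monoallelic loci on the same chromosome;
* the two alleles replicate asynchronously, again coordinated
  chromosome-wide.

`asarscan` implements the computational side of a screen for this profile:
domain calling from coverage, repeat-composition statistics with a
resampling null, allelic-state calling with homolog assignment,
cytogenetic (FISH / ReTiSH) coordination scoring, and homolog-resolved
BrdU replication-timing quantification. Because the underlying raw data
for the motivating system (a human fibrosarcoma line with two separable
chromosome 6 homologs) is not publicly deposited, the package ships a
synthetic-data generator that reproduces the *statistical structure* of
every assay, so the full pipeline is testable end to end.

## Transcribed-domain calling

A domain is a maximal run of positions with depth `>= min_cov`, after
bridging sub-threshold gaps of at most `max_gap` bases, kept when its
genomic span reaches `min_len` (default 50,000 bases — the vlinc length
criterion). Design choices:

* **Relative coverage default.** No published threshold delimits these
  domains, so `min_cov` defaults to 0.25 x the median nonzero depth of the
  track, with an absolute floor of 2 reads. A relative default adapts to
  library depth; both knobs are exposed.
* **Gap accounting.** Bridged (sub-threshold) bases count toward the
  domain's *length* — length is genomic span — but not toward the
  `mean_depth` numerator, which averages observed signal over
  above-threshold positions only. Hence `mean_depth >= min_cov` always
  holds.
* **Strand handling.** Stranded tracks are called per strand; unstranded
  tracks yield unstranded domains.
* **"Not associated with protein-coding genes"** is operationalized as
  gene-*body* overlap on either strand (default tolerance 0 bases),
  not exon-only overlap: vlincRNAs are defined intergenically, and the
  stricter rule is the safer screen. The tolerance is a parameter.
* **A monotonicity caveat.** Raising `min_cov` never increases the total
  called length, but it *can* increase the number of domains when a
  bridged domain splits into two pieces that each clear `min_len`. Only
  the length form of the monotonicity property is guaranteed (and
  tested).

## L1 composition and the intron-resampling null

The L1 fraction of an interval is the number of its bases covered by the
union of L1 repeat annotations, divided by its length — merged first, so
overlapping repeat fragments are never double-counted. L1 membership means
RepeatMasker class/family `LINE/L1` (or a bare `L1` label in 6-column
BEDs); the predicate is replaceable. When the transcription strand is
known, the antisense L1 fraction (L1 elements on the opposite strand) is
reported, since antisense L1 content is the functionally implicated
orientation.

Enrichment is judged against introns, the natural "expressed but
nonfunctional-sequence" background. Each of `n_reps` (default 10,000)
replicates assembles an intronic segment of exactly the focal domain's
length `L`:

1. introns are drawn uniformly **with replacement** from the canonically
   sorted merged intron set (sorting makes the draw independent of input
   order);
2. whole introns are concatenated until the running length reaches `L`;
3. the final intron is trimmed to the exact remainder, starting at a
   uniformly chosen in-intron offset.

The replicate's L1 fraction is its L1-covered bases over `L`. A beta law
is fitted to the replicate fractions by the method of moments
(`c = m(1-m)/v - 1`, `alpha = mc`, `beta = (1-m)c`), and the enrichment
p-value is the beta upper tail at the observed fraction; the empirical
rank p-value `(r+1)/(n_reps+1)` is always reported alongside. Choices
worth recording:

* **Whole-intron concatenation.** "Intronic regions of length `L`" is
  ambiguous when few single introns reach vlinc scale; concatenation keeps
  every replicate at exactly `L` without restricting to the longest
  introns. (Sampling fixed-length windows *within* long introns only would
  bias the null toward large genes.)
* **Span, not exonic length.** `L` is the genomic span of the domain —
  the transcript class is unspliced, so span and transcript length
  coincide.
* **Beta tail as the headline p.** The fitted tail interpolates below the
  empirical resolution limit of `1/(n_reps+1)`. The two agree within
  Monte-Carlo error through roughly the 95th percentile of the null; in
  the far tail a two-moment fit cannot be expected to track the empirical
  distribution, which is why both numbers are always emitted. A degenerate
  null (all replicate fractions equal) flags the fit unavailable; the
  empirical p remains valid.
* Intron sets come from per-gene gaps between exons, merged across genes,
  with any candidate intron that overlaps an exon of any gene removed
  entirely (not trimmed).

## Allelic state and homolog assignment

The motivating assay reads allelic state qualitatively from Sanger traces
at SNPs heterozygous in genomic DNA. The quantitative proxy here: a SNP is
*monoallelic* when its RNA major-allele fraction is at least
`mono_threshold` (default 0.95, boundary inclusive) at depth at least
`min_depth` (default 20); below threshold it is *biallelic*; below depth,
*indeterminate*. No per-SNP statistical test is applied by default — the
categorical readout matches the source assay, and a binomial null is not
meaningful at Sanger-like depth.

Homolog assignment uses a mono-chromosomal hybrid genotype table (one
genotype per homolog per SNP): the expressed major allele matching exactly
one homolog's allele assigns that homolog; matching both or neither gives
"unknown". The labels A/B are arbitrary per sample and fixed by the
table. A locus is monoallelic only when every informative SNP is
monoallelic *and* the homolog assignments agree; one biallelic SNP makes
the locus biallelic; conflicting homologs make it indeterminate.

Nuclear retention is the fold ratio of nuclear to cytoplasmic levels on a
common normalized scale, regularized by a pseudocount. In the screen the
levels are mean depth over the domain and the pseudocount is one read over
the domain span — the smallest observable level on that scale — so a locus
absent from the cytoplasmic fraction gets a large, finite, depth-dependent
fold rather than infinity.

## FISH and ReTiSH coordination

For two probed loci, cells with exactly one signal per probe are
informative; the cis count (both signals on the same homolog) is tested
against p = 0.5 with the exact two-sided binomial test (summation of all
outcome probabilities at most that of the observed count — `binom.test`'s
method). Classification at `alpha` (default 0.01) gives
coordinated-cis/-trans or not-coordinated; the exact p is always reported.
The logic of the assay: in a *non-clonal* population, a ~50% cis fraction
is what imprinting (parent-of-origin choice) predicts, whereas near-total
coordination with a known PRME locus identifies random monoallelic
expression under chromosome-wide control. Cells showing two signals for a
probe (biallelic-appearing, a few percent in practice) are excluded from
coordination and tallied separately.

ReTiSH distinguishes early- from late-replicating alleles: a 14 h BrdU
pulse covers all of S phase (signal on both homologs — a QC requirement),
a 5 h pulse only late S, so a 5 h signal on exactly one homolog marks that
homolog's allele as late-replicating. Centromeric heterochromatin is late,
so the centromere probe must label both homologs at both time points; any
violation fails the cell's QC. Aggregation reports, among cells where both
loci are asynchronous, the fraction with late alleles on the same homolog.

## BrdU replication timing

From a metaphase image triplet (DAPI, BrdU, centromere), the pipeline

1. segments chromosome bodies from DAPI by Otsu's threshold plus
   connected components (minimum area 50 px);
2. identifies homologs by the centromere-size polymorphism: of the two
   bodies, the one with the larger integrated centromere signal is 6A.
   Blobs within a 10% relative margin are indistinguishable and the cell
   is excluded — a tie-break that prefers dropping a cell to guessing;
3. measures each chromosome as mean pixel intensity x occupied area
   (identically the pixel sum — asserted to machine precision in the
   tests), after subtracting the per-image median of non-mask pixels from
   the BrdU channel (background correction is on for images, off for
   pre-extracted workstation tables, which are assumed corrected);
4. forms the per-cell ratio total BrdU(6B) / total BrdU(6A), and
5. compares genotype groups with the tie-corrected Kruskal–Wallis test.

The chi-square p of the Kruskal–Wallis test is an approximation that is
visibly off at the 8–12 cells per group typical of metaphase counts (we
measured 0.019 vs an exact 0.006 on a 3 x 4 instance); a Monte-Carlo
permutation p (`p_method = "permutation"`) is provided and is what the
test suite validates against an independent permutation oracle. The H
statistic itself is exact and invariant under strictly monotone transforms
of the measurements.

## What the synthetic generator emulates — and what it does not

The generator reproduces the study conditions as statistical structure:

* a 6 Mb chromosome analog whose repeat content is placed by sequential
  uniform sampling with overlap rejection (log-normal fragment lengths,
  median ~1 kb), filled to target coverage fractions — 13% L1 for
  autosomal background, 27% for an X-analog, 29% for the planted 185 kb
  focal window, which is kept gene-free; the final fragment is trimmed so
  realized fractions land on target;
* coverage with Poisson (or noiseless) depth inside planted domains —
  a six-window cluster with only the focal window expressed emulates the
  one-expressed-among-six situation;
* allele counts at heterozygous SNPs phased to homologs, with minor
  counts Binomial(depth, error_rate) for monoallelic loci and
  Binomial(depth, 0.5) reference counts for biallelic ones;
* FISH tables with detection, miscall and biallelic-signal rates
  (closed-form cis expectation `(1-m)^2 + m^2` under miscall rate `m`);
* ReTiSH tables built by construction from each cell's late homolog;
* metaphase images as two equal-area elliptical bodies with uniform DAPI,
  planted BrdU density ratio, centromere blobs of unequal size, and
  additive Gaussian noise.

Every simulator is a pure function of (parameters, seed); one master seed
fans out to per-simulator child seeds by fixed offsets; truth labels are
always emitted next to observations.

What it deliberately does **not** emulate: sequence content (no FASTQ, no
mappability or alignment bias), repeat subfamily structure and divergence,
realistic chromosome morphology or banding, chromatid overlap in
metaphase spreads, optical PSFs, or the empirical clumpiness of L1 in a
real genome. The last point matters for interpretation: the variance of
the intron-resampling null depends on how L1 clusters in real introns, so
a passing synthetic test demonstrates the machinery is correct, not that a
particular real-genome p-value will take any particular value — on the
synthetic genome the focal enrichment p comes out far smaller than it
does against a real annotation, precisely because uniform placement gives
a tighter null.

## Problem sizes and numerical conventions

The bundled analyses and tests use a 5–6 Mb genome analog, 10,000
resampling replicates, FISH tables of 100–20,000 cells, 1,000-replicate
calibration of the coordination test, 10–12 cells per genotype group for
replication timing, and 128 x 256 px images — sizes chosen so the whole
suite runs comfortably on a laptop while keeping every Monte-Carlo
comparison inside 3-standard-error bands. Other conventions: intervals are
GRanges-native (1-based closed) internally, with conversion to and from
0-based half-open formats (BED, bedGraph) only at the format boundary via
rtracklayer; chromosome names match exactly (no silent "chr" stripping);
beta-tail p-values are clamped below by the smallest positive double so
reported p-values are always in (0, 1]; and screens share one resampling
null per domain length, with no multiple-testing correction by default
(a single-locus test is the motivating use; Benjamini–Hochberg is a flag).

## Known limitations

* The image path is a faithful stand-in for workstation-assisted
  quantification, not a general metaphase-image analysis tool; touching
  or bent chromosomes are out of scope.
* Allele-specific mapping bias, statistical phasing, and read-level
  simulation are out of scope; the pipeline consumes coverage and counts.
* The PRME criteria involving subclone randomness are reported from the
  cytogenetic tables when supplied but are not required flags of the
  sequencing-only screen, which keeps the screen runnable from coverage
  and counts alone.
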