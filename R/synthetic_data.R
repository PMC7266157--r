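## Synthetic-data generators. Every generator is a pure function of its
## parameters and a seed, emits truth labels alongside observations, and
## attaches a provenance attribute (seed + parameters) sufficient to
## regenerate the output. Defaults encode the study conditions: a ~185 kb
## nuclear-retained transcribed domain inside a six-domain cluster, ~13%
## background L1 density vs ~29% inside the focal locus (~27% on the X
## analog), monoallelic allele counts phased to two homologs, FISH tables
## with high cis coordination, ReTiSH 5 h / 14 h patterns, and metaphase
## images with planted BrdU homolog ratios.

#' Derive a child seed from a master seed
#'
#' One master seed fans out to per-simulator child seeds by fixed offsets so
#' that simulators are reproducible yet mutually independent.
#'
#' @param seed Master seed (integer).
#' @param k Offset index (integer).
#' @return An integer seed in `[0, 2^31)`.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483647)
}

with_provenance <- function(x, seed, params) {
  attr(x, "provenance") <- list(seed = as.integer(seed), params = params)
  x
}

## Sequentially place non-overlapping fragments in [1, region_len] until the
## covered fraction reaches `target`. Proposals are drawn in batches and an
## earlier proposal always wins an overlap, which reproduces sequential
## uniform sampling with rejection. `exclude` (IRanges) is never intruded on.
place_fragments <- function(region_len, target, meanlog, sdlog,
                            exclude = NULL) {
  if (target <= 0) return(IRanges())
  kept <- IRanges()
  covered <- 0
  mean_len <- exp(meanlog + sdlog^2 / 2)
  guard <- 0
  while (covered < target * region_len) {
    guard <- guard + 1
    if (guard > 200) stop("repeat placement failed to reach target density")
    need <- target * region_len - covered
    n <- max(20L, ceiling(need / mean_len * 1.6))
    len <- pmax(50, round(rlnorm(n, meanlog, sdlog)))
    st <- floor(runif(n, 1, pmax(2, region_len - len + 1)))
    cand <- IRanges(st, width = pmin(len, region_len - st + 1))
    if (!is.null(exclude) && length(exclude) > 0) {
      cand <- cand[!IRanges::overlapsAny(cand, exclude)]
    }
    if (length(kept) > 0) {
      cand <- cand[!IRanges::overlapsAny(cand, kept)]
    }
    if (length(cand) == 0) next
    hits <- findOverlaps(cand, drop.self = TRUE, drop.redundant = FALSE)
    drop <- unique(queryHits(hits)[queryHits(hits) > subjectHits(hits)])
    if (length(drop) > 0) cand <- cand[-drop]
    cum <- cumsum(width(cand))
    take <- which(covered + cum >= target * region_len)
    stop_at <- if (length(take) > 0) take[1] else length(cand)
    cand <- cand[seq_len(stop_at)]
    if (length(take) > 0) {
      ## trim the final fragment so realized coverage lands on the target
      excess <- covered + cum[stop_at] - ceiling(target * region_len)
      if (excess > 0) {
        IRanges::end(cand)[stop_at] <- end(cand)[stop_at] - excess
      }
    }
    kept <- c(kept, cand)
    covered <- covered + sum(width(cand))
  }
  sort(kept)
}

#' Simulate a genome annotation (genes, exons, repeats)
#'
#' Places non-overlapping protein-coding gene bodies with exon/intron
#' structure, then fills each chromosome with repeat fragments (log-normal
#' lengths, median ~1 kb) to per-chromosome target coverage fractions, with
#' independent uniform strand. Optional planted windows receive their own
#' (typically higher) L1 target and are kept gene-free, emulating an
#' L1-rich intergenic vlincRNA locus against the ~13% autosomal background.
#' Realized genome-wide family fractions land within about +/-0.02 of target
#' for genomes of 5 Mb and up.
#'
#' @param genome Named integer vector of chromosome lengths.
#' @param l1_density L1 target coverage fraction; scalar or named per
#'   chromosome. Default 0.13 (autosomal background).
#' @param other_densities Named vector of additional repeat-family target
#'   fractions (names are family labels). Default `c("SINE/Alu" = 0.10)`.
#' @param genes_per_mb Gene density. Default 8, which with the default
#'   exon/intron geometry leaves roughly 15-20% of the genome intronic, so
#'   the intron set comfortably exceeds the length of a vlinc-scale focal
#'   domain.
#' @param planted_windows Optional `GRanges` with an `l1_target` metadata
#'   column: windows kept free of genes and filled to their own L1 fraction.
#' @param seed Integer seed.
#' @return A feature-set `GRanges` (genes, exons, repeats) with seqlengths.
#' @export
simulate_annotation <- function(genome, l1_density = 0.13,
                                other_densities = c("SINE/Alu" = 0.10),
                                genes_per_mb = 8,
                                planted_windows = NULL,
                                seed = 1) {
  stopifnot(length(genome) >= 1, all(genome > 0), !is.null(names(genome)))
  dens <- function(chrom) {
    d <- if (!is.null(names(l1_density)) && chrom %in% names(l1_density)) {
      l1_density[[chrom]]
    } else if (is.null(names(l1_density))) l1_density[[1]] else 0.13
    d
  }
  for (chrom in names(genome)) {
    total <- dens(chrom) + sum(other_densities)
    if (dens(chrom) < 0 || dens(chrom) > 1 || total > 1) {
      stop("infeasible repeat density on ", chrom, " (sum ", total, ")")
    }
  }
  set.seed(seed)
  feats <- list()
  for (chrom in names(genome)) {
    len <- genome[[chrom]]
    win <- if (is.null(planted_windows)) GRanges() else
      planted_windows[seqnames(planted_windows) == chrom]
    win_ir <- ranges(win)
    ## gene bodies: exon/intron structure, placed with rejection, kept out
    ## of planted windows
    n_genes <- round(genes_per_mb * len / 1e6)
    gene_occupied <- win_ir
    for (g in seq_len(n_genes)) {
      n_ex <- sample(3:8, 1)
      ex_w <- round(runif(n_ex, 150, 300))
      in_w <- pmax(200, round(rlnorm(n_ex - 1, log(3000), 1.0)))
      body_w <- sum(ex_w) + sum(in_w)
      placed <- FALSE
      for (try in 1:50) {
        st <- floor(runif(1, 1, max(2, len - body_w)))
        cand <- IRanges(st, width = body_w)
        if (!IRanges::overlapsAny(cand, gene_occupied)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) next
      gene_occupied <- c(gene_occupied, cand)
      gid <- sprintf("%s_gene%03d", chrom, g)
      strand_g <- sample(c("+", "-"), 1)
      ex_starts <- st + cumsum(c(0, head(ex_w, -1) + in_w))
      exons <- GRanges(chrom, IRanges(ex_starts, width = ex_w),
                       strand = strand_g)
      gene <- GRanges(chrom, IRanges(st, width = body_w), strand = strand_g)
      feats[[length(feats) + 1]] <- feature_set(
        c(gene, exons), kind = c("gene", rep("exon", n_ex)),
        family = "protein_coding", name = gid)
    }
    ## repeats: planted windows first (their own L1 target), then background
    fam_targets <- c(setNames(dens(chrom), "LINE/L1"), other_densities)
    for (fam in names(fam_targets)) {
      tgt <- fam_targets[[fam]]
      placed_ir <- IRanges()
      if (fam == "LINE/L1" && length(win_ir) > 0) {
        for (wi in seq_along(win_ir)) {
          w <- win_ir[wi]
          wt <- mcols(win)$l1_target[wi]
          frag <- place_fragments(width(w), wt, log(1000), 0.6)
          placed_ir <- c(placed_ir, IRanges::shift(frag, start(w) - 1))
        }
      }
      ## the background target counts only the bases outside planted
      ## windows, which are filled to their own targets
      tgt_bg <- tgt * (len - sum(width(win_ir))) / len
      bg <- place_fragments(len, tgt_bg, log(1000), 0.6, exclude = win_ir)
      placed_ir <- sort(c(placed_ir, bg))
      if (length(placed_ir) > 0) {
        rep_gr <- GRanges(chrom, placed_ir,
                          strand = sample(c("+", "-"), length(placed_ir),
                                          replace = TRUE))
        feats[[length(feats) + 1]] <- feature_set(
          rep_gr, kind = "repeat", family = fam,
          name = paste0(gsub("/", "_", fam), "_", seq_along(rep_gr)))
      }
    }
  }
  ## per-chromosome pieces carry disjoint seqlevels; combining them warns
  ## about the (expected) lack of common levels
  out <- if (length(feats) > 0) suppressWarnings(do.call(c, feats)) else
    GRanges()
  out <- feature_set(out, kind = mcols(out)$kind, family = mcols(out)$family,
                     name = mcols(out)$name, genome = genome)
  with_provenance(out, seed,
                  list(genome = genome, l1_density = l1_density,
                       other_densities = other_densities,
                       genes_per_mb = genes_per_mb))
}

#' Simulate a coverage track with planted transcribed domains
#'
#' Inside each domain, per-base depth is the target depth (noise "none") or
#' Poisson around it; outside, a configurable background rate (default 0).
#'
#' @param domains `GRanges` with a `depth` metadata column; strands must be
#'   all `*` (unstranded track) or all in `+`/`-` (stranded track).
#' @param genome Named chromosome lengths.
#' @param noise `"none"` or `"poisson"`.
#' @param background Background depth rate (Poisson mean when noise is
#'   `"poisson"`, constant otherwise). Default 0.
#' @param seed Integer seed.
#' @return A `coverage_track`.
#' @export
simulate_coverage <- function(domains, genome, noise = c("none", "poisson"),
                              background = 0, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(!is.null(names(genome)))
  if (length(domains) > 0) {
    stopifnot(!is.null(mcols(domains)$depth), all(mcols(domains)$depth >= 0))
  }
  strands <- unique(as.character(strand(domains)))
  if (length(strands) == 0) strands <- "*"
  if ("*" %in% strands && length(strands) > 1) {
    stop("domains must be all unstranded or all stranded")
  }
  set.seed(seed)
  build_strand <- function(s) {
    doms <- domains[as.character(strand(domains)) == s]
    if (length(doms) > 1) {
      hits <- findOverlaps(doms, drop.self = TRUE)
      if (length(hits) > 0) stop("overlapping domains on strand ", s)
    }
    lst <- lapply(names(genome), function(chrom) {
      len <- genome[[chrom]]
      base <- if (background > 0 && noise == "poisson") {
        Rle(rpois(len, background))
      } else {
        Rle(background, len)
      }
      d <- doms[seqnames(doms) == chrom]
      if (length(d) > 0) {
        for (i in seq_along(d)) {
          w <- width(d)[i]
          vals <- if (noise == "poisson") rpois(w, mcols(d)$depth[i])
                  else rep(mcols(d)$depth[i], w)
          base[start(d)[i]:end(d)[i]] <- vals
        }
      }
      base
    })
    names(lst) <- names(genome)
    methods::as(lst, "SimpleRleList")
  }
  cov <- lapply(strands, build_strand)
  names(cov) <- strands
  track <- do.call(coverage_track, cov)
  with_provenance(track, seed,
                  list(noise = noise, background = background,
                       n_domains = length(domains)))
}

#' Simulate RNA allele counts at heterozygous SNPs
#'
#' Emulates allele-count readout at SNPs heterozygous in genomic DNA, phased
#' onto two homologs (A/B) as established by mono-chromosomal hybrid
#' genotypes. `monoallelic` draws the minor-allele count from
#' `Binomial(depth, error_rate)` off the single expressed haplotype;
#' `biallelic` draws the reference count from `Binomial(depth, 0.5)`;
#' `imprinted` is monoallelic with the expressed homolog fixed (the
#' distinction from random monoallelic expression is only visible in
#' population-of-cells assays, not bulk counts).
#'
#' @param mode `"monoallelic"`, `"biallelic"` or `"imprinted"`.
#' @param n_snps Number of heterozygous SNPs (> 0).
#' @param depth Read depth per SNP (>= 1).
#' @param error_rate Per-read error rate in `[0, 0.5)`.
#' @param expressed_homolog `"A"` or `"B"`; homolog carrying the expressed
#'   allele in monoallelic/imprinted modes. Default `"B"`.
#' @param chrom,region Chromosome name and `c(start, end)` for SNP positions.
#' @param seed Integer seed.
#' @return A data.frame of allele-count records with truth columns
#'   (`hap_A_allele`, `hap_B_allele`, `true_mode`, `true_expressed_homolog`).
#' @export
simulate_allele_counts <- function(mode = c("monoallelic", "biallelic",
                                            "imprinted"),
                                   n_snps, depth, error_rate = 0,
                                   expressed_homolog = "B",
                                   chrom = "chr6S",
                                   region = c(1L, 200000L), seed = 1) {
  mode <- match.arg(mode)
  if (n_snps <= 0) stop("n_snps must be positive")
  stopifnot(depth >= 1, error_rate >= 0, error_rate < 0.5,
            expressed_homolog %in% c("A", "B"))
  if (mode == "imprinted") expressed_homolog <- "A"
  set.seed(seed)
  pos <- sort(sample(region[1]:region[2], n_snps))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  ## phase: which homolog carries the ref allele
  ref_on_A <- runif(n_snps) < 0.5
  hap_A <- ifelse(ref_on_A, ref, alt)
  hap_B <- ifelse(ref_on_A, alt, ref)
  if (mode == "biallelic") {
    rna_ref <- rbinom(n_snps, depth, 0.5)
    rna_alt <- depth - rna_ref
  } else {
    expressed <- if (expressed_homolog == "A") hap_A else hap_B
    minor <- rbinom(n_snps, depth, error_rate)
    rna_ref <- ifelse(expressed == ref, depth - minor, minor)
    rna_alt <- depth - rna_ref
  }
  out <- data.frame(
    snp_id = sprintf("snp%03d", seq_len(n_snps)),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    dna_genotype = "het",
    rna_ref_count = rna_ref, rna_alt_count = rna_alt,
    hap_A_allele = hap_A, hap_B_allele = hap_B,
    true_mode = mode,
    true_expressed_homolog = if (mode == "biallelic") NA_character_
                             else expressed_homolog,
    stringsAsFactors = FALSE)
  with_provenance(out, seed, list(mode = mode, n_snps = n_snps,
                                  depth = depth, error_rate = error_rate))
}

#' Extract a mono-chromosomal hybrid genotype table
#'
#' The phasing truth of a simulated allele-count table in the format the
#' allelic-state module consumes (one genotype per homolog per SNP, as read
#' off two mono-chromosomal hybrid cell lines).
#'
#' @param counts Output of [simulate_allele_counts()].
#' @return data.frame with columns `snp_id`, `allele_A`, `allele_B`.
#' @export
hybrid_table <- function(counts) {
  data.frame(snp_id = counts$snp_id,
             allele_A = counts$hap_A_allele,
             allele_B = counts$hap_B_allele,
             stringsAsFactors = FALSE)
}

#' Simulate a two-probe RNA-FISH cell table
#'
#' Each cell expresses each probed locus from one homolog. Modes:
#' `coordinated_cis` puts both probes on the same (randomly chosen) homolog
#' before noise; `coordinated_trans` on opposite homologs; `independent`
#' draws homologs independently (cis expectation 0.5); `imprinted` fixes the
#' first probe's homolog and draws the second independently (cis expectation
#' 0.5 in a non-clonal population — the signature that distinguishes
#' imprinting from coordinated random monoallelic expression).
#' `detection_rate` governs zero-signal cells, `miscall_rate` flips a
#' detected probe's homolog, and `biallelic_rate` produces two-signal cells
#' (reported separately by the scorer).
#'
#' @param mode Coordination mode (see above).
#' @param n_cells Number of cells (> 0).
#' @param detection_rate,miscall_rate,biallelic_rate Probabilities in [0,1].
#' @param probes Length-2 character vector of probe names.
#' @param seed Integer seed.
#' @return Long data.frame: `cell_id`, `probe`, `n_signals`, `homolog`
#'   (observed; NA unless exactly one signal), `true_homolog`.
#' @export
simulate_fish_table <- function(mode = c("coordinated_cis",
                                         "coordinated_trans",
                                         "independent", "imprinted"),
                                n_cells, detection_rate = 1,
                                miscall_rate = 0, biallelic_rate = 0,
                                probes = c("vlinc273", "KCNQ5"), seed = 1) {
  mode <- match.arg(mode)
  if (n_cells <= 0) stop("n_cells must be positive")
  stopifnot(all(c(detection_rate, miscall_rate, biallelic_rate) >= 0),
            all(c(detection_rate, miscall_rate, biallelic_rate) <= 1),
            length(probes) == 2)
  set.seed(seed)
  h1 <- sample(c("A", "B"), n_cells, replace = TRUE)
  h2 <- switch(mode,
    coordinated_cis = h1,
    coordinated_trans = ifelse(h1 == "A", "B", "A"),
    independent = sample(c("A", "B"), n_cells, replace = TRUE),
    imprinted = {
      h1 <- rep("A", n_cells)
      sample(c("A", "B"), n_cells, replace = TRUE)
    })
  truth <- cbind(h1, h2)
  rows <- lapply(1:2, function(p) {
    true_h <- truth[, p]
    biall <- runif(n_cells) < biallelic_rate
    detected <- runif(n_cells) < detection_rate
    flipped <- runif(n_cells) < miscall_rate
    n_sig <- ifelse(biall, 2L, ifelse(detected, 1L, 0L))
    obs <- ifelse(n_sig == 1L,
                  ifelse(flipped, ifelse(true_h == "A", "B", "A"), true_h),
                  NA_character_)
    data.frame(cell_id = sprintf("cell%04d", seq_len(n_cells)),
               probe = probes[p], n_signals = n_sig, homolog = obs,
               true_homolog = true_h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cell_id, out$probe), ]
  rownames(out) <- NULL
  with_provenance(out, seed, list(mode = mode, n_cells = n_cells,
                                  detection_rate = detection_rate,
                                  miscall_rate = miscall_rate,
                                  biallelic_rate = biallelic_rate))
}

#' Simulate a ReTiSH per-cell hybridization table
#'
#' In ReTiSH, a 14 h BrdU pulse labels the whole S phase (probes hybridize to
#' both homologs) while a 5 h pulse labels only late S, so a locus whose
#' alleles replicate asynchronously shows a 5 h signal on the late-replicating
#' homolog only. Centromeric heterochromatin is late-replicating, so the
#' centromere probe hybridizes to both homologs at both time points (the QC
#' rule). Modes: `async_cis` puts both loci's 5 h signals on the same
#' homolog, `async_trans` on opposite homologs, `synchronous` on neither
#' (or on both, with `sync_late = TRUE`).
#'
#' @param mode `"async_cis"`, `"async_trans"` or `"synchronous"`.
#' @param n_cells Number of cells (> 0).
#' @param probes Length-2 character vector of locus probe names.
#' @param sync_late In synchronous mode, label both homologs at 5 h
#'   (synchronous-late) instead of neither (synchronous-early).
#' @param seed Integer seed.
#' @return Long data.frame: `cell_id`, `timepoint` (`"5h"`/`"14h"`),
#'   `probe` (the two loci plus `"cen"`), `homologs` (comma-joined subset of
#'   `A,B`), `true_late_homolog`.
#' @export
simulate_retish_table <- function(mode = c("async_cis", "async_trans",
                                           "synchronous"),
                                  n_cells,
                                  probes = c("ASAR6", "vlinc273"),
                                  sync_late = FALSE, seed = 1) {
  mode <- match.arg(mode)
  if (n_cells <= 0) stop("n_cells must be positive")
  stopifnot(length(probes) == 2)
  set.seed(seed)
  late1 <- sample(c("A", "B"), n_cells, replace = TRUE)
  late2 <- switch(mode,
    async_cis = late1,
    async_trans = ifelse(late1 == "A", "B", "A"),
    synchronous = rep(NA_character_, n_cells))
  if (mode == "synchronous") late1 <- rep(NA_character_, n_cells)
  both <- "A,B"
  sync5 <- if (sync_late) both else ""
  one_cell <- function(i) {
    l <- c(late1[i], late2[i])
    sig5 <- if (mode == "synchronous") c(sync5, sync5) else l
    data.frame(
      cell_id = sprintf("cell%04d", i),
      timepoint = rep(c("5h", "14h"), each = 3),
      probe = rep(c(probes, "cen"), 2),
      homologs = c(sig5[1], sig5[2], both, both, both, both),
      true_late_homolog = c(l[1], l[2], NA, l[1], l[2], NA),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(n_cells), one_cell))
  rownames(out) <- NULL
  with_provenance(out, seed, list(mode = mode, n_cells = n_cells,
                                  sync_late = sync_late))
}

## Pixel mask of an axis-aligned ellipse on an nrow x ncol grid.
ellipse_mask <- function(nrow, ncol, cy, cx, ry, rx) {
  y <- matrix(seq_len(nrow), nrow, ncol)
  x <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  ((y - cy) / ry)^2 + ((x - cx) / rx)^2 <= 1
}

#' Simulate a metaphase BrdU / DAPI / centromere image triplet
#'
#' Two elongated chromosome bodies (equal-area axis-aligned ellipses) with
#' uniform DAPI; the BrdU density of homolog 6B is `ratio_6B_over_6A` times
#' that of 6A; the centromere channel carries one blob per body with the 6A
#' blob strictly larger (the centromere-size polymorphism that identifies
#' the homologs). Gaussian noise of sd `noise_sd` (absolute intensity units)
#' is added to all channels and clipped at zero. Which body is 6A is
#' randomized per image. Truth masks are returned alongside.
#'
#' @param ratio_6B_over_6A Planted total-BrdU ratio (> 0).
#' @param nrow,ncol Grid size (>= 64 each).
#' @param noise_sd Gaussian noise sd in intensity units (DAPI plateau 200,
#'   6A BrdU plateau 100, centromere plateau 150).
#' @param cen_radius_6A,cen_radius_6B Centromere blob radii in pixels;
#'   6A must be larger.
#' @param seed Integer seed.
#' @return List: `dapi`, `brdu`, `cen` (matrices), `mask_6A`, `mask_6B`
#'   (logical truth masks), `ratio` (planted value).
#' @export
simulate_brdu_image <- function(ratio_6B_over_6A, nrow = 128, ncol = 256,
                                noise_sd = 0, cen_radius_6A = 8,
                                cen_radius_6B = 5, seed = 1) {
  stopifnot(ratio_6B_over_6A > 0, nrow >= 64, ncol >= 64,
            cen_radius_6A > cen_radius_6B)
  set.seed(seed)
  ry <- round(nrow * 0.10)
  rx <- round(ncol * 0.38)
  cx <- round(ncol / 2)
  cy1 <- round(nrow * 0.28)
  cy2 <- round(nrow * 0.72)
  if (cy1 + ry >= cy2 - ry) stop("chromosome bodies would overlap")
  m1 <- ellipse_mask(nrow, ncol, cy1, cx, ry, rx)
  m2 <- ellipse_mask(nrow, ncol, cy2, cx, ry, rx)
  a_on_top <- runif(1) < 0.5
  mask_6A <- if (a_on_top) m1 else m2
  mask_6B <- if (a_on_top) m2 else m1
  dapi <- matrix(0, nrow, ncol); dapi[m1 | m2] <- 200
  brdu <- matrix(0, nrow, ncol)
  brdu[mask_6A] <- 100
  brdu[mask_6B] <- 100 * ratio_6B_over_6A
  cen <- matrix(0, nrow, ncol)
  blob <- function(mask, cy, r) {
    cxb <- cx - round(rx * 0.55)  # centromere off-center along the body
    ellipse_mask(nrow, ncol, cy, cxb, r, r) & mask
  }
  cen[blob(mask_6A, if (a_on_top) cy1 else cy2, cen_radius_6A)] <- 150
  cen[blob(mask_6B, if (a_on_top) cy2 else cy1, cen_radius_6B)] <- 150
  if (noise_sd > 0) {
    dapi <- pmax(dapi + matrix(rnorm(nrow * ncol, 0, noise_sd), nrow), 0)
    brdu <- pmax(brdu + matrix(rnorm(nrow * ncol, 0, noise_sd), nrow), 0)
    cen <- pmax(cen + matrix(rnorm(nrow * ncol, 0, noise_sd), nrow), 0)
  }
  out <- list(dapi = dapi, brdu = brdu, cen = cen,
              mask_6A = mask_6A, mask_6B = mask_6B,
              ratio = ratio_6B_over_6A)
  with_provenance(out, seed, list(ratio = ratio_6B_over_6A, nrow = nrow,
                                  ncol = ncol, noise_sd = noise_sd))
}
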