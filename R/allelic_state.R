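## Allelic expression state from RNA allele counts at heterozygous SNPs,
## homolog assignment via mono-chromosomal hybrid genotypes, and nuclear
## enrichment. The Sanger-trace readout of the source assay is categorical;
## its quantitative proxy here is a major-allele-fraction threshold at a
## minimum depth, both exposed as parameters.

#' Per-SNP allelic expression call
#'
#' A SNP heterozygous in genomic DNA is called `monoallelic` when its RNA
#' major-allele fraction is at least `mono_threshold` (boundary inclusive),
#' `biallelic` when below, and `indeterminate` when depth is insufficient.
#' Non-heterozygous records are rejected.
#'
#' @param counts data.frame with columns `snp_id`, `ref`, `alt`,
#'   `dna_genotype`, `rna_ref_count`, `rna_alt_count` (the format written by
#'   [simulate_allele_counts()], or read from TSV).
#' @param min_depth Minimum RNA depth for an informative call (default 20).
#' @param mono_threshold Major-allele fraction at or above which a SNP is
#'   monoallelic (default 0.95).
#' @return data.frame: `snp_id`, `state`, `major_fraction`, `major_allele`,
#'   `depth`.
#' @export
call_snp_allelic <- function(counts, min_depth = 20, mono_threshold = 0.95) {
  stopifnot(all(c("snp_id", "ref", "alt", "dna_genotype",
                  "rna_ref_count", "rna_alt_count") %in% names(counts)))
  if (any(counts$dna_genotype != "het")) {
    stop("non-heterozygous record(s): ",
         paste(counts$snp_id[counts$dna_genotype != "het"], collapse = ", "),
         " (allelic calls require DNA heterozygosity)")
  }
  stopifnot(all(counts$rna_ref_count >= 0), all(counts$rna_alt_count >= 0))
  depth <- counts$rna_ref_count + counts$rna_alt_count
  major_is_ref <- counts$rna_ref_count >= counts$rna_alt_count
  major_n <- pmax(counts$rna_ref_count, counts$rna_alt_count)
  frac <- ifelse(depth > 0, major_n / depth, NA_real_)
  state <- ifelse(depth < min_depth, "indeterminate",
                  ifelse(frac >= mono_threshold, "monoallelic", "biallelic"))
  data.frame(snp_id = counts$snp_id,
             state = state,
             major_fraction = frac,
             major_allele = ifelse(state == "indeterminate", NA_character_,
                                   ifelse(major_is_ref, counts$ref,
                                          counts$alt)),
             depth = depth,
             stringsAsFactors = FALSE)
}

#' Assign the expressed homolog from hybrid genotypes
#'
#' The homolog labels A/B are arbitrary per sample and fixed by the hybrid
#' genotype table (one genotype per homolog per SNP, as read off two
#' mono-chromosomal hybrid cell lines). A SNP's expressed major allele that
#' matches exactly one homolog's allele assigns that homolog; matching both
#' or neither (or a SNP absent from the table) yields `"unknown"`.
#'
#' @param snp_calls Output of [call_snp_allelic()].
#' @param hybrids data.frame with `snp_id`, `allele_A`, `allele_B`.
#' @return `snp_calls` with an `expressed_homolog` column.
#' @export
assign_expressed_homolog <- function(snp_calls, hybrids) {
  stopifnot(all(c("snp_id", "allele_A", "allele_B") %in% names(hybrids)))
  i <- match(snp_calls$snp_id, hybrids$snp_id)
  missing_snp <- is.na(i)
  if (any(missing_snp)) {
    warning("SNP(s) absent from hybrid table: ",
            paste(snp_calls$snp_id[missing_snp], collapse = ", "))
  }
  a <- hybrids$allele_A[i]
  b <- hybrids$allele_B[i]
  maj <- snp_calls$major_allele
  hom <- ifelse(is.na(maj) | missing_snp, "unknown",
         ifelse(maj == a & maj != b, "A",
         ifelse(maj == b & maj != a, "B", "unknown")))
  snp_calls$expressed_homolog <- hom
  snp_calls
}

#' Locus-level allelic call
#'
#' A locus is `monoallelic` only if every informative SNP is monoallelic and
#' all homolog assignments agree; any biallelic SNP makes the locus
#' `biallelic`; homolog disagreement among monoallelic SNPs, or zero
#' informative SNPs, makes it `indeterminate`.
#'
#' @param snp_calls Output of [assign_expressed_homolog()] (the
#'   `expressed_homolog` column may be absent, in which case the locus
#'   homolog is `"unknown"`).
#' @param min_snps Minimum informative SNPs (default 1).
#' @return List of class `allelic_call`: `state`, `expressed_homolog`,
#'   `n_informative_snps`, `major_allele_fraction` (depth-weighted mean over
#'   informative SNPs).
#' @export
locus_allelic_call <- function(snp_calls, min_snps = 1) {
  inf <- snp_calls[snp_calls$state != "indeterminate", , drop = FALSE]
  n <- nrow(inf)
  maf <- if (n > 0) {
    sum(inf$major_fraction * inf$depth) / sum(inf$depth)
  } else NA_real_
  state <- "indeterminate"
  hom <- "unknown"
  if (n >= min_snps && n > 0) {
    if (any(inf$state == "biallelic")) {
      state <- "biallelic"
    } else {
      homs <- inf$expressed_homolog
      if (is.null(homs)) homs <- rep("unknown", n)
      known <- homs[homs != "unknown"]
      if (length(known) > 0 && length(unique(known)) > 1) {
        state <- "indeterminate"   # monoallelic SNPs phased to opposite homologs
      } else {
        state <- "monoallelic"
        if (length(known) == n && n > 0) hom <- known[1]
      }
    }
  }
  structure(list(state = state, expressed_homolog = hom,
                 n_informative_snps = n, major_allele_fraction = maf),
            class = "allelic_call")
}

#' @export
print.allelic_call <- function(x, ...) {
  cat(sprintf(
    "allelic_call: %s (homolog %s, %d informative SNP(s), MAF %.3f)\n",
    x$state, x$expressed_homolog, x$n_informative_snps,
    x$major_allele_fraction))
  invisible(x)
}

#' Nuclear enrichment ratio
#'
#' Fold enrichment of a transcript in the nuclear over the cytoplasmic
#' fraction, on a common normalized scale, regularized by a pseudocount
#' (default: the smallest positive value observed on the scale, or 1 when
#' none is supplied). Both levels zero is reported as not expressed (NA).
#'
#' @param nuclear,cytoplasmic Non-negative expression levels.
#' @param pseudocount Regularizer added to both levels; 0 is allowed when
#'   `cytoplasmic > 0`.
#' @return Fold ratio (NA with attribute `not_expressed` when both are 0).
#' @export
nuclear_enrichment <- function(nuclear, cytoplasmic, pseudocount = NULL) {
  stopifnot(nuclear >= 0, cytoplasmic >= 0)
  if (nuclear == 0 && cytoplasmic == 0) {
    return(structure(NA_real_, not_expressed = TRUE))
  }
  if (is.null(pseudocount)) {
    pos <- c(nuclear, cytoplasmic)
    pos <- pos[pos > 0]
    pseudocount <- if (cytoplasmic > 0) 0 else min(pos)
  }
  (nuclear + pseudocount) / (cytoplasmic + pseudocount)
}

#' Read an allele-count TSV
#'
#' Columns: snp_id, chrom, pos, ref, alt, dna_genotype, rna_ref_count,
#' rna_alt_count (extra columns pass through).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_allele_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "ref", "alt", "dna_genotype",
            "rna_ref_count", "rna_alt_count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("allele-count table missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}
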