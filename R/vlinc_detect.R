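## Contiguous-transcription (vlinc) domain calling. vlincRNAs are >50 kb of
## contiguously expressed sequence not associated with protein-coding genes;
## the caller finds maximal runs of above-threshold coverage, bridges short
## sub-threshold gaps, and applies the length filter.

#' Default coverage threshold for domain calling
#'
#' A relative default: 0.25 of the median nonzero depth across the track,
#' with an absolute floor of 2 reads. The source data set states no
#' threshold, so the default adapts to library depth rather than fixing an
#' absolute value.
#'
#' @param track A `coverage_track`.
#' @return A positive depth threshold.
#' @export
default_min_cov <- function(track) {
  vals <- unlist(lapply(track$cov, function(rl) {
    unlist(lapply(rl, function(r) {
      v <- runValue(r)
      rep(v[v > 0], S4Vectors::runLength(r)[v > 0])
    }), use.names = FALSE)
  }), use.names = FALSE)
  if (length(vals) == 0) return(2)
  max(2, 0.25 * median(vals))
}

#' Call contiguous transcribed domains from coverage
#'
#' Finds maximal runs of positions with depth >= `min_cov`, bridges
#' sub-threshold gaps of at most `max_gap` bases, and reports runs of at
#' least `min_len` bases. Stranded tracks are called independently per
#' strand. With `max_gap = 0` the output equals the plain thresholded
#' run-length encoding. Bridged bases count toward domain length (length is
#' genomic span) but not toward the `mean_depth` numerator, which averages
#' observed signal over above-threshold positions only.
#'
#' @param track A `coverage_track`.
#' @param min_cov Depth threshold (> 0); default [default_min_cov()].
#' @param max_gap Maximum sub-threshold gap to bridge (bases, >= 0).
#' @param min_len Minimum domain length (bases); default 50000, the vlinc
#'   length criterion.
#' @return `GRanges` of domains, sorted and disjoint per strand, with
#'   metadata columns `mean_depth` and `n_gaps_bridged`.
#' @export
call_transcribed_domains <- function(track, min_cov = NULL, max_gap = 0,
                                     min_len = 50000) {
  stopifnot(is(track, "coverage_track"), max_gap >= 0, min_len > 0)
  if (is.null(min_cov)) min_cov <- default_min_cov(track)
  stopifnot(min_cov > 0)
  out <- GRanges()
  for (s in track_strands(track)) {
    rl <- track_rle(track, s)
    for (chrom in names(rl)) {
      r <- rl[[chrom]]
      runs <- slice(r, lower = min_cov, rangesOnly = TRUE)
      if (length(runs) == 0) next
      dom <- reduce(runs, min.gapwidth = max_gap + 1)
      dom <- dom[width(dom) >= min_len]
      if (length(dom) == 0) next
      n_gaps <- IRanges::countOverlaps(dom, runs) - 1L
      md <- vapply(seq_along(dom), function(i) {
        v <- as.numeric(r[start(dom)[i]:end(dom)[i]])
        keep <- v >= min_cov
        sum(v[keep]) / sum(keep)
      }, 0)
      gr <- GRanges(chrom, dom, strand = s,
                    mean_depth = md, n_gaps_bridged = n_gaps)
      out <- c(out, gr)
    }
  }
  sort(out, ignore.strand = TRUE)
}

#' Remove domains associated with protein-coding genes
#'
#' Drops any domain whose overlap with a protein-coding gene body (either
#' strand) exceeds `max_overlap` bases (default 0: any overlap disqualifies).
#' Gene-body rather than exon-only overlap is used because vlincRNAs are
#' defined intergenically.
#'
#' @param domains Domain `GRanges` (from [call_transcribed_domains()]).
#' @param genes Feature-set `GRanges`; rows with `kind == "gene"` and
#'   `family == "protein_coding"` are the disqualifying set.
#' @param max_overlap Maximum tolerated overlap in bases.
#' @return The retained domains, unchanged.
#' @export
filter_protein_coding <- function(domains, genes, max_overlap = 0) {
  if (length(domains) == 0) return(domains)
  pc <- genes[!is.na(mcols(genes)$kind) & mcols(genes)$kind == "gene" &
              !is.na(mcols(genes)$family) &
              mcols(genes)$family == "protein_coding"]
  if (length(pc) == 0) return(domains)
  ov <- vapply(seq_along(domains),
               function(i) overlap_length(domains[i], pc), 0L)
  domains[ov <= max_overlap]
}

#' Write called domains as BED6 and TSV
#'
#' BED score column carries `mean_depth` scaled by 10 (capped at 1000, the
#' BED score ceiling); the TSV carries the full fields.
#'
#' @param domains Domain `GRanges`.
#' @param bed_path,tsv_path Output files (either may be NULL to skip).
#' @return Invisibly, the TSV data.frame.
#' @export
write_domains <- function(domains, bed_path = NULL, tsv_path = NULL) {
  df <- data.frame(
    chrom = as.character(seqnames(domains)),
    start = start(domains), end = end(domains),
    strand = as.character(strand(domains)),
    length = width(domains),
    mean_depth = mcols(domains)$mean_depth,
    n_gaps_bridged = mcols(domains)$n_gaps_bridged)
  if (!is.null(bed_path)) {
    write_features_bed(domains, bed_path,
                       score = pmin(1000, round(df$mean_depth * 10)))
  }
  if (!is.null(tsv_path)) {
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}
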