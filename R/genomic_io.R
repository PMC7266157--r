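## Feature and coverage input/output plus the interval-algebra kernel used by
## every other module. Features live in a GRanges with metadata columns
## kind ("gene", "exon", "intron", "repeat", "domain"), family (repeat family
## such as "LINE/L1", or a gene biotype such as "protein_coding") and name.
## Coordinates are GRanges-native (1-based, closed); conversion to and from
## the 0-based half-open conventions of BED/bedGraph happens only inside
## rtracklayer at the format boundary.

#' Construct a feature set
#'
#' A feature set is a `GRanges` whose metadata columns `kind`, `family` and
#' `name` classify each range. `kind = "repeat"` features must carry a
#' non-empty `family` (e.g. `"LINE/L1"`).
#'
#' @param gr A `GRanges`.
#' @param kind Character vector (recycled): one of `gene`, `exon`, `intron`,
#'   `repeat`, `domain`.
#' @param family Character vector (recycled): repeat family or gene biotype.
#' @param name Character vector (recycled): feature label.
#' @param genome Optional named vector of chromosome lengths; stored as
#'   `seqlengths` and validated against the ranges.
#' @return A `GRanges` with `kind`, `family`, `name` metadata columns.
#' @export
feature_set <- function(gr, kind = "domain", family = NA_character_,
                        name = NA_character_, genome = NULL) {
  stopifnot(is(gr, "GRanges"))
  mcols(gr)$kind <- rep_len(as.character(kind), length(gr))
  mcols(gr)$family <- rep_len(as.character(family), length(gr))
  mcols(gr)$name <- rep_len(as.character(name), length(gr))
  bad <- mcols(gr)$kind == "repeat" &
    (is.na(mcols(gr)$family) | mcols(gr)$family == "")
  if (any(bad)) {
    stop("repeat features must carry a non-empty family")
  }
  if (!is.null(genome)) {
    known <- as.character(seqnames(gr)) %in% names(genome)
    w <- which(known & end(gr) > genome[as.character(seqnames(gr))])
    if (length(w) > 0) {
      stop("feature(s) extend beyond chromosome length: index ", w[1])
    }
    seqlevels(gr) <- union(seqlevels(gr), names(genome))
    seqlengths(gr)[names(genome)] <- genome
  }
  gr
}

#' Read genomic features from standard annotation formats
#'
#' Reads BED (0-based half-open, converted at the boundary), GFF3/GTF
#' (1-based closed, kept as GRanges-native) or RepeatMasker `.out` files into
#' a feature set. Gzipped input is accepted for all formats.
#'
#' For GFF3/GTF, `kind` is taken from the `type` column (rows typed `gene`,
#' `exon` or `intron` keep that kind; other types are dropped unless
#' `keep_types = TRUE`), `family` from a `gene_biotype`/`biotype`/
#' `gene_type` attribute when present, and `name` from `gene_id`/`ID`/`Name`.
#' For RepeatMasker `.out`, every row becomes `kind = "repeat"` with
#' `family` equal to the `repClass/repFamily` token, `name` the repeat name,
#' and strand `"C"` mapped to `"-"`.
#'
#' @param path Input file.
#' @param format One of `"bed"`, `"gff3"`, `"gtf"`, `"rmsk_out"`.
#' @param kind Kind assigned to BED rows (BED carries no type column);
#'   default `"domain"`. When `kind = "repeat"`, the BED name column is used
#'   as the repeat family.
#' @param keep_types Keep GFF/GTF rows of types other than
#'   gene/exon/intron (as their own `kind`).
#' @return A feature-set `GRanges`.
#' @export
read_features <- function(path, format = c("bed", "gff3", "gtf", "rmsk_out"),
                          kind = "domain", keep_types = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "rmsk_out") {
    return(read_rmsk_out(path))
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else NA_character_
    fam <- if (identical(kind, "repeat")) nm else NA_character_
    out <- granges(gr)
    return(feature_set(out, kind = kind, family = fam, name = nm))
  }
  gr <- rtracklayer::import(path, format = format)
  type <- as.character(mcols(gr)$type)
  fam <- rep(NA_character_, length(gr))
  for (col in c("gene_biotype", "biotype", "gene_type")) {
    if (!is.null(mcols(gr)[[col]])) {
      take <- is.na(fam) & !is.na(mcols(gr)[[col]])
      fam[take] <- as.character(mcols(gr)[[col]][take])
    }
  }
  nm <- rep(NA_character_, length(gr))
  for (col in c("gene_id", "ID", "Name")) {
    if (!is.null(mcols(gr)[[col]])) {
      take <- is.na(nm) & !is.na(mcols(gr)[[col]])
      nm[take] <- as.character(mcols(gr)[[col]][take])
    }
  }
  keep <- type %in% c("gene", "exon", "intron")
  if (keep_types) keep <- rep(TRUE, length(gr))
  out <- granges(gr)[keep]
  feature_set(out, kind = type[keep], family = fam[keep], name = nm[keep])
}

## RepeatMasker .out: two header lines then whitespace-delimited columns
## (score, div, del, ins, query, begin, end, left, strand, repName,
## repClass/repFamily, ...). begin/end are 1-based inclusive. Strand "C"
## (complement) means minus. No installed reader handles .out, so parse here.
read_rmsk_out <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines, which = "left")
  ## drop header block (starts with "SW" / "score") and blank lines
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(SW|score)", lines)]
  if (length(lines) == 0) {
    return(feature_set(GRanges(), kind = character(0),
                       family = character(0), name = character(0)))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 11)) {
    stop("malformed RepeatMasker .out line ", which(nf < 11)[1],
         ": fewer than 11 fields")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:11))
  st <- suppressWarnings(as.integer(m[, 6]))
  en <- suppressWarnings(as.integer(m[, 7]))
  if (anyNA(st) || anyNA(en)) {
    stop("malformed RepeatMasker .out line ",
         which(is.na(st) | is.na(en))[1], ": non-numeric coordinates")
  }
  strand <- ifelse(m[, 9] == "C", "-", ifelse(m[, 9] == "+", "+", "*"))
  gr <- GRanges(m[, 5], IRanges(st, en), strand = strand)
  feature_set(gr, kind = "repeat", family = m[, 11], name = m[, 10])
}

#' Write a feature set as BED6
#'
#' BED conversion (to 0-based half-open) is handled by rtracklayer; a
#' write/read round trip preserves every interval and strand exactly.
#'
#' @param features Feature-set `GRanges`.
#' @param path Output file.
#' @param score Optional numeric score column (BED column 5).
#' @return `path`, invisibly.
#' @export
write_features_bed <- function(features, path, score = NULL) {
  gr <- granges(features)
  nm <- mcols(features)$name
  if (is.null(nm)) nm <- mcols(features)$family
  mcols(gr)$name <- if (is.null(nm)) "." else ifelse(is.na(nm), ".", nm)
  mcols(gr)$score <- if (is.null(score)) 0 else score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a coverage track from bedGraph
#'
#' Returns a strand-aware coverage track: a list of per-strand `RleList`s of
#' non-negative per-base depth. Positions absent from the file have depth 0.
#' Two files can be given for a stranded library (plus and minus); a single
#' file yields an unstranded track.
#'
#' @param path bedGraph for the unstranded (or plus-strand) signal.
#' @param path_minus Optional bedGraph for the minus-strand signal.
#' @param genome Optional named chromosome lengths (pads the vectors).
#' @return A `coverage_track` object.
#' @export
read_coverage <- function(path, path_minus = NULL, genome = NULL) {
  read1 <- function(p) {
    gr <- rtracklayer::import(p, format = "bedGraph")
    if (length(gr) > 1) {
      hits <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
      if (length(hits) > 0) {
        i <- queryHits(hits); j <- subjectHits(hits)
        bad <- gr$score[i] != gr$score[j]
        if (any(bad)) {
          stop("overlapping bedGraph intervals with conflicting values ",
               "(records ", i[which(bad)[1]], " and ", j[which(bad)[1]], ")")
        }
        stop("overlapping bedGraph intervals (records ", i[1], " and ",
             j[1], "); merge the input first")
      }
    }
    if (length(gr) > 0 && any(gr$score < 0)) {
      stop("negative coverage in ", p)
    }
    if (!is.null(genome)) {
      seqlevels(gr) <- union(seqlevels(gr), names(genome))
      seqlengths(gr)[names(genome)] <- genome
    }
    coverage(gr, weight = if (length(gr) > 0) gr$score else 1)
  }
  if (is.null(path_minus)) {
    coverage_track(`*` = read1(path))
  } else {
    coverage_track(`+` = read1(path), `-` = read1(path_minus))
  }
}

#' Write one strand of a coverage track as bedGraph
#'
#' Zero-depth runs are omitted, so an empty track writes an empty file; a
#' write/read round trip reproduces the per-base depths exactly.
#'
#' @param track A `coverage_track`.
#' @param path Output file.
#' @param strand Which component to write (`"*"`, `"+"` or `"-"`).
#' @return `path`, invisibly.
#' @export
write_coverage_bedgraph <- function(track, path, strand = "*") {
  rl <- track_rle(track, strand)
  gr <- methods::as(rl, "GRanges")
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Coverage-track container
#'
#' A thin strand-indexed wrapper around `RleList` per-base depth vectors.
#' Supply either an unstranded list (`*`) or plus/minus lists.
#'
#' @param ... Named arguments among `*`, `+`, `-`, each an `RleList`.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(...) {
  cov <- list(...)
  if (is.null(names(cov)) || !all(names(cov) %in% c("*", "+", "-"))) {
    stop("coverage_track components must be named '*', '+' or '-'")
  }
  if ("*" %in% names(cov) && length(cov) > 1) {
    stop("an unstranded track cannot also carry stranded components")
  }
  structure(list(cov = cov), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  strands <- names(x$cov)
  cat("coverage_track [", paste(strands, collapse = ", "), "]\n", sep = "")
  for (s in strands) {
    chrs <- names(x$cov[[s]])
    tot <- sum(vapply(x$cov[[s]], function(r) sum(as.numeric(r)), 0))
    cat("  strand ", s, ": ", length(chrs), " chromosome(s), total depth ",
        format(tot, big.mark = ","), "\n", sep = "")
  }
  invisible(x)
}

track_strands <- function(track) names(track$cov)

track_rle <- function(track, strand = "*") {
  if (!strand %in% names(track$cov)) {
    stop("track has no '", strand, "' component")
  }
  track$cov[[strand]]
}

#' Merge genomic intervals
#'
#' Sorts and merges a collection of intervals on a single chromosome into the
#' minimal set of disjoint intervals covering the same bases; abutting
#' intervals are merged. Merging is idempotent.
#'
#' @param intervals A `GRanges` (all on one chromosome).
#' @return A sorted, disjoint `GRanges`.
#' @export
merge_intervals <- function(intervals) {
  stopifnot(is(intervals, "GRanges"))
  if (length(intervals) == 0) return(granges(intervals))
  if (length(unique(as.character(seqnames(intervals)))) > 1) {
    stop("merge_intervals requires intervals on a single chromosome")
  }
  reduce(granges(intervals), ignore.strand = TRUE)
}

#' Bases of a query interval covered by a subject set
#'
#' The number of bases of `query` covered by the union of `subject`
#' (double-counting of overlapping subject intervals is impossible: the
#' subject is reduced first). Disjoint chromosomes give 0.
#'
#' @param query A length-1 `GRanges` (or a longer one: per-range results are
#'   summed).
#' @param subject A `GRanges`.
#' @return Integer base count in `[0, sum(width(query))]`.
#' @export
overlap_length <- function(query, subject) {
  stopifnot(is(query, "GRanges"), is(subject, "GRanges"))
  if (length(query) == 0 || length(subject) == 0) return(0L)
  q <- reduce(granges(query), ignore.strand = TRUE)
  s <- reduce(granges(subject), ignore.strand = TRUE)
  lev <- union(seqlevels(q), seqlevels(s))   # disjoint chromosomes give 0
  seqlevels(q) <- lev
  seqlevels(s) <- lev
  sum(width(GenomicRanges::intersect(q, s, ignore.strand = TRUE)))
}

#' Default LINE-1 family predicate
#'
#' TRUE for RepeatMasker-style `repClass/repFamily` tokens belonging to the
#' L1 family (`"LINE/L1"`, optionally with a subfamily suffix) and for bare
#' `"L1"` labels as used in 6-column repeat BEDs.
#'
#' @param family Character vector of family labels.
#' @return Logical vector.
#' @export
is_l1_family <- function(family) {
  !is.na(family) & (family == "L1" | startsWith(family, "LINE/L1"))
}
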