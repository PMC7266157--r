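## LINE-1 composition of intervals and the intron-resampling beta null for
## L1-content enrichment: replicate intronic segments of the focal domain's
## length are drawn at random, their L1 fractions collected, a beta law
## fitted by the method of moments, and the observed fraction scored by the
## beta upper tail (an empirical rank p-value is always reported alongside).

#' L1 repeat composition of an interval
#'
#' Fractions are computed on merged repeat unions, so overlapping repeat
#' fragments are never double-counted. When a transcription strand is given,
#' the antisense L1 fraction (bases covered by L1 elements on the opposite
#' strand — the orientation implicated in chromosome-territory retention) is
#' reported as well.
#'
#' @param interval Length-1 `GRanges`.
#' @param repeats Feature-set `GRanges` (rows with `kind == "repeat"` used).
#' @param transcription_strand Optional `"+"` or `"-"`.
#' @param is_l1 Predicate on family labels; default [is_l1_family()].
#' @return List of class `repeat_composition`: `interval`, `l1_fraction`,
#'   `antisense_l1_fraction` (NA when no strand given),
#'   `per_family_fractions`.
#' @export
l1_fraction <- function(interval, repeats, transcription_strand = NULL,
                        is_l1 = is_l1_family) {
  stopifnot(is(interval, "GRanges"), length(interval) == 1)
  reps <- repeats
  if (!is.null(mcols(reps)$kind)) {
    reps <- reps[mcols(reps)$kind == "repeat"]
  }
  fam <- mcols(reps)$family
  l1 <- reps[is_l1(fam)]
  len <- width(interval)
  frac <- overlap_length(interval, l1) / len
  anti <- NA_real_
  if (!is.null(transcription_strand)) {
    stopifnot(transcription_strand %in% c("+", "-"))
    opp <- if (transcription_strand == "+") "-" else "+"
    anti <- overlap_length(interval,
                           l1[as.character(strand(l1)) == opp]) / len
  }
  fams <- unique(fam[!is.na(fam)])
  pf <- vapply(fams, function(f) {
    overlap_length(interval, reps[!is.na(fam) & fam == f]) / len
  }, 0)
  structure(list(interval = interval, l1_fraction = frac,
                 antisense_l1_fraction = anti,
                 per_family_fractions = pf),
            class = "repeat_composition")
}

#' @export
print.repeat_composition <- function(x, ...) {
  cat(sprintf("repeat_composition %s:%d-%d  L1 fraction %.3f",
              as.character(seqnames(x$interval)), start(x$interval),
              end(x$interval), x$l1_fraction))
  if (!is.na(x$antisense_l1_fraction)) {
    cat(sprintf("  (antisense %.3f)", x$antisense_l1_fraction))
  }
  cat("\n")
  invisible(x)
}

#' Build the merged intron set of a gene annotation
#'
#' Per-gene gaps between consecutive exons, merged across genes; any
#' candidate intron overlapping an exon of any gene is removed (not
#' trimmed). Single-exon genes contribute nothing.
#'
#' @param features Feature-set `GRanges` with `kind` in gene/exon and exon
#'   `name` identifying the parent gene.
#' @return `GRanges` of disjoint intronic intervals.
#' @export
build_intron_set <- function(features) {
  exons <- features[mcols(features)$kind == "exon"]
  if (length(exons) == 0) return(GRanges())
  key <- paste(as.character(seqnames(exons)), mcols(exons)$name)
  parts <- split(granges(exons), key)
  introns <- unlist(methods::as(lapply(parts, function(ex) {
    if (length(ex) < 2) return(GRanges())
    GenomicRanges::setdiff(range(granges(ex), ignore.strand = TRUE),
                           reduce(granges(ex), ignore.strand = TRUE),
                           ignore.strand = TRUE)
  }), "GRangesList"), use.names = FALSE)
  if (length(introns) == 0) return(GRanges())
  introns <- reduce(introns, ignore.strand = TRUE)
  introns[!IRanges::overlapsAny(introns, exons, ignore.strand = TRUE)]
}

#' Intron-resampling null for L1 content
#'
#' Each replicate draws introns uniformly with replacement (from a
#' canonically sorted intron set, so input order is irrelevant),
#' concatenating whole introns until the accumulated length reaches the
#' target `L`, then trims the final intron to the exact remaining length,
#' starting at a uniformly chosen in-intron offset. The replicate's L1
#' fraction is L1-covered bases / `L`. A beta distribution is fitted to the
#' replicate fractions by the method of moments; when the fractions are
#' degenerate the fit is flagged unavailable (the empirical p-value remains
#' valid).
#'
#' @param introns `GRanges` of intronic intervals.
#' @param repeats Feature-set `GRanges` of repeats.
#' @param L Target length in bases (genomic span of the focal domain).
#' @param n_reps Number of replicates (>= 100; default 10000).
#' @param seed Integer seed (mandatory).
#' @param is_l1 Family predicate; default [is_l1_family()].
#' @return List of class `resampling_null`: `replicate_fractions`, `n_reps`,
#'   `L`, `alpha`, `beta` (NA when the fit fails), `fit_ok`, `seed`.
#' @export
sample_intron_null <- function(introns, repeats, L, n_reps = 10000, seed,
                               is_l1 = is_l1_family) {
  stopifnot(n_reps >= 100, L > 0)
  if (missing(seed)) stop("a seed is required")
  introns <- sort(reduce(granges(introns), ignore.strand = TRUE),
                  ignore.strand = TRUE)
  total <- sum(as.numeric(width(introns)))
  if (total < L) stop("total intronic length (", total,
                      ") is smaller than target L (", L, ")")
  reps <- repeats
  if (!is.null(mcols(reps)$kind)) reps <- reps[mcols(reps)$kind == "repeat"]
  l1 <- reduce(granges(reps[is_l1(mcols(reps)$family)]),
               ignore.strand = TRUE)
  ## per-intron whole-length L1 overlap, and per-intron L1 pieces for the
  ## trimmed final draw
  w <- width(introns)
  hits <- findOverlaps(introns, l1, ignore.strand = TRUE)
  inter <- IRanges::pintersect(ranges(introns)[queryHits(hits)],
                               ranges(l1)[subjectHits(hits)])
  l1_by_intron <- rep(0, length(introns))
  if (length(hits) > 0) {
    agg <- tapply(width(inter), queryHits(hits), sum)
    l1_by_intron[as.integer(names(agg))] <- as.numeric(agg)
  }
  ## per-intron L1 piece endpoints as plain numeric vectors (fast clipping
  ## against the trimmed final draw)
  piece_starts <- vector("list", length(introns))
  piece_ends <- vector("list", length(introns))
  if (length(hits) > 0) {
    qh <- queryHits(hits)
    sp_s <- split(start(inter), qh)
    sp_e <- split(end(inter), qh)
    piece_starts[as.integer(names(sp_s))] <- sp_s
    piece_ends[as.integer(names(sp_e))] <- sp_e
  }
  set.seed(seed)
  mean_w <- mean(w)
  frac <- vapply(seq_len(n_reps), function(rep_i) {
    acc <- 0
    l1_acc <- 0
    repeat {
      k <- max(2L, ceiling((L - acc) / mean_w * 1.3))
      idx <- sample.int(length(introns), k, replace = TRUE)
      cum <- acc + cumsum(as.numeric(w[idx]))
      cross <- which(cum >= L)
      if (length(cross) == 0) {
        acc <- cum[k]
        l1_acc <- l1_acc + sum(l1_by_intron[idx])
        next
      }
      last <- cross[1]
      if (last > 1) {
        l1_acc <- l1_acc + sum(l1_by_intron[idx[seq_len(last - 1)]])
        acc <- cum[last - 1]
      }
      ## trim the final intron to the exact remaining length
      r <- L - acc
      fi <- idx[last]
      if (r >= w[fi]) {
        l1_acc <- l1_acc + l1_by_intron[fi]
      } else {
        off <- floor(runif(1, 0, w[fi] - r + 1))
        sub_start <- start(introns)[fi] + off
        sub_end <- sub_start + r - 1
        ps <- piece_starts[[fi]]
        if (!is.null(ps)) {
          pe <- piece_ends[[fi]]
          l1_acc <- l1_acc +
            sum(pmax(0, pmin(pe, sub_end) - pmax(ps, sub_start) + 1))
        }
      }
      break
    }
    l1_acc / L
  }, 0)
  fit <- fit_beta_mom(frac)
  structure(list(replicate_fractions = frac, n_reps = n_reps, L = L,
                 alpha = if (fit$ok) fit$alpha else NA_real_,
                 beta = if (fit$ok) fit$beta else NA_real_,
                 fit_ok = fit$ok, seed = seed),
            class = "resampling_null")
}

#' @export
print.resampling_null <- function(x, ...) {
  cat(sprintf(paste0("resampling_null: %d replicates of length %d; mean ",
                     "fraction %.4f"),
              x$n_reps, x$L, mean(x$replicate_fractions)))
  if (x$fit_ok) {
    cat(sprintf("; beta(%.2f, %.2f)", x$alpha, x$beta))
  } else {
    cat("; beta fit unavailable")
  }
  cat("\n")
  invisible(x)
}

#' Method-of-moments beta fit
#'
#' For sample mean `m` and variance `v` with `0 < v < m(1-m)`:
#' `c = m(1-m)/v - 1`, `alpha = m c`, `beta = (1-m) c`. The fitted mean
#' equals the sample mean exactly. Degenerate input (fewer than 2 distinct
#' values, or variance outside the feasible range) yields `ok = FALSE`.
#'
#' @param fractions Numeric vector of proportions in [0, 1].
#' @return List: `ok`, `alpha`, `beta`, `mean`, `var`.
#' @export
fit_beta_mom <- function(fractions) {
  fractions <- fractions[!is.na(fractions)]
  m <- mean(fractions)
  v <- var(fractions)
  if (length(unique(fractions)) < 2 || !is.finite(v) || v <= 0 ||
      v >= m * (1 - m)) {
    return(list(ok = FALSE, alpha = NA_real_, beta = NA_real_,
                mean = m, var = v))
  }
  cc <- m * (1 - m) / v - 1
  list(ok = TRUE, alpha = m * cc, beta = (1 - m) * cc, mean = m, var = v)
}

#' L1 enrichment p-value against the intron-resampling null
#'
#' `beta_tail` is the upper-tail probability of the fitted beta at the
#' observed fraction (the default); `empirical` is the rank p-value
#' `(r + 1) / (n_reps + 1)` where `r` counts replicates at or above the
#' observed fraction. Both are non-increasing in the observed fraction and
#' lie in (0, 1].
#'
#' @param null A `resampling_null`.
#' @param observed Observed L1 fraction in [0, 1].
#' @param method `"beta_tail"` or `"empirical"`.
#' @return A p-value in (0, 1].
#' @export
l1_enrichment_pvalue <- function(null, observed,
                                 method = c("beta_tail", "empirical")) {
  method <- match.arg(method)
  stopifnot(is(null, "resampling_null"), observed >= 0, observed <= 1)
  if (method == "beta_tail") {
    if (!null$fit_ok) {
      stop("beta fit unavailable for this null; use method = \"empirical\"")
    }
    p <- pbeta(observed, null$alpha, null$beta, lower.tail = FALSE)
    return(max(p, .Machine$double.xmin))
  }
  r <- sum(null$replicate_fractions >= observed)
  (r + 1) / (null$n_reps + 1)
}
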