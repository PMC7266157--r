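## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's interval machinery: everything is per-base boolean
## masks or direct formula evaluation.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## Per-base boolean mask of a set of 1-based closed intervals on [1, len].
rasterize <- function(starts, ends, len) {
  mask <- logical(len)
  for (i in seq_along(starts)) {
    s <- max(1L, starts[i])
    e <- min(len, ends[i])
    if (s <= e) mask[s:e] <- TRUE
  }
  mask
}

## Per-base depth accumulation oracle for bedGraph-style records
## (0-based half-open on disk).
rasterize_depth <- function(starts0, ends0, scores, len) {
  v <- numeric(len)
  for (i in seq_along(starts0)) {
    idx <- (starts0[i] + 1):ends0[i]
    v[idx] <- v[idx] + scores[i]
  }
  v
}

## Run-length oracle for domain calling: positions with depth >= min_cov,
## gaps <= max_gap bridged, runs >= min_len kept. Returns matrix of
## (start, end) rows, 1-based closed.
rle_domain_oracle <- function(depth, min_cov, max_gap, min_len) {
  above <- depth >= min_cov
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) == 0) return(runs)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs[i, 1] - merged[nrow(merged), 2] - 1 <= max_gap) {
        merged[nrow(merged), 2] <- runs[i, 2]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  merged[merged[, 2] - merged[, 1] + 1 >= min_len, , drop = FALSE]
}

## Tie-corrected Kruskal-Wallis H by direct formula evaluation.
kw_H_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- length(x)
  rk <- rank(x)
  Rj <- tapply(rk, rep(seq_along(groups), n), sum)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / n) - 3 * (N + 1)
  t <- table(x)
  H / (1 - sum(t^3 - t) / (N^3 - N))
}

## Exact two-sided binomial p at p0 = 0.5 by summation of all outcome
## probabilities no larger than the observed one.
binom_two_sided_oracle <- function(k, n) {
  pr <- dbinom(0:n, n, 0.5)
  sum(pr[pr <= pr[k + 1] * (1 + 1e-7)])
}

## Write a bedGraph file (0-based half-open) and return its path.
write_bedgraph <- function(chrom, starts0, ends0, scores,
                           path = tempfile(fileext = ".bedGraph")) {
  writeLines(sprintf("%s\t%d\t%d\t%g", chrom, starts0, ends0, scores), path)
  path
}

## A small reusable annotation with a planted L1-rich focal window,
## mirroring the study geometry at reduced genome size.
make_test_annotation <- function(genome_size = 6e6, seed = 42,
                                 focal_l1 = 0.29) {
  win <- GRanges("chr6S", IRanges(2000001, 2185000), l1_target = focal_l1)
  ann <- simulate_annotation(c(chr6S = genome_size),
                             planted_windows = win, seed = seed)
  list(annotation = ann, window = win, genome = c(chr6S = genome_size))
}
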