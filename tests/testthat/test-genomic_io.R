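test_that("GFF and BED coordinate conventions give the expected lengths", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1"),
             gff)
  fs <- read_features(gff, "gff3")
  expect_equal(width(fs), 10)
  expect_equal(start(fs), 1)

  bed <- tempfile(fileext = ".bed")
  writeLines("chr6\t140300000\t141300000", bed)
  fs <- read_features(bed, "bed")
  expect_equal(width(fs), 1000000L)
})

test_that("BED write/read round trip preserves intervals and strands", {
  set.seed(7)
  gr <- GRanges("chrZ", IRanges(sort(sample(1:100000, 20)), width = 500),
                strand = sample(c("+", "-"), 20, TRUE))
  fs <- feature_set(gr, kind = "domain", name = paste0("d", 1:20))
  path <- tempfile(fileext = ".bed")
  write_features_bed(fs, path)
  back <- read_features(path, "bed")
  expect_equal(start(back), start(fs))
  expect_equal(end(back), end(fs))
  expect_equal(as.character(strand(back)), as.character(strand(fs)))
})

test_that("RepeatMasker .out parsing maps C to minus and keeps families", {
  out <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query",
    "score   div. del. ins.  sequence  begin  end",
    "",
    "  463   1.3  0.6  1.7  chr6   1001   1500  (4e6) +  L1PA3    LINE/L1      1 500 (0) 1",
    "  239  29.4  1.9  1.0  chr6   2001   2300  (4e6) C  AluSx    SINE/Alu   (0) 300 1 2",
    "  300  10.0  0.0  0.0  chr6   3001   3800  (4e6) +  L1MB5    LINE/L1      1 800 (0) 3"),
    out)
  fs <- read_features(out, "rmsk_out")
  expect_equal(length(fs), 3)
  expect_true(all(mcols(fs)$kind == "repeat"))
  expect_equal(as.character(strand(fs)), c("+", "-", "+"))
  expect_equal(mcols(fs)$family, c("LINE/L1", "SINE/Alu", "LINE/L1"))
  expect_equal(is_l1_family(mcols(fs)$family), c(TRUE, FALSE, TRUE))
  expect_equal(start(fs), c(1001L, 2001L, 3001L))

  bad <- tempfile(fileext = ".out")
  writeLines("  463 1.3 0.6 1.7 chr6 oops", bad)
  expect_error(read_features(bad, "rmsk_out"), "line 1")
})

test_that("bedGraph coverage equals the per-base accumulation oracle", {
  ## empty file -> all-zero track
  empty <- write_bedgraph("chr1", integer(0), integer(0), numeric(0))
  trk <- read_coverage(empty, genome = c(chr1 = 1000))
  expect_equal(sum(track_depth <- as.numeric(trk$cov[["*"]]$chr1)), 0)

  ## adjacent constant records
  p <- write_bedgraph("chr1", c(0, 100), c(100, 200), c(5, 5))
  trk <- read_coverage(p, genome = c(chr1 = 300))
  v <- as.numeric(trk$cov[["*"]]$chr1)
  expect_equal(v, c(rep(5, 200), rep(0, 100)))

  ## 50 random non-overlapping records vs brute-force rasterization
  set.seed(11)
  starts0 <- sort(sample(seq(0, 9900, 100), 50))
  ends0 <- starts0 + sample(1:99, 50, TRUE)
  scores <- sample(1:30, 50, TRUE)
  p <- write_bedgraph("chr1", starts0, ends0, scores)
  trk <- read_coverage(p, genome = c(chr1 = 10000))
  expect_equal(as.numeric(trk$cov[["*"]]$chr1),
               rasterize_depth(starts0, ends0, scores, 10000))
})

test_that("bedGraph write/read round trip reproduces per-base depth", {
  trk <- simulate_coverage(GRanges("c1", IRanges(c(101, 5001), c(300, 5300)),
                                   depth = c(7, 2)),
                           c(c1 = 10000), noise = "poisson", seed = 19)
  p <- tempfile(fileext = ".bedGraph")
  write_coverage_bedgraph(trk, p)
  back <- read_coverage(p, genome = c(c1 = 10000))
  expect_identical(as.numeric(back$cov[["*"]]$c1),
                   as.numeric(trk$cov[["*"]]$c1))
})

test_that("conflicting overlapping bedGraph records are rejected", {
  p <- write_bedgraph("chr1", c(0, 50), c(100, 150), c(5, 7))
  expect_error(read_coverage(p), "conflicting")
})

test_that("merge_intervals matches the boolean-mask oracle and is idempotent", {
  expect_equal(length(merge_intervals(GRanges())), 0)
  m <- merge_intervals(GRanges("c", IRanges(c(10, 15), c(20, 30))))
  expect_equal(start(m), 10)
  expect_equal(end(m), 30)
  ## abutting intervals merge
  m <- merge_intervals(GRanges("c", IRanges(c(1, 11), c(10, 20))))
  expect_equal(length(m), 1)

  set.seed(3)
  for (rep in 1:5) {
    st <- sample(1:5000, 100, TRUE)
    en <- st + sample(0:200, 100, TRUE)
    gr <- GRanges("c", IRanges(st, en))
    m <- merge_intervals(gr)
    mask <- rasterize(st, en, 6000)
    got <- rasterize(start(m), end(m), 6000)
    expect_identical(got, mask)
    expect_identical(merge_intervals(m), m)   # idempotent
    expect_false(is.unsorted(start(m)))
  }
  expect_error(merge_intervals(GRanges(c("a", "b"), IRanges(1, 2))),
               "single chromosome")
})

test_that("overlap_length matches the per-base mask oracle and its complement identity", {
  q <- GRanges("c", IRanges(100, 399))
  expect_equal(overlap_length(q, GRanges("c", IRanges(1000, 2000))), 0)
  expect_equal(overlap_length(q, q), 300)
  expect_equal(overlap_length(q, GRanges("other", IRanges(100, 399))), 0)

  set.seed(5)
  for (rep in 1:5) {
    st <- sample(1:3000, 50, TRUE)
    en <- st + sample(0:100, 50, TRUE)
    s <- GRanges("c", IRanges(st, en))
    got <- overlap_length(q, s)
    mask <- rasterize(st, en, 4000)
    expect_equal(got, sum(mask[100:399]))
    ## complement identity within the query
    comp <- GenomicRanges::setdiff(q, reduce(s, ignore.strand = TRUE),
                                   ignore.strand = TRUE)
    expect_equal(got, width(q) - overlap_length(q, comp))
  }
})

test_that("feature sets validate repeat families and chromosome bounds", {
  gr <- GRanges("c", IRanges(1, 10))
  expect_error(feature_set(gr, kind = "repeat", family = NA), "family")
  expect_error(feature_set(gr, kind = "gene", genome = c(c = 5)),
               "beyond chromosome length")
  ok <- feature_set(gr, kind = "repeat", family = "LINE/L1",
                    genome = c(c = 100))
  expect_equal(seqlengths(ok)[["c"]], 100)
})
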