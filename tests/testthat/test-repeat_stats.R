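test_that("l1_fraction matches the per-base mask oracle without double counting", {
  iv <- GRanges("c1", IRanges(1000, 1999))
  none <- feature_set(GRanges("c1", IRanges(5000, 6000)), kind = "repeat",
                      family = "SINE/Alu")
  expect_equal(l1_fraction(iv, none)$l1_fraction, 0)

  ## overlapping L1 fragments must not be double-counted
  set.seed(41)
  st <- sample(800:2100, 40, TRUE)
  en <- st + sample(20:200, 40, TRUE)
  reps <- feature_set(GRanges("c1", IRanges(st, en),
                              strand = sample(c("+", "-"), 40, TRUE)),
                      kind = "repeat", family = "LINE/L1")
  got <- l1_fraction(iv, reps, transcription_strand = "+")
  mask <- rasterize(st, en, 3000)
  expect_equal(got$l1_fraction, sum(mask[1000:1999]) / 1000)
  ## antisense fraction counts only minus-strand L1 and never exceeds total
  minus <- as.character(strand(reps)) == "-"
  mask_m <- rasterize(st[minus], en[minus], 3000)
  expect_equal(got$antisense_l1_fraction, sum(mask_m[1000:1999]) / 1000)
  expect_lte(got$antisense_l1_fraction, got$l1_fraction)
})

test_that("l1_fraction of a union is the length-weighted mean of its parts", {
  set.seed(43)
  reps <- feature_set(GRanges("c1", IRanges(sample(1:20000, 60),
                                            width = sample(50:300, 60, TRUE))),
                      kind = "repeat", family = "LINE/L1")
  a <- GRanges("c1", IRanges(1000, 4999))    # 4000 bp
  b <- GRanges("c1", IRanges(9000, 14999))   # 6000 bp
  fa <- l1_fraction(a, reps)$l1_fraction
  fb <- l1_fraction(b, reps)$l1_fraction
  fu <- (overlap_length(a, reps) + overlap_length(b, reps)) / 10000
  expect_equal(fu, (4000 * fa + 6000 * fb) / 10000)
})

test_that("intron construction matches manual enumeration", {
  ## single-exon gene contributes nothing
  single <- feature_set(GRanges("c1", IRanges(c(100, 100), c(500, 500))),
                        kind = c("gene", "exon"), family = "protein_coding",
                        name = "g1")
  expect_equal(length(build_intron_set(single)), 0)

  ## exons (1,100), (201,300) -> intron (101,200)
  g <- feature_set(GRanges("c1", IRanges(c(1, 1, 201), c(300, 100, 300))),
                   kind = c("gene", "exon", "exon"),
                   family = "protein_coding", name = "g2")
  intr <- build_intron_set(g)
  expect_equal(start(intr), 101)
  expect_equal(end(intr), 200)

  ## multi-gene toy locus: gene A exons {1-100, 201-300, 401-500} gives
  ## candidate introns (101,200) and (301,400); gene B exons
  ## {1001-1100, 1301-1400} give (1101,1300); gene C's exon at 320-360 sits
  ## inside gA's second intron, which is therefore removed entirely (not
  ## trimmed)
  ge <- feature_set(
    GRanges("c1", IRanges(c(1, 1, 201, 401,
                            1001, 1001, 1301,
                            320, 320),
                          c(500, 100, 300, 500,
                            1400, 1100, 1400,
                            360, 360))),
    kind = c("gene", "exon", "exon", "exon",
             "gene", "exon", "exon",
             "gene", "exon"),
    family = "protein_coding", name = rep(c("gA", "gB", "gC"), c(4, 3, 2)))
  intr <- build_intron_set(ge)
  expect_setequal(paste(start(intr), end(intr)),
                  c("101 200", "1101 1300"))
})

test_that("beta method-of-moments fit has its algebraic identities", {
  set.seed(47)
  x <- rbeta(500, 3, 9)
  fit <- fit_beta_mom(x)
  expect_true(fit$ok)
  ## MoM identity: fitted mean equals sample mean exactly
  expect_equal(fit$alpha / (fit$alpha + fit$beta), mean(x))

  ## closed-form evaluation at m = 0.29, v = 0.001
  m <- 0.29; v <- 0.001
  cc <- m * (1 - m) / v - 1
  fit2 <- list(alpha = m * cc, beta = (1 - m) * cc)
  expect_equal(fit2$alpha, 0.29 * (0.29 * 0.71 / 0.001 - 1))
  expect_equal(fit2$beta, 0.71 * (0.29 * 0.71 / 0.001 - 1))

  ## shape recovery within 5% relative error at n = 10,000
  set.seed(49)
  y <- rbeta(10000, 2, 5)
  fy <- fit_beta_mom(y)
  expect_lt(abs(fy$alpha - 2) / 2, 0.05)
  expect_lt(abs(fy$beta - 5) / 5, 0.05)

  expect_false(fit_beta_mom(rep(0.3, 10))$ok)
})

test_that("method-of-moments fit agrees with an independent mme fitter", {
  skip_if_not_installed("fitdistrplus")
  set.seed(53)
  x <- rbeta(2000, 4, 11)
  ours <- fit_beta_mom(x)
  ref <- fitdistrplus::fitdist(x, "beta", method = "mme")
  ## same estimator up to the variance denominator (n vs n-1)
  expect_equal(ours$alpha, unname(ref$estimate["shape1"]), tolerance = 0.01)
  expect_equal(ours$beta, unname(ref$estimate["shape2"]), tolerance = 0.01)
})

test_that("intron-resampling null tracks the simulator's intronic L1 density", {
  fix <- make_test_annotation(genome_size = 5e6, seed = 61)
  introns <- build_intron_set(fix$annotation)
  expect_gt(sum(width(introns)), 185000)

  null <- sample_intron_null(introns, fix$annotation, L = 120000,
                             n_reps = 300, seed = 62)
  expect_equal(length(null$replicate_fractions), 300)
  expect_true(all(null$replicate_fractions >= 0 &
                  null$replicate_fractions <= 1))
  ## replicate mean within 3 SE of the true intronic L1 density
  l1 <- fix$annotation[is_l1_family(mcols(fix$annotation)$family)]
  d <- sum(vapply(seq_along(introns),
                  function(i) overlap_length(introns[i], l1), 0L)) /
    sum(width(introns))
  se <- sd(null$replicate_fractions) / sqrt(300)
  expect_lt(abs(mean(null$replicate_fractions) - d), 3 * se)

  ## degenerate nulls: fully covered and empty intron sets
  cov_all <- feature_set(GRanges("cX", IRanges(1, 100000)),
                         kind = "repeat", family = "LINE/L1")
  toy_introns <- GRanges("cX", IRanges(c(1, 50001), c(20000, 90000)))
  n1 <- sample_intron_null(toy_introns, cov_all, L = 30000, n_reps = 100,
                           seed = 1)
  expect_true(all(n1$replicate_fractions == 1))
  expect_false(n1$fit_ok)
  n0 <- sample_intron_null(toy_introns,
                           feature_set(GRanges("cX", IRanges(99990, 99999)),
                                       kind = "repeat", family = "SINE/Alu"),
                           L = 30000, n_reps = 100, seed = 1)
  expect_true(all(n0$replicate_fractions == 0))

  expect_error(sample_intron_null(toy_introns, cov_all, L = 1e7,
                                  n_reps = 100, seed = 1), "smaller")
})

test_that("intron input order does not change the null (canonical sorting)", {
  fix <- make_test_annotation(genome_size = 5e6, seed = 63)
  introns <- build_intron_set(fix$annotation)
  shuffled <- introns[sample(length(introns))]
  n1 <- sample_intron_null(introns, fix$annotation, L = 50000,
                           n_reps = 120, seed = 9)
  n2 <- sample_intron_null(shuffled, fix$annotation, L = 50000,
                           n_reps = 120, seed = 9)
  expect_identical(n1$replicate_fractions, n2$replicate_fractions)
})

test_that("enrichment p-values are monotone and consistent between methods", {
  fix <- make_test_annotation(genome_size = 5e6, seed = 65)
  introns <- build_intron_set(fix$annotation)
  null <- sample_intron_null(introns, fix$annotation, L = 100000,
                             n_reps = 2000, seed = 66)
  obs <- seq(0, 1, by = 0.05)
  pb <- vapply(obs, function(o) l1_enrichment_pvalue(null, o, "beta_tail"), 0)
  pe <- vapply(obs, function(o) l1_enrichment_pvalue(null, o, "empirical"), 0)
  expect_true(all(diff(pb) <= 0))
  expect_true(all(diff(pe) <= 0))
  expect_true(all(pb > 0 & pb <= 1))
  expect_true(all(pe > 0 & pe <= 1))
  ## an observation below every replicate: beta tail > 0.5, empirical ~ 1
  low <- min(null$replicate_fractions) - 0.01
  expect_gt(l1_enrichment_pvalue(null, max(low, 0), "beta_tail"), 0.5)
  expect_equal(l1_enrichment_pvalue(null, max(low, 0), "empirical"),
               (2000 + 1) / (2000 + 1))

  ## beta_tail on a failed fit directs to empirical
  broken <- null
  broken$fit_ok <- FALSE
  expect_error(l1_enrichment_pvalue(broken, 0.2, "beta_tail"), "empirical")
})
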