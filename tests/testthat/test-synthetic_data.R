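test_that("simulators are pure functions of (parameters, seed)", {
  a1 <- simulate_annotation(c(c1 = 1e6), seed = 9)
  a2 <- simulate_annotation(c(c1 = 1e6), seed = 9)
  expect_identical(as.data.frame(a1), as.data.frame(a2))

  f1 <- simulate_fish_table("independent", 50, seed = 4)
  f2 <- simulate_fish_table("independent", 50, seed = 4)
  expect_identical(f1, f2)

  c1 <- simulate_allele_counts("monoallelic", 5, 30, 0.05, seed = 2)
  c2 <- simulate_allele_counts("monoallelic", 5, 30, 0.05, seed = 2)
  expect_identical(c1, c2)
  expect_false(identical(
    c1$rna_ref_count,
    simulate_allele_counts("monoallelic", 5, 30, 0.05, seed = 3)$rna_ref_count))

  expect_type(attr(a1, "provenance")$seed, "integer")
})

test_that("annotation hits per-chromosome L1 density targets", {
  ann0 <- simulate_annotation(c(c1 = 1e6), l1_density = 0,
                              other_densities = c(), seed = 1)
  expect_equal(sum(is_l1_family(mcols(ann0)$family), na.rm = TRUE), 0)

  ## 10 Mb at the autosomal background target 0.13 -> realized in [0.11, 0.15]
  ann <- simulate_annotation(c(c1 = 10e6), l1_density = 0.13, seed = 8)
  l1 <- ann[mcols(ann)$kind == "repeat" & is_l1_family(mcols(ann)$family)]
  frac <- overlap_length(GRanges("c1", IRanges(1, 10e6)), l1) / 10e6
  expect_gt(frac, 0.11)
  expect_lt(frac, 0.15)

  expect_error(simulate_annotation(c(c1 = 1e6), l1_density = 0.7,
                                   other_densities = c(x = 0.5)),
               "infeasible")
})

test_that("planted windows get their own L1 fraction and stay gene-free", {
  win <- GRanges("c1", IRanges(2000001, 2185000), l1_target = 0.29)
  ann <- simulate_annotation(c(c1 = 6e6), planted_windows = win, seed = 21)
  comp <- l1_fraction(win, ann)
  expect_gt(comp$l1_fraction, 0.27)
  expect_lt(comp$l1_fraction, 0.31)
  genes <- ann[mcols(ann)$kind == "gene"]
  expect_equal(overlap_length(win, genes), 0)
})

test_that("coverage simulation honors domains, background and noise model", {
  genome <- c(c1 = 100000)
  trk0 <- simulate_coverage(GRanges(), genome, seed = 1)
  expect_equal(sum(as.numeric(trk0$cov[["*"]]$c1)), 0)

  dom <- GRanges("c1", IRanges(10001, 40000), depth = 20)
  trk <- simulate_coverage(dom, genome, noise = "none", seed = 1)
  v <- as.numeric(trk$cov[["*"]]$c1)
  expect_true(all(v[10001:40000] == 20))
  expect_true(all(v[-(10001:40000)] == 0))

  ## Poisson mean within 3 SE of target over a 10 kb domain
  dom <- GRanges("c1", IRanges(1, 10000), depth = 20)
  trk <- simulate_coverage(dom, genome, noise = "poisson", seed = 5)
  m <- mean(as.numeric(trk$cov[["*"]]$c1)[1:10000])
  se <- sqrt(20 / 10000)
  expect_lt(abs(m - 20), 3 * se)

  over <- GRanges("c1", IRanges(c(1, 500), c(1000, 1500)), depth = 5)
  expect_error(simulate_coverage(over, genome), "overlapping")
})

test_that("allele-count simulation matches its binomial model", {
  mono <- simulate_allele_counts("monoallelic", 50, 40, error_rate = 0,
                                 seed = 6)
  minor <- pmin(mono$rna_ref_count, mono$rna_alt_count)
  expect_true(all(minor == 0))
  ## expressed haplotype B: the expressed allele always gets all the reads
  exp_allele <- mono$hap_B_allele
  got_ref <- ifelse(exp_allele == mono$ref, mono$rna_ref_count,
                    mono$rna_alt_count)
  expect_true(all(got_ref == 40))

  bi <- simulate_allele_counts("biallelic", 200, 1000, seed = 7)
  fr <- mean(bi$rna_ref_count / 1000)
  se <- sqrt(0.25 / 1000 / 200)
  expect_lt(abs(fr - 0.5), 3 * se)

  expect_error(simulate_allele_counts("monoallelic", 0, 10), "positive")
})

test_that("FISH simulation matches closed-form expectations", {
  clean <- simulate_fish_table("coordinated_cis", 200, seed = 1)
  res <- score_cis_trans(clean, c("vlinc273", "KCNQ5"))
  expect_equal(res$cis_fraction, 1.0)

  ind <- simulate_fish_table("independent", 10000, seed = 2)
  res <- score_cis_trans(ind, c("vlinc273", "KCNQ5"))
  se <- sqrt(0.25 / res$n_informative)
  expect_lt(abs(res$cis_fraction - 0.5), 3 * se)

  ## with miscall m, expected cis fraction among doubly-detected cells is
  ## (1-m)^2 + m^2
  m <- 0.1
  mis <- simulate_fish_table("coordinated_cis", 20000, miscall_rate = m,
                             seed = 3)
  res <- score_cis_trans(mis, c("vlinc273", "KCNQ5"))
  expect_cis <- (1 - m)^2 + m^2
  se <- sqrt(expect_cis * (1 - expect_cis) / res$n_informative)
  expect_lt(abs(res$cis_fraction - expect_cis), 3 * se)
})

test_that("ReTiSH simulation is classified as constructed", {
  syn <- simulate_retish_table("synchronous", 50, seed = 1)
  agg <- aggregate_retish(syn, "ASAR6", "vlinc273")
  expect_equal(agg$n_informative, 0)
  ## no single-homolog 5 h locus signal anywhere
  five <- syn[syn$timepoint == "5h" & syn$probe != "cen", ]
  expect_true(all(five$homologs %in% c("", "A,B")))

  cis <- aggregate_retish(simulate_retish_table("async_cis", 100, seed = 2),
                          "ASAR6", "vlinc273")
  expect_equal(cis$cis_fraction, 1.0)

  tr <- aggregate_retish(simulate_retish_table("async_trans", 500, seed = 3),
                         "ASAR6", "vlinc273")
  expect_equal(tr$trans_fraction, 1.0)
  expect_equal(tr$n_informative, 500)
})

test_that("BrdU image construction plants exact ratios", {
  img <- simulate_brdu_image(1.0, noise_sd = 0, seed = 1)
  t6a <- sum(img$brdu[img$mask_6A])
  t6b <- sum(img$brdu[img$mask_6B])
  expect_equal(t6b / t6a, 1.0)

  img <- simulate_brdu_image(0.5, noise_sd = 0, seed = 2)
  expect_equal(sum(img$brdu[img$mask_6B]) / sum(img$brdu[img$mask_6A]), 0.5)

  ## 6A centromere blob strictly larger
  expect_gt(sum(img$cen[img$mask_6A] > 0), sum(img$cen[img$mask_6B] > 0))

  expect_error(simulate_brdu_image(2, nrow = 32, ncol = 64))
  expect_error(simulate_brdu_image(0))
})
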