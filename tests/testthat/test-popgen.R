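test_that("pairwise differences match a brute-force sequence comparison", {
  gm <- tiny_gene_model()
  expect_identical(pairwise_differences(haplotype(), haplotype()), 0L)
  # {4->A} vs {} differ at one site (reference base at 4 is G)
  h <- haplotype(4L, "A", gm = gm)
  expect_identical(pairwise_differences(h, haplotype()), 1L)
  # shared position with different bases counts once
  h1 <- haplotype(c(5L, 9L), c("C", "T"), gm = gm)
  h2 <- haplotype(5L, "G", gm = gm)
  expect_identical(pairwise_differences(h1, h2), 2L)

  set.seed(101)
  for (rep in 1:100) {
    a <- random_haplotype(gm, sample(0:6, 1L))
    b <- random_haplotype(gm, sample(0:6, 1L))
    expect_identical(pairwise_differences(a, b), oracle_pairwise(a, b, gm))
    expect_identical(pairwise_differences(a, b), pairwise_differences(b, a))
  }
})

test_that("pi and dxy equal the brute-force double-loop oracles exactly", {
  gm <- tiny_gene_model()
  expect_equal(nucleotide_diversity(list(haplotype(), haplotype())), 0)
  expect_true(is.na(nucleotide_diversity(list(haplotype()))))
  one_diff <- list(haplotype(), haplotype(3L, "C", gm = gm))
  expect_equal(nucleotide_diversity(one_diff), 1)

  set.seed(202)
  for (rep in 1:10) {
    group <- lapply(seq_len(sample(2:8, 1L)), function(i) random_haplotype(gm, sample(0:5, 1L)))
    expect_equal(nucleotide_diversity(group), oracle_pi(group, gm))
    ga <- lapply(1:4, function(i) random_haplotype(gm, sample(0:5, 1L)))
    gb <- lapply(1:3, function(i) random_haplotype(gm, sample(0:5, 1L)))
    expect_equal(dxy(ga, gb), oracle_dxy(ga, gb, gm))
  }

  # W all reference vs Z all carrying one LOF site -> dxy = 1
  w <- list(haplotype(), haplotype())
  z <- list(haplotype(12L, "A", gm = gm), haplotype(12L, "A", gm = gm))
  expect_equal(dxy(w, z), 1)
  expect_true(is.na(dxy(list(), z)))
})

test_that("diversity_stats matches the pairwise definitions on whole populations", {
  gm <- tiny_gene_model()
  set.seed(303)
  haps <- c(
    lapply(1:6, function(i) random_haplotype(gm, sample(0:4, 1L))),
    list(haplotype(12L, "A", gm = gm), haplotype(12L, "A", gm = gm))
  )
  pop <- manual_population(haps, gm)
  dv <- diversity_stats(pop, gm)
  functional <- vapply(haps, `[[`, logical(1), "functional")
  expect_equal(dv$pi_all, oracle_pi(haps, gm))
  expect_equal(dv$pi_w, oracle_pi(haps[functional], gm))
  expect_equal(dv$pi_z, oracle_pi(haps[!functional], gm))
  expect_equal(dv$dxy, oracle_dxy(haps[functional], haps[!functional], gm))
})

test_that("fst behaves at the degenerate and exchangeable extremes", {
  expect_equal(fst(0, 0, 1), 1)          # complete fixation of the difference
  expect_equal(fst(2, 2, 2), 0)          # no differentiation
  expect_true(is.na(fst(0, 0, 0)))       # undefined when dxy = 0
  expect_true(is.na(fst(NA, 1, 2)))

  # random label shuffles of one pool: never above 1, symmetric in the labels
  gm <- tiny_gene_model()
  set.seed(404)
  pool <- lapply(1:10, function(i) random_haplotype(gm, sample(1:4, 1L)))
  for (rep in 1:20) {
    idx <- sample(10L, 5L)
    a <- pool[idx]; b <- pool[-idx]
    v <- fst(nucleotide_diversity(a), nucleotide_diversity(b), dxy(a, b))
    v_swap <- fst(nucleotide_diversity(b), nucleotide_diversity(a), dxy(b, a))
    if (!is.na(v)) {
      expect_lte(v, 1)
      expect_equal(v, v_swap)
    }
  }
  # two literally identical groups: the cross-pair mean includes self pairs,
  # so dxy = pi (n-1)/n and fst = -1/(n-1) exactly (slightly below zero,
  # never positive differentiation)
  same <- pool[1:4]
  expect_equal(fst(nucleotide_diversity(same), nucleotide_diversity(same),
                   dxy(same, same)), -1 / 3, tolerance = 1e-12)
})

test_that("the genotypic sex-association test reproduces the worked examples", {
  # 45 heterozygous females vs 37 homozygous males
  tab <- rbind(female = c(het = 45, hom = 0), male = c(het = 0, hom = 37))
  res <- genotypic_sex_association(tab)
  expect_equal(res$df, 1)
  expect_equal(res$chi2, 82)           # perfect association: chi2 = n
  expect_equal(res$p, 1.36e-19, tolerance = 5e-3)

  # 14 heterozygous females vs 7 homozygous males: chi2 = 21
  tab_fl <- rbind(female = c(het = 14, hom = 0), male = c(het = 0, hom = 7))
  res_fl <- genotypic_sex_association(tab_fl)
  expect_equal(res_fl$chi2, 21)
  expect_equal(res_fl$p, 4.56e-6, tolerance = 1e-2)

  # equal genotype distribution in both sexes: chi2 = 0, p = 1
  eq <- rbind(female = c(10, 10), male = c(5, 5))
  res_eq <- genotypic_sex_association(eq)
  expect_equal(res_eq$chi2, 0)
  expect_equal(res_eq$p, 1)

  # invariant to swapping the sex rows
  res_sw <- genotypic_sex_association(tab[2:1, ])
  expect_equal(res_sw$p, res$p)

  # degenerate margins yield the undefined marker, not an error
  deg <- rbind(female = c(0, 10), male = c(0, 5))
  expect_true(is.na(genotypic_sex_association(deg)$p))

  # full 3-class mode uses 2 degrees of freedom
  tab3 <- rbind(female = c(hom_ref = 2, het = 40, hom_alt = 3),
                male = c(hom_ref = 20, het = 1, hom_alt = 16))
  expect_equal(genotypic_sex_association(tab3, mode = "full_df2")$df, 2)
})

test_that("heterogamety patterns are classified from genotype-by-sex data", {
  sex <- c(rep("F", 4), rep("M", 3))
  expect_equal(heterogamety_pattern(c(1, 1, 1, 1, 2, 2, 2), sex), "ZW_like")
  expect_equal(heterogamety_pattern(c(1, 1, 1, 1, 0, 0, 0), sex), "ZW_like")
  expect_equal(heterogamety_pattern(c(0, 0, 0, 0, 1, 1, 1), sex), "XY_like")
  expect_equal(heterogamety_pattern(c(0, 0, 0, 0, 0, 0, 0), sex), "none")
  expect_equal(heterogamety_pattern(c(1, 1, 1, 0, 2, 2, 2), sex), "none")
  # males homozygous but for different alleles: not a clean pattern
  expect_equal(heterogamety_pattern(c(1, 1, 1, 1, 0, 2, 0), sex), "none")
  # missing genotypes are excluded; all-missing in one sex errors
  expect_equal(heterogamety_pattern(c(1, 1, 1, NA, 2, 2, 2), sex), "ZW_like")
  expect_error(heterogamety_pattern(c(1, 1, 1, 1, NA, NA, NA), sex), "missing")
})

test_that("sex-ratio chi-square matches hand arithmetic", {
  expect_equal(sex_ratio_chisq(50, 50)$chi2, 0)
  expect_equal(sex_ratio_chisq(50, 50)$p, 1)
  r <- sex_ratio_chisq(502, 504)
  expect_equal(r$chi2, 4 / 1006)
  expect_equal(sex_ratio_chisq(10, 0)$chi2, 10)
  expect_error(sex_ratio_chisq(0, 0), "positive")
})

test_that("windowed pi tiles half-open windows and sums to the whole-segment value", {
  # no variants
  w0 <- windowed_pi(integer(0), numeric(0), 30000L, n_haplotypes = 4L)
  expect_equal(w0$pi, rep(0, 3))

  # one site at frequency 0.5, n = 4 haplotypes, in the third window
  w <- windowed_pi(25000L, 0.5, 30000L, n_haplotypes = 4L)
  expect_equal(w$pi, c(0, 0, 2 / 3))
  # oracle: mean pairwise differences among 4 haplotypes, 2 of each allele
  # = (# discordant pairs) / C(4,2) = 4/6
  expect_equal(w$pi[3], 4 / 6)

  # a variant exactly at position 10,000 falls in the second window
  w2 <- windowed_pi(10000L, 0.5, 20000L, n_haplotypes = 4L)
  expect_equal(w2$pi[1], 0)
  expect_gt(w2$pi[2], 0)

  # BED-like export of per-window values
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "pi.bed")
  write_windows_bed(w2, bed, chrom = "chr16")
  got <- read.table(bed, sep = "\t")
  expect_equal(got$V1, rep("chr16", 2))
  expect_equal(got$V2, c(0, 10000))
  expect_equal(got$V3, c(10000, 20000))
  expect_equal(got$V4, w2$pi, tolerance = 1e-6)  # values serialized at 6 sig. digits

  # dosage-matrix interface + total consistency
  set.seed(77)
  dos <- matrix(sample(0:2, 30 * 8, replace = TRUE), nrow = 30)
  pos <- sort(sample(0:49999, 30))
  ww <- windowed_pi(pos, dos, 50000L)
  p <- rowSums(dos) / 16
  expect_equal(sum(ww$pi), sum(2 * p * (1 - p) * 16 / 15))
})

test_that("depth log-ratio uses the symmetric pseudocount", {
  expect_equal(depth_log_ratio(3, 3), 0)
  expect_equal(depth_log_ratio(0, 0), 0)
  expect_equal(depth_log_ratio(1.9, 0.9), 1)
  expect_equal(depth_log_ratio(c(1.9, 0), c(0.9, 0)), c(1, 0))
  expect_error(depth_log_ratio(-1, 1), "non-negative")
})
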