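test_that("allele frequencies count two alleles per non-missing call", {
  expect_equal(allele_frequencies(rep("A:A", 10)), c(A = 1))
  expect_equal(allele_frequencies(c(rep("A:A", 5), rep("B:B", 5))),
               c(A = 0.5, B = 0.5))
  # 8 A/A + 1 A/B + 1 missing: 17 of 18 alleles are A
  calls <- c(rep("A:A", 8), "A:B", NA)
  expect_equal(unname(allele_frequencies(calls)), c(17, 1) / 18)
  expect_error(allele_frequencies(c(NA, NA)), "non-missing")
})

test_that("PIC and gene diversity reproduce the printed validation cells", {
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(round_half_up(pic(c(0.5, 0.5))), 0.38)
  expect_equal(round_half_up(pic(c(0.8, 0.2))), 0.27)
  expect_equal(round_half_up(pic(c(0.89, 0.11))), 0.18)
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.5, 0.25, 0.25)), 0.5546875)
  expect_equal(gene_diversity(c(0.5, 0.5)), 0.5)
  expect_equal(gene_diversity(c(0.8, 0.2)), 0.32)
  expect_equal(gene_diversity(1), 0)
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
})

test_that("pic matches the double-loop oracle and obeys its bounds", {
  set.seed(21)
  for (i in 1:50) {
    k <- sample(1:6, 1)
    p <- as.numeric(stats::rgamma(k, 1)); p <- p / sum(p)
    expect_equal(pic(p), oracle_pic(p), tolerance = 1e-12)
    # permutation invariance
    expect_equal(pic(sample(p)), pic(p), tolerance = 1e-12)
    # pic <= gene diversity, equal only when monomorphic
    expect_lte(pic(p), gene_diversity(p) + 1e-12)
    if (k > 1) expect_lt(pic(p), gene_diversity(p))
  }
  # bi-allelic PIC is maximal at p = 0.5
  top <- pic(c(0.5, 0.5))
  for (q in seq(0.05, 0.95, by = 0.05))
    expect_lte(pic(c(q, 1 - q)), top)
})

test_that("observed heterozygosity is the heterozygous-call fraction", {
  expect_equal(observed_heterozygosity(rep("A:B", 5)), 1)
  expect_equal(observed_heterozygosity(rep("A:A", 5)), 0)
  calls <- c(rep("A:B", 7), rep("A:A", 3), NA, NA)
  expect_equal(observed_heterozygosity(calls), 0.7)
})

test_that("qc_filter drops samples then loci with strict thresholds", {
  # 5 samples x 10 loci, alternating calls so every locus segregates
  calls <- matrix(rep(c("A:A", "A:B"), length.out = 50), 5, 10,
                  dimnames = list(paste0("S", 1:5), paste0("L", 1:10)))
  calls[1, 1:9] <- NA    # S1: 90% missing -> dropped (> 80%)
  calls[2, 1:7] <- NA    # S2: 80% missing exactly (with L9) -> kept
  calls[, 9] <- NA       # L9: fully missing -> dropped (> 90%)
  calls[, 10] <- "A:A"   # L10: monomorphic -> dropped
  qc <- qc_filter(genotype_matrix(calls))
  expect_false("S1" %in% qc$matrix$sample_ids)
  expect_true("S2" %in% qc$matrix$sample_ids)
  expect_setequal(qc$matrix$locus_ids, paste0("L", 1:8))
  expect_setequal(qc$exclusions$id, c("S1", "L9", "L10"))
  expect_equal(qc$exclusions$kind[qc$exclusions$id == "S1"], "sample")
  # monomorphic is judged across retained samples only
  calls2 <- matrix("A:A", 4, 2,
                   dimnames = list(paste0("S", 1:4), c("L1", "L2")))
  calls2[1, 1] <- "A:B"; calls2[1, 2] <- NA; calls2[2, 2] <- "A:B"
  calls2[1, ] <- NA  # S1, the only carrier at L1, is 100% missing
  qc2 <- qc_filter(genotype_matrix(calls2))
  expect_false("L1" %in% qc2$matrix$locus_ids)
})

test_that("locus summary flags group-monomorphic loci as NA", {
  calls <- rbind(
    S1 = c("A:A", "A:B"), S2 = c("A:B", "A:A"),
    S3 = c("A:B", "A:A"), S4 = c("B:B", "A:A"))
  colnames(calls) <- c("L1", "L2")
  gm <- genotype_matrix(calls, groups = c("wild", "wild",
                                          "cultivated", "cultivated"))
  summ <- locus_summary(gm)
  # L1 segregates in both groups; L2 only among wild samples
  expect_false(is.na(summ$pic_wild[1]))
  expect_false(is.na(summ$pic_cultivated[1]))
  expect_false(is.na(summ$pic_wild[2]))
  expect_true(is.na(summ$pic_cultivated[2]))
  expect_equal(polymorphic_count(summ, "wild"), 2L)
  expect_equal(polymorphic_count(summ, "cultivated"), 1L)
  expect_error(polymorphic_count(summ, "feral"), "unknown group")
  # footer means are the means of defined entries
  means <- summary_means(summ)
  expect_equal(means[["pic"]], mean(summ$pic))
  expect_equal(means[["pic_cultivated"]],
               mean(summ$pic_cultivated, na.rm = TRUE))
})

test_that("relabelling alleles leaves every statistic unchanged", {
  set.seed(9)
  g <- simulate_genotype_matrix(2, 10, 30, missing_rate = 0.05, seed = 12)
  summ1 <- locus_summary(g$matrix)
  swapped <- chartr("AB", "BA", g$matrix$calls)
  # restore sorted within-call order after the swap
  swapped[] <- vapply(swapped, function(x) {
    if (is.na(x)) return(NA_character_)
    p <- sort(strsplit(x, ":", fixed = TRUE)[[1]])
    paste(p, collapse = ":")
  }, "")
  gm2 <- genotype_matrix(swapped, groups = unname(g$matrix$groups))
  summ2 <- locus_summary(gm2)
  for (col in c("maf", "k", "gene_diversity", "ho", "pic"))
    expect_equal(summ2[[col]], summ1[[col]], tolerance = 1e-12)
})

test_that("selfed synthetic matrices have zero Ho but live gene diversity", {
  g <- simulate_genotype_matrix(1, 30, 80, selfing = 1, missing_rate = 0,
                                seed = 31)
  summ <- locus_summary(g$matrix)
  polym <- summ  # monomorphic loci were not dropped (no QC): keep all
  expect_true(all(polym$ho == 0))
  # observed allele frequency tracks the generator truth binomially
  p_b <- g$truth$P_true[1, ]
  for (l in seq_along(p_b)) {
    freqs <- allele_frequencies(g$matrix$calls[, l])
    obs_b <- if ("B" %in% names(freqs)) freqs[["B"]] else 0
    # under full selfing the 30 samples carry 30 independent founder alleles
    expect_lt(abs(obs_b - p_b[l]), 3 * sqrt(p_b[l] * (1 - p_b[l]) / 30) + 1e-9)
  }
})
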