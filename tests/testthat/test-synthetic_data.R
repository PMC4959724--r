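test_that("plant_ssrs with no templates yields clean background", {
  pl <- plant_ssrs(1, 1000, NULL, seed = 7)
  expect_length(pl$sequences, 1L)
  expect_equal(nchar(pl$sequences[[1]]), 1000L)
  expect_equal(nrow(pl$truth), 0L)
  # rejection sampling leaves no qualifying run in the background
  expect_equal(nrow(find_ssrs(pl$sequences[[1]])), 0L)
})

test_that("a planted repeat is recovered at its exact truth coordinates", {
  spec <- data.frame(contig_id = "contig1", start = 100L,
                     motif = "AT", n_repeats = 6L)
  pl <- plant_ssrs(1, 1000, spec, seed = 3)
  mined <- find_ssrs(pl$sequences[[1]], contig_id = "contig1")
  expect_equal(nrow(mined), 1L)
  expect_equal(mined$start, 100L)
  expect_equal(mined$end, 112L)
  expect_equal(mined$motif, "AT")
})

test_that("planted truth and mined loci agree exactly (recall and precision 1)", {
  for (seed in 1:5) {
    specs <- random_ssr_specs(15, 4, 8000, seed = seed)
    pl <- plant_ssrs(4, 8000, specs, seed = seed + 10)
    mined <- find_ssrs_set(pl$sequences)
    expect_identical(
      sort(with(pl$truth, paste(contig_id, start, end, motif))),
      sort(with(mined, paste(contig_id, start, end, motif))))
  }
})

test_that("random_ssr_specs hits the requested class mix exactly", {
  sp <- random_ssr_specs(1000, 20, 50000, seed = 9)
  mix <- table(factor(nchar(sp$motif), levels = 2:4))
  frac <- as.numeric(mix) / 1000
  target <- c(0.80, 0.183, 0.012) / sum(c(0.80, 0.183, 0.012))
  # counts are fixed by largest-remainder rounding of the target mix
  expect_equal(as.integer(mix), as.integer(round_half_up(1000 * target, 0)))
  expect_lt(max(abs(frac - target)), 1.5e-3)
})

test_that("plant_ssrs rejects invalid templates", {
  expect_error(plant_ssrs(1, 100, data.frame(
    contig_id = "contig1", start = 0L, motif = "ATAT", n_repeats = 5L)),
    "shorter unit")
  expect_error(plant_ssrs(1, 20, data.frame(
    contig_id = "contig1", start = 10L, motif = "AT", n_repeats = 6L)),
    "fit")
  expect_error(plant_ssrs(1, 100, data.frame(
    contig_id = c("contig1", "contig1"), start = c(10L, 15L),
    motif = c("AT", "AC"), n_repeats = c(5L, 5L))), "overlap")
})

test_that("generators are seed-deterministic", {
  a <- plant_ssrs(2, 2000, random_ssr_specs(4, 2, 2000, seed = 1), seed = 2)
  b <- plant_ssrs(2, 2000, random_ssr_specs(4, 2, 2000, seed = 1), seed = 2)
  expect_identical(a, b)
  v1 <- simulate_allotetraploid_variants(20000, 3, seed = 5)
  v2 <- simulate_allotetraploid_variants(20000, 3, seed = 5)
  expect_identical(v1, v2)
  g1 <- simulate_genotype_matrix(2, 10, 30, seed = 8)
  g2 <- simulate_genotype_matrix(2, 10, 30, seed = 8)
  expect_identical(g1, g2)
})

test_that("zero variant rates yield empty sets", {
  v <- simulate_allotetraploid_variants(10000, 2, homeolog_rate = 0,
                                        allelic_rate = 0, seed = 1)
  expect_equal(nrow(v$truth), 0L)
  expect_equal(nrow(v$combined), 0L)
  expect_true(all(vapply(v$self_sets, nrow, 0L) == 0L))
  expect_error(simulate_allotetraploid_variants(1000, 2, homeolog_rate = 1),
               "rates")
})

test_that("homeologous site count follows the per-bp rate binomially", {
  L <- 100000; rate <- 1 / 657
  counts <- vapply(1:8, function(s)
    sum(simulate_allotetraploid_variants(L, 2, homeolog_rate = rate,
                                         allelic_rate = 0,
                                         seed = s)$truth$kind == "homeologous"),
    0)
  expected <- L * rate                       # ~152
  sd3 <- 3 * sqrt(L * rate * (1 - rate))
  expect_true(all(abs(counts - expected) < sd3))
  # mean over seeds sits much closer
  expect_lt(abs(mean(counts) - expected), sd3 / 2)
})

test_that("homeologous substitution classes follow the default spectrum", {
  v <- simulate_allotetraploid_variants(400000, 2, seed = 13)
  hom <- v$combined[v$truth$kind == "homeologous", ]
  spec <- substitution_spectrum(hom)
  n <- nrow(hom)
  # CT/AG ~62% and CG ~7.5% within 3 binomial sd
  expect_lt(abs(spec[["CT/AG"]] - 0.62), 3 * sqrt(0.62 * 0.38 / n))
  expect_lt(abs(spec[["CG"]] - 0.075), 3 * sqrt(0.075 * 0.925 / n))
})

test_that("every emitted variant site passes the support thresholds unless degraded", {
  v <- simulate_allotetraploid_variants(50000, 2, seed = 4)
  expect_true(all(v$combined$quality >= 30))
  expect_true(all(v$combined$depth >= 3))
  for (s in v$self_sets) {
    expect_true(all(s$quality >= 30))
    expect_true(all(s$depth >= 3))
  }
  vd <- simulate_allotetraploid_variants(50000, 2, degrade_frac = 0.3,
                                         seed = 4)
  deg <- vd$truth$degraded
  expect_equal(sum(deg), floor(0.3 * nrow(vd$truth)))
  ok <- vd$combined$quality >= 30 & vd$combined$depth >= 3
  expect_true(all(ok[!deg]))
  expect_true(all(!ok[deg]))
})

test_that("genotype matrix honours K=1, maximal divergence and selfing", {
  g1 <- simulate_genotype_matrix(1, 10, 20, seed = 2)
  expect_true(all(g1$truth$Q_true == 1))
  # K=2, fixed opposite frequencies, nearly pure ancestry
  g2 <- simulate_genotype_matrix(2, 10, 40, divergence = 1, alpha = 1e-6,
                                 selfing = 1, missing_rate = 0, seed = 3)
  expect_true(all(g2$truth$P_true %in% c(0, 1)))
  d <- ibs_distance(g2$matrix)
  pops <- g2$matrix$groups
  between <- d[pops == "pop1", pops == "pop2"]
  expect_true(all(between == 1))
  # full selfing: no heterozygous call anywhere
  gs <- simulate_genotype_matrix(2, 15, 80, selfing = 1, missing_rate = 0,
                                 seed = 5)
  ho <- apply(gs$matrix$calls, 2, observed_heterozygosity)
  expect_true(all(ho == 0))
})

test_that("Q_true rows sum to one and missingness matches the rate", {
  g <- simulate_genotype_matrix(3, 20, 100, missing_rate = 0.07, seed = 6)
  expect_true(all(abs(rowSums(g$truth$Q_true) - 1) < 1e-9))
  expect_lt(abs(mean(is.na(g$matrix$calls)) - 0.07), 0.02)
  expect_error(simulate_genotype_matrix(2, 5, 10, alpha = 0), "alpha")
})
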