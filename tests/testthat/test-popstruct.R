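test_that("IBS distance counts shared alleles of unordered pairs", {
  gm <- genotype_matrix(rbind(x = "A:A", y = "A:G"), locus_ids = "L1")
  expect_equal(ibs_distance(gm)["x", "y"], 0.5)
  gm2 <- genotype_matrix(rbind(x = c("A:A", "A:G"), y = c("A:A", "A:G")))
  expect_equal(ibs_distance(gm2)["x", "y"], 0)
  gm3 <- genotype_matrix(rbind(x = "A:A", y = "B:B"))
  expect_equal(ibs_distance(gm3)["x", "y"], 1)
  # unordered comparison: G:A vs A:G are identical genotypes
  gm4 <- genotype_matrix(rbind(x = "A:G", y = "A:G"))
  expect_equal(ibs_distance(gm4)["x", "y"], 0)
  gm5 <- genotype_matrix(rbind(x = c("A:A", NA), y = c(NA, "B:B")))
  expect_error(ibs_distance(gm5), "share no")
})

test_that("upgma reproduces hand-worked merges", {
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- upgma(d2)
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_equal(unname(t2$edge.length), c(1.5, 1.5))
  d3 <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  co <- ape::cophenetic.phylo(t3)
  expect_equal(co["A", "B"], 2)
  expect_equal(co["A", "C"], 8)
  # node heights 1 and 4: C's pendant edge is 4
  expect_equal(t3$edge.length[which(t3$edge[, 2] ==
    which(t3$tip.label == "C"))], 4)
})

test_that("upgma equals the average-linkage oracle and is ultrametric", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    m <- random_distance_matrix(n)
    t1 <- upgma(m)
    t2 <- phangorn::upgma(stats::as.dist(m))
    c1 <- ape::cophenetic.phylo(t1)
    c2 <- ape::cophenetic.phylo(t2)[rownames(c1), colnames(c1)]
    expect_lt(max(abs(c1 - c2)), 1e-8)
    # ultrametric: all root-to-tip path lengths equal
    depths <- ape::node.depth.edgelength(t1)[seq_len(n)]
    expect_lt(diff(range(depths)), 1e-9)
  }
  expect_error(upgma(matrix(c(0, NA, NA, 0), 2)), "NA")
})

test_that("upgma tie-break and outgroup rotation are deterministic", {
  # three equidistant taxa: tie resolved toward the smallest ID pair
  d <- matrix(0.4, 3, 3, dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  diag(d) <- 0
  tr <- upgma(d)
  first_pair <- ape::extract.clade(tr, 5L)$tip.label
  expect_setequal(first_pair, c("a", "b"))
  tro <- upgma(d, ladderize_outgroup = "c")
  expect_equal(tro$tip.label[1], "c")
  # rotation preserves the distances
  expect_equal(ape::cophenetic.phylo(tro)[c("a", "b", "c"), c("a", "b", "c")],
               ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")])
  expect_error(upgma(d, ladderize_outgroup = "zz"), "outgroup")
})

test_that("gibbs_admixture respects Q-row normalization and K=1 exactness", {
  g <- simulate_genotype_matrix(2, 8, 25, seed = 2)
  r1 <- gibbs_admixture(g$matrix, K = 1, burnin = 20, reps = 50, seed = 3)
  expect_true(all(r1$Q == 1))
  r2 <- gibbs_admixture(g$matrix, K = 2, burnin = 50, reps = 150, seed = 3)
  expect_true(all(abs(rowSums(r2$Q) - 1) < 1e-9))
  for (Pl in r2$P)
    expect_true(all(abs(rowSums(Pl) - 1) < 1e-9))
  expect_length(r2$loglik_trace, 150L)
  # deterministic under a fixed seed
  r2b <- gibbs_admixture(g$matrix, K = 2, burnin = 50, reps = 150, seed = 3)
  expect_identical(r2, r2b)
  expect_error(gibbs_admixture(g$matrix, K = 99), "exceeds")
  expect_error(gibbs_admixture(g$matrix, K = 2, alpha = 0), "alpha")
})

test_that("admixture recovery on a strongly differentiated K=2 fixture", {
  g <- simulate_genotype_matrix(2, 10, 60, divergence = 1, alpha = 0.05,
                                selfing = 0.95, missing_rate = 0.02,
                                seed = 17)
  run <- gibbs_admixture(g$matrix, K = 2, burnin = 200, reps = 800,
                         alpha = 0.1, seed = 5)
  Qt <- g$truth$Q_true
  mae <- min(mean(abs(run$Q - Qt)), mean(abs(run$Q[, 2:1] - Qt)))
  expect_lt(mae, 0.1)
})

test_that("lnpd is the trace mean penalized by half the variance", {
  expect_equal(lnpd(c(-100, -102)), -102)
  expect_equal(lnpd(rep(-55, 10)), -55)
  # equal mean, higher variance, lower evidence
  expect_lt(lnpd(c(-90, -110)), lnpd(c(-99, -101)))
  expect_error(lnpd(numeric()), "empty")
})

test_that("delta_k finds a planted slope break", {
  set.seed(33)
  for (i in 1:100) {
    kbreak <- sample(2:5, 1)
    mu <- cumsum(c(-1000, ifelse(seq(2, 6) <= kbreak, 100, 4)))
    tab <- expand.grid(K = 1:6, run = 1:4)
    tab$lnpd <- mu[tab$K] + stats::rnorm(nrow(tab), 0, 1)
    expect_equal(attr(delta_k(tab), "best_K"), kbreak)
  }
  lin <- expand.grid(K = 1:4, run = 1:2)
  lin$lnpd <- -100 + 10 * lin$K +
    ifelse(lin$run == 1, -0.5, 0.5)              # exactly linear means
  dk <- delta_k(lin)
  expect_equal(dk$lsecond[2:3], c(0, 0))
  expect_equal(dk$delta_k[2:3], c(0, 0))
  expect_error(delta_k(data.frame(K = rep(1:2, 2), lnpd = 1:4)),
               "three consecutive")
})

test_that("align_runs undoes label switching and averages", {
  set.seed(8)
  Q <- matrix(stats::runif(30), 15, 2); Q <- Q / rowSums(Q)
  expect_equal(align_runs(list(Q, Q)), Q)
  expect_equal(align_runs(list(Q, Q[, 2:1])), Q)
  # exhaustive and greedy search agree for K <= 4
  for (K in 2:4) for (i in 1:10) {
    ref <- matrix(stats::runif(10 * K), 10, K); ref <- ref / rowSums(ref)
    noisy <- ref[, sample(K)] + matrix(stats::runif(10 * K, 0, 0.02), 10, K)
    pe <- markermine:::best_permutation(ref, noisy, exhaustive = TRUE)
    pg <- markermine:::best_permutation(ref, noisy, exhaustive = FALSE)
    expect_equal(as.integer(pe), as.integer(pg))
  }
  expect_error(align_runs(list(Q, Q[, 1, drop = FALSE])), "mixed K")
  avg <- align_runs(list(Q, Q[, 2:1], Q))
  expect_true(all(abs(rowSums(avg) - 1) < 1e-9))
})

test_that("permuting cluster labels leaves lnpd and alignment unchanged", {
  g <- simulate_genotype_matrix(2, 8, 30, seed = 19)
  run <- gibbs_admixture(g$matrix, K = 3, burnin = 30, reps = 100, seed = 9)
  permuted <- run
  permuted$Q <- run$Q[, c(2, 3, 1)]
  expect_equal(lnpd(permuted), lnpd(run))   # trace is label-free
  expect_equal(align_runs(list(run$Q, permuted$Q)), run$Q)
})
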