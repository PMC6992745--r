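test_that("pairwise theta matches the brute-force WC84 oracle per locus", {
  set.seed(101)
  for (i in 1:30) {
    nA <- sample(2:8, 1); nB <- sample(2:8, 1)
    gA <- sample(0:2, nA, replace = TRUE)
    gB <- sample(0:2, nB, replace = TRUE)
    if (length(unique(c(gA, gB))) == 1 && !any(c(gA, gB) == 1)) next
    gm <- gm_from_dosage(matrix(c(gA, gB), ncol = 1))
    A <- gm$samples[seq_len(nA)]; B <- gm$samples[nA + seq_len(nB)]
    est <- wc_fst_pair(gm, A, B)
    orc <- wc84_oracle(gA, gB)
    expect_equal(est$theta, orc$theta, tolerance = 1e-12)
    expect_equal(est$loci$a, orc$a, tolerance = 1e-12)
    expect_equal(est$loci$d, orc$d, tolerance = 1e-12)
  }
})

test_that("fixation and identity limits behave exactly", {
  # complete fixation: theta = 1
  gm <- gm_from_dosage(matrix(c(0, 0, 2, 2), ncol = 1))
  est <- wc_fst_pair(gm, c("s01", "s02"), c("s03", "s04"))
  expect_equal(est$theta, 1)
  # identical genotype vectors: theta <= 0 (unclamped)
  gm2 <- gm_from_dosage(matrix(rep(c(0, 1, 2, 1, 0, 1), each = 4), nrow = 4))
  est2 <- wc_fst_pair(gm2, c("s01", "s02"), c("s03", "s04"))
  expect_lte(est2$theta, 0)
  # single-accession pairs with the allele-copies estimator
  gmp <- gm_from_dosage(matrix(c(0, 2), ncol = 1))
  expect_equal(wc_fst_pair(gmp, "s01", "s02", estimator = "copies")$theta, 1)
  gmq <- gm_from_dosage(matrix(c(1, 1), ncol = 1))
  expect_lte(wc_fst_pair(gmq, "s01", "s02", estimator = "copies")$theta, 0)
})

test_that("theta is symmetric and invariant to site order and ref/alt swap", {
  set.seed(7)
  d <- matrix(sample(0:2, 80, replace = TRUE), nrow = 8)
  gm <- gm_from_dosage(d)
  A <- gm$samples[1:4]; B <- gm$samples[5:8]
  t1 <- wc_fst_pair(gm, A, B)$theta
  expect_identical(t1, wc_fst_pair(gm, B, A)$theta)
  perm <- sample(ncol(d))
  expect_equal(wc_fst_pair(subset_geno(gm, sites = perm), A, B)$theta, t1,
               tolerance = 1e-12)
  gm_sw <- gm_from_dosage(2 - d)   # relabel ref<->alt at every site
  expect_equal(wc_fst_pair(gm_sw, A, B)$theta, t1, tolerance = 1e-12)
})

test_that("ratio of sums differs from the average of per-locus ratios", {
  set.seed(12)
  d <- matrix(sample(0:2, 120, replace = TRUE), nrow = 6)
  gm <- gm_from_dosage(d)
  est <- wc_fst_pair(gm, gm$samples[1:3], gm$samples[4:6])
  expect_equal(est$theta, sum(est$loci$a) / sum(est$loci$d))
  expect_false(isTRUE(all.equal(est$theta, mean(est$loci$a / est$loci$d))))
})

test_that("group matrix view is symmetric; identical groups give theta ~ 0", {
  set.seed(3)
  d <- matrix(sample(0:2, 300, replace = TRUE), nrow = 10)
  gm <- gm_from_dosage(rbind(d, d))   # two identical groups of 10
  pm <- tibble::tibble(sample = gm$samples, pop = gm$samples)
  part <- group_partition(gm$samples, rep(c("gA", "gB"), each = 10))
  tab <- pairwise_group_fst(gm, pm, part)
  expect_lte(tab$theta, 0)          # no differentiation: at most 0
  expect_lt(abs(tab$theta), 0.1)    # and close to it
  m <- fst_matrix(tab)
  expect_identical(m["gA", "gB"], m["gB", "gA"])
  expect_true(all(is.na(diag(m))))
})

test_that("within-group comparisons produce all accession pairs per group", {
  sc <- synth_scenario(n_per_group = c(east = 5, west = 4, kyushu = 3),
                       L = 300, seed = 2)
  ds <- simulate_dataset(sc)
  w <- within_group_pairwise_fst(ds$gm, ds$popmap, ds$partition)
  counts <- table(w$group)
  expect_equal(unname(counts[c("east", "west", "kyushu")]),
               c(choose(5, 2), choose(4, 2), choose(3, 2)),
               ignore_attr = TRUE)
  # a group of two identical accessions yields one value <= 0
  d <- matrix(rep(c(0, 1, 2, 1), 2), nrow = 2, byrow = TRUE)
  gm <- gm_from_dosage(rbind(d, matrix(sample(0:2, 8, replace = TRUE), 2)))
  pm <- tibble::tibble(sample = gm$samples, pop = gm$samples)
  part <- group_partition(gm$samples, c("twin", "twin", "other", "other"))
  w2 <- within_group_pairwise_fst(gm, pm, part)
  expect_lte(w2$theta[w2$group == "twin"], 0)
  # a single-accession group is skipped with a warning
  part3 <- group_partition(gm$samples, c("a", "a", "b", "solo"))
  expect_warning(within_group_pairwise_fst(gm, pm, part3), "fewer than 2")
})

test_that("lower accession-level drift lowers the within-group mean", {
  base <- function(fw, seed) {
    sc <- synth_scenario(n_per_group = c(east = 8, west = 8, kyushu = 8),
                         L = 600,
                         F_within = c(east = fw, west = 0.6, kyushu = 0.6),
                         seed = seed)
    ds <- simulate_dataset(sc)
    m <- fst_within_means(within_group_pairwise_fst(ds$gm, ds$popmap,
                                                    ds$partition))
    m$mean_theta[m$group == "east"]
  }
  expect_lt(base(0.2, 17), base(0.6, 17))
})

test_that("rank-sum test agrees with the exact enumeration oracle", {
  cases <- list(list(a = c(1, 2), b = c(2, 3)),
                list(a = c(3, 9, 4), b = c(6, 1, 8, 2)),
                list(a = c(1.5, 2.5, 2.5), b = c(2.5, 7, 0)))
  for (cs in cases) {
    rs <- rank_sum_test(cs$a, cs$b)
    orc <- ranksum_exact_oracle(cs$a, cs$b)
    expect_equal(rs$U, orc$U)
    # the normal approximation can only roughly track the exact p at these
    # tiny tied sizes; direction and magnitude must agree
    expect_lt(abs(rs$p_value - orc$p), 0.35)
  }
  # complete separation and identity
  sep <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$direction, "A<B")
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1, tolerance = 0.05)
  # large-sample sanity: shifted distributions are significant
  set.seed(5)
  big <- rank_sum_test(rnorm(60), rnorm(60) + 2)
  expect_lt(big$p_value, 1e-10)
})
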