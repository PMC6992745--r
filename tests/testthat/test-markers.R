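two_group_part <- function(gm, g1, g2) {
  group_partition(gm$samples, c(rep("gA", g1), rep("gB", g2)))
}

test_that("allele summaries record fixed alleles and match a brute tally", {
  # group1 fixed hom-ref, group2 fixed hom-alt, plus a het-broken group
  d <- matrix(c(0, 0, 2, 2,
                0, 1, 2, 2,
                1, 1, 1, 1), nrow = 4)
  gm <- gm_from_dosage(d)
  pm <- tibble::tibble(sample = gm$samples, pop = gm$samples)
  part <- two_group_part(gm, 2, 2)
  summ <- enumerate_snp_loci(gm, pm, part)
  s1 <- summ[summ$id == "chr1:1", ]
  expect_equal(s1$fixed_allele[s1$group == "gA"], "A")
  expect_equal(s1$fixed_allele[s1$group == "gB"], "G")
  s2 <- summ[summ$id == "chr1:2", ]
  expect_true(is.na(s2$fixed_allele[s2$group == "gA"]))  # heterozygote
  # monomorphic-het-everywhere site is still polymorphic (A and G observed)
  expect_true("chr1:3" %in% summ$id)
  # brute-force tally on random sites
  set.seed(33)
  dr <- matrix(sample(c(0:2, NA), 6 * 50, replace = TRUE), nrow = 6)
  gmr <- gm_from_dosage(dr)
  pmr <- tibble::tibble(sample = gmr$samples, pop = gmr$samples)
  partr <- two_group_part(gmr, 3, 3)
  sr <- enumerate_snp_loci(gmr, pmr, partr)
  sg <- sample_groups(pmr, partr)[gmr$samples]
  for (k in sample(nrow(sr), 25)) {
    l <- match(sr$id[k], gmr$sites$id)
    rows <- which(sg == sr$group[k])
    expect_equal(sr$n_typed[k], sum(!is.na(gmr$a1[rows, l])))
    orc <- fixed_allele_oracle(gmr, rows, l)
    expect_equal(sr$fixed_allele[k],
                 radpopgen:::allele_string(gmr$sites[l, ], orc))
  }
})

test_that("two-group search demands strict fixation in both groups", {
  d <- matrix(c(0, 0, 0, 2, 2, 2,   # diagnostic
                0, 1, 0, 2, 2, 2,   # het in gA -> disqualified
                0, 0, 0, 0, 0, 2,   # not fixed in gB
                2, 2, 2, 0, 0, 0),  # diagnostic (swapped orientation)
              nrow = 6)
  gm <- gm_from_dosage(d)
  pm <- tibble::tibble(sample = gm$samples, pop = gm$samples)
  part <- two_group_part(gm, 3, 3)
  mk <- find_two_group_diagnostic(gm, pm, part, min_typed_per_group = 3)
  expect_equal(mk$id, c("chr1:1", "chr1:4"))
  expect_equal(mk$allele_gA, c("A", "G"))
  expect_equal(mk$allele_gB, c("G", "A"))
  # raising min_typed_per_group never adds sites
  mk4 <- find_two_group_diagnostic(gm, pm, part, min_typed_per_group = 4)
  expect_true(all(mk4$id %in% mk$id))
  expect_error(find_two_group_diagnostic(gm, pm,
                                         group_partition(gm$samples,
                                                         rep(c("a", "b", "c"), 2))),
               "exactly 2")
})

test_that("two-group search recovers exactly the planted truth sites", {
  sc <- synth_scenario(n_per_group = c(east = 20, west = 20, kyushu = 20),
                       L = 1500, n_fixed_diagnostic = c(root = 12, wk = 0),
                       seed = 19)
  ds <- simulate_dataset(sc)
  part2 <- group_partition(ds$partition$pop,
                           ifelse(ds$partition$group == "east",
                                  "eastjapan", "westjapan"))
  mk <- find_two_group_diagnostic(ds$gm, ds$popmap, part2)
  truth <- sort(ds$truth$sites$id[ds$truth$sites$split == "root"])
  expect_identical(sort(mk$id), truth)   # precision = recall = 1
})

test_that("search output is invariant to sample order and allele relabeling", {
  set.seed(55)
  lst <- random_three_group(n_per = 4, L = 25, seed = 55)
  part2 <- group_partition(lst$partition$pop,
                           ifelse(lst$partition$group == "g1", "one", "rest"))
  base <- find_two_group_diagnostic(lst$gm, lst$pm, part2,
                                    min_typed_per_group = 1)
  perm <- sample(n_samples(lst$gm))
  mk_p <- find_two_group_diagnostic(subset_geno(lst$gm, samples = perm),
                                    lst$pm, part2, min_typed_per_group = 1)
  expect_identical(mk_p$id, base$id)
  # swap ref/alt labels everywhere
  d <- dosage(lst$gm)
  mk_sw <- find_two_group_diagnostic(gm_from_dosage(2 - d), lst$pm, part2,
                                     min_typed_per_group = 1)
  expect_identical(mk_sw$id, base$id)
})

test_that("no single biallelic site can separate three groups (pigeonhole)", {
  for (seed in 1:5) {
    lst <- random_three_group(n_per = 3, L = 30, seed = seed)
    res <- find_k_group_diagnostic_set(lst$gm, lst$pm, lst$partition,
                                       max_set_size = 2,
                                       min_typed_per_group = 1)
    if (nrow(res) > 0) {
      expect_true(all(table(res$solution) == 2))  # pairs, never singletons
    }
  }
})

test_that("pair search equals brute-force enumeration on small matrices", {
  for (seed in c(2, 7, 11, 23)) {
    lst <- random_three_group(n_per = 4, L = 30, seed = seed)
    res <- find_k_group_diagnostic_set(lst$gm, lst$pm, lst$partition,
                                       min_typed_per_group = 1)
    brute <- brute_force_k_sets(lst$gm, lst$pm, lst$partition)
    got <- if (nrow(res) == 0) list() else
      lapply(split(res$id, res$solution), function(ids)
        sort(match(ids, lst$gm$sites$id)))
    expect_setequal(lapply(got, paste, collapse = "-"),
                    lapply(brute, function(s) paste(sort(s), collapse = "-")))
  }
})

test_that("a triallelic site can label three groups on its own", {
  sc <- synth_scenario(n_per_group = c(east = 5, west = 5, kyushu = 5),
                       L = 100, n_fixed_diagnostic = c(root = 0, wk = 0),
                       n_triallelic_diagnostic = 1, seed = 77)
  ds <- simulate_dataset(sc)
  res <- find_k_group_diagnostic_set(ds$gm, ds$popmap, ds$partition)
  expect_equal(nrow(res), 1L)   # one single-site solution
  tri <- ds$truth$sites[ds$truth$sites$split == "tri", ]
  expect_equal(res$id, tri$id)
  pats <- unlist(res[paste0("allele_", c("east", "west", "kyushu"))])
  expect_equal(length(unique(pats)), 3L)
})

test_that("every returned diagnostic site has zero within-group variance", {
  sc <- synth_scenario(n_per_group = c(east = 6, west = 6, kyushu = 6),
                       L = 400, seed = 41, missing_rate = 0.05)
  ds <- simulate_dataset(sc)
  part2 <- group_partition(ds$partition$pop,
                           ifelse(ds$partition$group == "east",
                                  "eastjapan", "westjapan"))
  mk <- find_two_group_diagnostic(ds$gm, ds$popmap, part2)
  sg <- sample_groups(ds$popmap, part2)[ds$gm$samples]
  for (id in mk$id) {
    l <- match(id, ds$gm$sites$id)
    for (g in c("eastjapan", "westjapan")) {
      al <- c(ds$gm$a1[sg == g, l], ds$gm$a2[sg == g, l])
      expect_equal(length(unique(al[!is.na(al)])), 1L)
    }
  }
})
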