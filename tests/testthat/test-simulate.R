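test_that("identical scenario and seed give identical datasets", {
  sc <- synth_scenario(n_per_group = c(east = 4, west = 4, kyushu = 4),
                       L = 120, missing_rate = 0.05,
                       replicate_of = "east01", replicate_error = 0.01,
                       seed = 42)
  d1 <- simulate_dataset(sc)
  d2 <- simulate_dataset(sc)
  expect_identical(d1$gm$a1, d2$gm$a1)
  expect_identical(d1$truth$sites, d2$truth$sites)
  # and byte-identical VCF bodies
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_vcf(d1$gm, p1); write_vcf(d2$gm, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("no-drift limit reproduces the ancestral frequencies", {
  sc <- synth_scenario(n_per_group = c(east = 60, west = 60, kyushu = 60),
                       L = 400,
                       F_branch = c(east = 0, wk_anc = 0, west = 0, kyushu = 0),
                       n_fixed_diagnostic = c(root = 0, wk = 0), seed = 5)
  ds <- simulate_dataset(sc)
  fg <- ds$truth$group_freq
  expect_equal(fg["east", ], fg["west", ])
  expect_equal(fg["west", ], fg["kyushu", ])
  # realized per-group frequencies match within binomial sampling error
  d <- dosage(ds$gm)
  sg <- sample_groups(ds$popmap, ds$partition)[ds$gm$samples]
  for (g in c("east", "west", "kyushu")) {
    obs <- colMeans(d[sg == g, ], na.rm = TRUE) / 2
    expect_lt(mean(abs(obs - fg[g, ])), 0.05)
  }
})

test_that("degenerate drift parameters are rejected", {
  expect_error(rbalding_nichols(0.5, 1), "\\[0, 1\\)")
  expect_error(synth_scenario(F_branch = c(east = 1, wk_anc = 0.1,
                                           west = 0.1, kyushu = 0.1)),
               "\\[0, 1\\)")
  expect_identical(rbalding_nichols(c(0.3, 0.7), 0), c(0.3, 0.7))
})

test_that("error-free technical replicates are identical to their source", {
  sc <- synth_scenario(n_per_group = c(east = 3, west = 3, kyushu = 3),
                       L = 150, replicate_of = c("west01"),
                       replicate_error = 0, missing_rate = 0, seed = 9)
  ds <- simulate_dataset(sc)
  expect_identical(unname(ds$gm$a1["west01", ]),
                   unname(ds$gm$a1["west01_rep", ]))
  expect_identical(unname(ds$gm$a2["west01", ]),
                   unname(ds$gm$a2["west01_rep", ]))
  expect_equal(ds$truth$replicates$replicate, "west01_rep")
})

test_that("increasing branch drift increases realized divergence", {
  theta_at <- function(F, seed) {
    sim <- simulate_balding_nichols(n_per_pop = 25, L = 1500, F = F,
                                    seed = seed)
    wc_fst_pair(sim$gm, sim$popmap$sample[sim$popmap$pop == "p1"],
                sim$popmap$sample[sim$popmap$pop == "p2"])$theta
  }
  for (seed in 1:3) {
    t_small <- theta_at(0.05, seed)
    t_mid <- theta_at(0.2, seed + 10)
    t_big <- theta_at(0.5, seed + 20)
    expect_lt(t_small, t_mid)
    expect_lt(t_mid, t_big)
  }
})

test_that("planted fixed differences are fixed in the realized matrix", {
  sc <- synth_scenario(n_per_group = c(east = 8, west = 8, kyushu = 8),
                       L = 300, n_fixed_diagnostic = c(root = 10, wk = 4),
                       seed = 13)
  ds <- simulate_dataset(sc)
  sg <- sample_groups(ds$popmap, ds$partition)[ds$gm$samples]
  d <- dosage(ds$gm)
  root <- ds$truth$sites[ds$truth$sites$split == "root", ]
  expect_equal(nrow(root), 10L)
  for (id in root$id) {
    l <- match(id, ds$gm$sites$id)
    east <- d[sg == "east", l]
    rest <- d[sg != "east", l]
    expect_true(all(east %in% c(0, 2)) && length(unique(east)) == 1)
    expect_true(all(rest %in% c(0, 2)) && length(unique(rest)) == 1)
    expect_false(east[1] == rest[1])
  }
})

test_that("a hybrid with alpha = 1 is a plain member of its parent group", {
  sc <- synth_scenario(
    n_per_group = c(east = 10, west = 10, kyushu = 10), L = 1500,
    hybrids = tibble::tibble(sample = "t1", parent1 = "west",
                             parent2 = "kyushu", alpha = 1,
                             sampled_group = "east"),
    seed = 21)
  ds <- simulate_dataset(sc)
  est <- estimate_ancestry_all(ds$gm, ds$popmap, ds$partition)
  q <- est[est$sample == "t1", ]
  # dominant west ancestry despite the small, noisy reference panel
  expect_gt(q$q_west, 0.85)
  expect_lt(q$q_east, 0.05)
  expect_equal(ds$truth$ancestry$west[ds$truth$ancestry$sample == "t1"], 1)
})

test_that("dataset files round-trip through the package readers", {
  sc <- synth_scenario(n_per_group = c(east = 3, west = 3, kyushu = 3),
                       L = 60, missing_rate = 0.1, seed = 31)
  ds <- simulate_dataset(sc)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  gm2 <- read_vcf(paths$vcf, verbose = FALSE)
  expect_identical(unname(gm2$a1), unname(ds$gm$a1))
  expect_identical(gm2$sites$id, ds$gm$sites$id)
  pm2 <- read_popmap(paths$popmap)
  expect_identical(pm2$sample, ds$popmap$sample)
  truth <- readr::read_tsv(file.path(dir, "truth_sites.tsv"),
                           show_col_types = FALSE)
  expect_equal(nrow(truth), sum(sc$n_fixed_diagnostic))
  fa <- read_genome_fasta(paths$fasta)
  expect_named(fa, c("chr1", "chr2"))
})
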