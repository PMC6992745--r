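#' Balding-Nichols frequency draw
#'
#' Child allele frequencies given parent frequencies `p` and branch drift
#' `F`: `Beta(p(1-F)/F, (1-p)(1-F)/F)`, so that `E[f] = p` and
#' `Var[f] = F p (1-p)`. `F = 0` is the exact no-drift limit (frequencies
#' pass through unchanged); fixed parent frequencies (0 or 1) stay fixed.
#'
#' @param p Parent frequency vector in `[0, 1]`.
#' @param F Branch drift in `[0, 1)`.
#' @return Child frequency vector, same length as `p`.
#' @export
rbalding_nichols <- function(p, F) {
  if (F < 0 || F >= 1) stop("drift parameter must lie in [0, 1)")
  if (F == 0) return(p)
  out <- p
  inner <- p > 0 & p < 1
  out[inner] <- stats::rbeta(sum(inner), p[inner] * (1 - F) / F,
                             (1 - p[inner]) * (1 - F) / F)
  out
}

#' Simulate a full synthetic dataset
#'
#' Draws the annotated toy genome, site frequencies along the
#' `((west, kyushu), east)` topology, diploid genotypes, hybrids, planted
#' diagnostic sites, technical replicates and missingness, all reproducible
#' from `scenario$seed`. Truth tables record everything downstream tests
#' need: planted diagnostic sites per split, true ancestry fractions,
#' replicate pairs, group allele frequencies and per-SNP region categories.
#'
#' @param scenario A [synth_scenario].
#' @return A list of class `synth_dataset` with elements `gm`
#'   ([geno_matrix]), `popmap`, `partition`, `genome` and `truth`.
#' @export
simulate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "synth_scenario"))
  genome <- simulate_annotated_genome(scenario)
  set.seed(scenario$seed)
  L <- scenario$L
  st <- genome$snp_truth
  sites <- tibble::tibble(chrom = st$chrom, pos = st$pos,
                          id = paste0(st$chrom, ":", st$pos),
                          ref = st$ref, alt = st$alt)

  # planted diagnostic sites, preferentially in noncoding sequence
  nfd <- scenario$n_fixed_diagnostic
  ntri <- scenario$n_triallelic_diagnostic
  need <- sum(nfd) + ntri
  pool <- which(st$category == "noncoding")
  if (length(pool) < need) pool <- seq_len(L)
  di <- if (need > 0) sample(pool, need) else integer(0)
  root_idx <- utils::head(di, nfd[["root"]])
  wk_idx <- di[seq_len(nfd[["wk"]]) + nfd[["root"]]]
  tri_idx <- utils::tail(di, ntri)
  if (ntri > 0) {
    bases <- c("A", "C", "G", "T")
    sites$alt[tri_idx] <- vapply(sites$ref[tri_idx], function(r)
      paste(sample(setdiff(bases, r), 2), collapse = ","), "")
  }

  # group frequencies along the topology
  Fb <- scenario$F_branch
  p_anc <- stats::runif(L, scenario$ancestral_freq_range[1],
                        scenario$ancestral_freq_range[2])
  f_east <- rbalding_nichols(p_anc, Fb[["east"]])
  f_wk <- rbalding_nichols(p_anc, Fb[["wk_anc"]])
  f_west <- rbalding_nichols(f_wk, Fb[["west"]])
  f_kyu <- rbalding_nichols(f_wk, Fb[["kyushu"]])
  if (length(root_idx) > 0) {
    ori <- rep_len(c(0, 1), length(root_idx))
    f_east[root_idx] <- ori
    f_west[root_idx] <- f_kyu[root_idx] <- 1 - ori
  }
  if (length(wk_idx) > 0) {
    ori <- rep_len(c(1, 0), length(wk_idx))
    f_west[wk_idx] <- ori
    f_kyu[wk_idx] <- 1 - ori
    f_east[wk_idx] <- stats::rbinom(length(wk_idx), 1, 0.5)
  }
  Fg <- rbind(east = f_east, west = f_west, kyushu = f_kyu)

  # core samples: each sample is one accession (its own population)
  grp_names <- names(scenario$n_per_group)
  core <- tibble::tibble(
    sample = unname(unlist(purrr::imap(scenario$n_per_group,
                                       ~ sprintf("%s%02d", .y, seq_len(.x))))),
    group = rep(grp_names, scenario$n_per_group))
  n_core <- nrow(core)
  dos <- matrix(NA_integer_, n_core, L, dimnames = list(core$sample, NULL))
  for (i in seq_len(n_core)) {
    fg <- Fg[core$group[i], ]
    fi <- rbalding_nichols(fg, scenario$F_within[[core$group[i]]])
    dos[i, ] <- stats::rbinom(L, 2L, fi)
  }

  hyb <- scenario$hybrids
  truth_q <- matrix(0, n_core, 3, dimnames = list(core$sample, grp_names))
  truth_q[cbind(seq_len(n_core), match(core$group, grp_names))] <- 1
  if (!is.null(hyb) && nrow(hyb) > 0) {
    hd <- matrix(NA_integer_, nrow(hyb), L, dimnames = list(hyb$sample, NULL))
    hq <- matrix(0, nrow(hyb), 3, dimnames = list(hyb$sample, grp_names))
    for (i in seq_len(nrow(hyb))) {
      fi <- hyb$alpha[i] * Fg[hyb$parent1[i], ] +
        (1 - hyb$alpha[i]) * Fg[hyb$parent2[i], ]
      hd[i, ] <- stats::rbinom(L, 2L, fi)
      hq[i, hyb$parent1[i]] <- hq[i, hyb$parent1[i]] + hyb$alpha[i]
      hq[i, hyb$parent2[i]] <- hq[i, hyb$parent2[i]] + 1 - hyb$alpha[i]
    }
    dos <- rbind(dos, hd)
    truth_q <- rbind(truth_q, hq)
  }
  samples <- rownames(dos)
  grp_of <- c(stats::setNames(core$group, core$sample),
              if (!is.null(hyb)) stats::setNames(hyb$sampled_group, hyb$sample))

  a1 <- ifelse(dos == 2L, 1L, 0L)
  a2 <- ifelse(dos >= 1L, 1L, 0L)
  if (ntri > 0) {
    # each group fixed for a different allele: east 0 (ref), west 1, kyushu 2
    allele_of <- c(east = 0L, west = 1L, kyushu = 2L)
    for (s in seq_along(samples)) {
      q <- truth_q[s, ]
      pick <- function() {
        g <- sample(grp_names, 1, prob = q)
        allele_of[[g]]
      }
      for (t in tri_idx) { a1[s, t] <- pick(); a2[s, t] <- pick() }
    }
  }

  if (scenario$prevent_chance_fixation) {
    is_core <- samples %in% core$sample
    bi <- setdiff(seq_len(L), tri_idx)
    break_fix <- function(set1, set2, keep_idx) {
      fx1 <- fixed_dosage(dos[set1, bi, drop = FALSE])
      fx2 <- fixed_dosage(dos[set2, bi, drop = FALSE])
      hit <- bi[!is.na(fx1) & !is.na(fx2) & fx1 != fx2]
      hit <- setdiff(hit, keep_idx)
      if (length(hit) > 0) {
        r <- which(samples == set1[1])
        a1[r, hit] <<- 0L; a2[r, hit] <<- 1L
        dos[r, hit] <<- 1L
      }
    }
    east_s <- core$sample[core$group == "east"]
    west_s <- core$sample[core$group == "west"]
    kyu_s <- core$sample[core$group == "kyushu"]
    break_fix(east_s, c(west_s, kyu_s), root_idx)
    break_fix(west_s, kyu_s, wk_idx)
  }

  # technical replicates: per-allele-copy flip with rate replicate_error
  reps <- tibble::tibble(sample = character(), replicate = character())
  for (s in scenario$replicate_of) {
    if (!s %in% samples) stop("replicate_of sample not simulated: ", s)
    r1 <- a1[s, ]; r2 <- a2[s, ]
    n_all <- 1L + lengths(strsplit(sites$alt, ",", fixed = TRUE))
    flip <- function(x) {
      fl <- which(!is.na(x) & stats::runif(L) < scenario$replicate_error)
      if (length(fl) > 0) {
        off <- 1L + as.integer(floor(stats::runif(length(fl)) * (n_all[fl] - 1L)))
        x[fl] <- (x[fl] + off) %% n_all[fl]
      }
      x
    }
    r1 <- flip(r1); r2 <- flip(r2)
    rn <- paste0(s, "_rep")
    a1 <- rbind(a1, stats::setNames(r1, NULL)); rownames(a1)[nrow(a1)] <- rn
    a2 <- rbind(a2, stats::setNames(r2, NULL)); rownames(a2)[nrow(a2)] <- rn
    samples <- c(samples, rn)
    grp_of[rn] <- grp_of[[s]]
    truth_q <- rbind(truth_q, truth_q[s, , drop = FALSE])
    rownames(truth_q)[nrow(truth_q)] <- rn
    reps <- dplyr::bind_rows(reps, tibble::tibble(sample = s, replicate = rn))
  }

  if (scenario$missing_rate > 0) {
    miss <- matrix(stats::runif(length(a1)) < scenario$missing_rate,
                   nrow(a1), ncol(a1))
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  }

  gm <- geno_matrix(samples, sites, a1, a2)
  popmap <- tibble::tibble(sample = samples, pop = samples)
  partition <- group_partition(samples, unname(grp_of[samples]))

  truth_sites <- dplyr::bind_rows(
    diag_truth(sites, root_idx, "root", Fg, tri = FALSE),
    diag_truth(sites, wk_idx, "wk", Fg, tri = FALSE),
    diag_truth(sites, tri_idx, "tri", Fg, tri = TRUE))
  structure(list(
    gm = gm, popmap = popmap, partition = partition, genome = genome,
    truth = list(
      sites = truth_sites,
      ancestry = tibble::as_tibble(truth_q, rownames = "sample"),
      replicates = reps,
      group_freq = Fg,
      snp_annotation = genome$snp_truth),
    scenario = scenario), class = "synth_dataset")
}

# fixed dosage per column: 0 if all rows 0, 2 if all rows 2, else NA
fixed_dosage <- function(d) {
  n <- nrow(d)
  out <- rep(NA_integer_, ncol(d))
  out[colSums(d == 0L) == n] <- 0L
  out[colSums(d == 2L) == n] <- 2L
  out
}

diag_truth <- function(sites, idx, split, Fg, tri) {
  if (length(idx) == 0) return(NULL)
  s <- sites[idx, ]
  if (tri) {
    al <- list(east = 0L, west = 1L, kyushu = 2L)
  } else {
    al <- list(east = as.integer(Fg["east", idx]),
               west = as.integer(Fg["west", idx]),
               kyushu = as.integer(Fg["kyushu", idx]))
  }
  tibble::tibble(split = split, id = s$id, chrom = s$chrom, pos = s$pos,
                 allele_east = allele_string(s, al$east),
                 allele_west = allele_string(s, al$west),
                 allele_kyushu = allele_string(s, al$kyushu)) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Two-population Balding-Nichols simulation
#'
#' Single-level calibration design: two populations drawn independently
#' around a common ancestral frequency with the same drift `F`, so the
#' expected multi-locus Weir-Cockerham fixation index is approximately `F`.
#'
#' @param n_per_pop Diploid samples per population.
#' @param L Number of biallelic sites.
#' @param F Drift parameter in `[0, 1)`.
#' @param ancestral_freq_range Uniform range for ancestral frequencies.
#' @param seed Integer seed.
#' @return List with `gm`, `popmap` (populations `p1`, `p2`) and `partition`.
#' @export
simulate_balding_nichols <- function(n_per_pop = 30, L = 5000, F = 0.2,
                                     ancestral_freq_range = c(0.1, 0.9),
                                     seed = 1) {
  set.seed(seed)
  p <- stats::runif(L, ancestral_freq_range[1], ancestral_freq_range[2])
  f1 <- rbalding_nichols(p, F)
  f2 <- rbalding_nichols(p, F)
  draw <- function(f) matrix(stats::rbinom(n_per_pop * L, 2L,
                                           rep(f, each = n_per_pop)),
                             nrow = n_per_pop)
  dos <- rbind(draw(f1), draw(f2))
  samples <- c(sprintf("p1_%02d", seq_len(n_per_pop)),
               sprintf("p2_%02d", seq_len(n_per_pop)))
  rownames(dos) <- samples
  sites <- tibble::tibble(chrom = "chr1", pos = seq_len(L),
                          id = paste0("chr1:", seq_len(L)),
                          ref = "A", alt = "G")
  gm <- geno_matrix(samples, sites,
                    ifelse(dos == 2L, 1L, 0L), ifelse(dos >= 1L, 1L, 0L))
  popmap <- tibble::tibble(sample = samples,
                           pop = rep(c("p1", "p2"), each = n_per_pop))
  list(gm = gm, popmap = popmap,
       partition = group_partition(c("p1", "p2"), c("p1", "p2")))
}
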