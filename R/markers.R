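#' Per-site, per-group allele summaries
#'
#' One summary row per polymorphic site and group: observed allele counts,
#' typed-sample count, and the fixed allele (defined exactly when a single
#' distinct allele is observed in the group). Sites monomorphic across all
#' samples are excluded.
#'
#' @param gm A [geno_matrix].
#' @param pm Popmap tibble.
#' @param partition A [group_partition] covering all samples.
#' @return Tibble with `id`, `chrom`, `pos`, `group`, `n_typed`, `alleles`
#'   (e.g. `"A:12,G:3"`, allele copies) and `fixed_allele` (nucleotide or
#'   `NA`).
#' @export
enumerate_snp_loci <- function(gm, pm, partition) {
  sg <- sample_groups(pm, partition)[gm$samples]
  if (anyNA(sg)) stop("partition does not cover all samples")
  poly <- polymorphic_sites(gm)
  groups <- unique(partition$group)
  purrr::map_dfr(groups, function(g) {
    rows <- which(sg == g)
    fx <- group_fixed_allele(gm, rows)
    purrr::map_dfr(which(poly), function(l) {
      al <- c(gm$a1[rows, l], gm$a2[rows, l])
      al <- al[!is.na(al)]
      tab <- table(allele_string(gm$sites[l, ], al))
      tibble::tibble(
        id = gm$sites$id[l], chrom = gm$sites$chrom[l], pos = gm$sites$pos[l],
        group = g, n_typed = fx$n_typed[l],
        alleles = paste(names(tab), tab, sep = ":", collapse = ","),
        fixed_allele = allele_string(gm$sites[l, ], fx$allele[l]))
    })
  }) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$group)
}

# sites with >= 2 distinct alleles observed over all samples
polymorphic_sites <- function(gm) {
  mn <- suppressWarnings(apply(gm$a1, 2, min, na.rm = TRUE))
  mx <- suppressWarnings(apply(gm$a2, 2, max, na.rm = TRUE))
  het <- colSums(gm$a1 != gm$a2, na.rm = TRUE) > 0
  is.finite(mn) & (mx > mn | het)
}

# per-site fixed allele index for a set of rows: defined when all typed
# genotypes are homozygous for the same allele; NA otherwise
group_fixed_allele <- function(gm, rows) {
  a1 <- gm$a1[rows, , drop = FALSE]
  a2 <- gm$a2[rows, , drop = FALSE]
  n_typed <- colSums(!is.na(a1))
  any_het <- colSums(a1 != a2, na.rm = TRUE) > 0
  mn <- suppressWarnings(apply(a1, 2, min, na.rm = TRUE))
  mx <- suppressWarnings(apply(a2, 2, max, na.rm = TRUE))
  allele <- ifelse(n_typed > 0 & !any_het & mn == mx, mn, NA_integer_)
  list(allele = unname(as.integer(allele)), n_typed = unname(n_typed))
}

#' Fixed-difference diagnostic SNPs for a two-group partition
#'
#' A site qualifies iff both groups have at least `min_typed_per_group`
#' typed samples, every typed genotype in each group is homozygous for a
#' single allele, and the two groups' fixed alleles differ. Output is
#' ordered by chromosome and position.
#'
#' @param gm A [geno_matrix].
#' @param pm Popmap tibble.
#' @param partition2 A [group_partition] with exactly 2 groups.
#' @param min_typed_per_group Minimum typed samples per group (default 3).
#' @param exclude_samples Optional sample blacklist (known transplants,
#'   admixed accessions, technical replicates) removed before searching.
#' @return Tibble of class `diagnostic_markers`: `id`, `chrom`, `pos`,
#'   `ref`, `alt`, one `allele_<group>` column per group; attribute
#'   `complete` is `TRUE` (two groups are always pairwise distinguished).
#' @export
find_two_group_diagnostic <- function(gm, pm, partition2,
                                      min_typed_per_group = 3,
                                      exclude_samples = character()) {
  groups <- unique(partition2$group)
  if (length(groups) != 2) stop("partition must have exactly 2 groups")
  fx <- partition_fixed_alleles(gm, pm, partition2, min_typed_per_group,
                                exclude_samples)
  hit <- which(!is.na(fx[1, ]) & !is.na(fx[2, ]) & fx[1, ] != fx[2, ])
  out <- marker_tibble(gm, hit, fx, groups)
  attr(out, "complete") <- TRUE
  attr(out, "partition") <- partition2
  class(out) <- c("diagnostic_markers", class(out))
  out
}

# groups x sites matrix of fixed allele indices (NA when not fixed or
# undertyped), after removing blacklisted samples
partition_fixed_alleles <- function(gm, pm, partition, min_typed_per_group,
                                    exclude_samples = character()) {
  sg <- sample_groups(pm, partition)[gm$samples]
  sg[gm$samples %in% exclude_samples] <- NA
  groups <- unique(partition$group)
  fx <- matrix(NA_integer_, length(groups), n_sites(gm),
               dimnames = list(groups, gm$sites$id))
  for (g in groups) {
    rows <- which(!is.na(sg) & sg == g)
    r <- group_fixed_allele(gm, rows)
    ok <- r$n_typed >= min_typed_per_group
    fx[g, ok] <- r$allele[ok]
  }
  fx
}

marker_tibble <- function(gm, idx, fx, groups) {
  s <- gm$sites[idx, , drop = FALSE]
  out <- tibble::tibble(id = s$id, chrom = s$chrom, pos = s$pos,
                        ref = s$ref, alt = s$alt)
  for (g in groups) {
    out[[paste0("allele_", g)]] <- allele_string(s, fx[g, idx])
  }
  dplyr::arrange(out, .data$chrom, .data$pos)
}

#' Minimal diagnostic site sets for a K-group partition
#'
#' First looks for single sites whose per-group fixed alleles are all
#' defined and pairwise distinct (possible for three groups only at
#' multiallelic sites); if none exist, exhaustively searches site tuples up
#' to `max_set_size` in which every group is fixed at every member site and
#' the group-to-allele-tuple map is injective. All minimal-cardinality
#' solutions are returned, ordered by the genomic position of their first
#' member.
#'
#' @inheritParams find_two_group_diagnostic
#' @param partitionK A [group_partition] with `K >= 3` groups.
#' @param max_set_size Largest tuple size searched (default 2).
#' @return Tibble of class `diagnostic_set`: one row per (solution, member
#'   site) with `solution`, `member`, site columns and per-group allele
#'   columns. Zero rows with attribute `status` explaining the failure when
#'   no solution exists within `max_set_size`.
#' @export
find_k_group_diagnostic_set <- function(gm, pm, partitionK,
                                        max_set_size = 2,
                                        min_typed_per_group = 3,
                                        exclude_samples = character()) {
  groups <- unique(partitionK$group)
  K <- length(groups)
  stopifnot(K >= 3, max_set_size >= 1)
  fx <- partition_fixed_alleles(gm, pm, partitionK, min_typed_per_group,
                                exclude_samples)
  all_fixed <- colSums(!is.na(fx)) == K
  distinct1 <- all_fixed &
    apply(fx, 2, function(col) length(unique(col)) == K)
  solutions <- lapply(which(distinct1), function(i) i)
  if (length(solutions) == 0 && max_set_size >= 2) {
    cand <- which(all_fixed)
    if (length(cand) >= 2) {
      # a pair fails iff some group pair shares its alleles at both sites
      eq <- lapply(utils::combn(K, 2, simplify = FALSE), function(pr) {
        fx[pr[1], cand] == fx[pr[2], cand]
      })
      bad <- Reduce(`|`, lapply(eq, function(e) outer(e, e, `&`)))
      ok <- which(!bad & upper.tri(bad), arr.ind = TRUE)
      solutions <- lapply(seq_len(nrow(ok)), function(r) {
        cand[c(ok[r, 1], ok[r, 2])]
      })
    }
  }
  if (length(solutions) == 0) {
    out <- marker_tibble(gm, integer(0), fx, groups)
    out$solution <- integer(0); out$member <- integer(0)
    attr(out, "status") <- paste0("no diagnostic set of size <= ",
                                  max_set_size, " exists")
  } else {
    first_pos <- vapply(solutions, function(s) {
      o <- order(gm$sites$chrom[s], gm$sites$pos[s])
      gm$sites$pos[s[o[1]]] + 1e9 * match(gm$sites$chrom[s[o[1]]],
                                          sort(unique(gm$sites$chrom)))
    }, 0)
    solutions <- solutions[order(first_pos)]
    out <- purrr::imap_dfr(solutions, function(s, i) {
      s <- s[order(gm$sites$chrom[s], gm$sites$pos[s])]
      m <- marker_tibble(gm, s, fx, groups)
      dplyr::mutate(m, solution = i, member = dplyr::row_number())
    })
    attr(out, "status") <- "ok"
  }
  attr(out, "complete") <- length(solutions) > 0
  attr(out, "partition") <- partitionK
  class(out) <- c("diagnostic_set", class(out))
  out
}

#' Export marker positions as BED (0-based half-open)
#' @param markers A `diagnostic_markers` / `diagnostic_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_bed <- function(markers, path) {
  writeLines(paste(markers$chrom, markers$pos - 1L, markers$pos, markers$id,
                   sep = "\t"), path)
  invisible(path)
}
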