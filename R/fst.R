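#' Pairwise Weir-Cockerham fixation index for two sample sets
#'
#' Computes per-locus variance components of the Weir & Cockerham (1984)
#' theta estimator for two populations and combines them as a ratio of sums
#' (sum of among-population components over sum of total components), never
#' as an average of per-locus ratios. Loci monomorphic across both sets,
#' untyped in either set, or (in `wc84` mode) with fewer than two typed
#' diploids on average are skipped and counted. Per-locus components are not
#' clamped; the overall estimate can be negative.
#'
#' Two estimator modes:
#' \describe{
#'   \item{`wc84`}{the diploid Weir-Cockerham (1984) components a, b, c
#'     built from allele frequencies, sample sizes and observed
#'     heterozygosity; requires mean sample size above one.}
#'   \item{`copies`}{a one-way analysis of variance on the individual allele
#'     copies (two per diploid), for comparisons where a "population" is a
#'     single accession and the diploid estimator's finite-sample terms are
#'     undefined.}
#' }
#'
#' @param gm A [geno_matrix]; only biallelic sites are used (others are
#'   excluded with a reported count).
#' @param samples_A,samples_B Disjoint, non-empty character vectors of
#'   sample ids.
#' @param estimator `"wc84"` (default) or `"copies"`.
#' @param verbose Report excluded-site counts.
#' @return An object of class `fst_estimate`: list with `theta` (overall
#'   ratio-of-sums estimate), `loci` (per-locus tibble of components `a` and
#'   `d`), `n_loci_used`, `n_loci_skipped` and `estimator`.
#' @export
wc_fst_pair <- function(gm, samples_A, samples_B,
                        estimator = c("wc84", "copies"), verbose = FALSE) {
  estimator <- match.arg(estimator)
  stopifnot(length(samples_A) > 0, length(samples_B) > 0)
  if (length(intersect(samples_A, samples_B)) > 0) {
    stop("sample sets must be disjoint")
  }
  bi <- is_biallelic(gm)
  if (verbose && any(!bi)) {
    message(sum(!bi), " multiallelic site(s) excluded from the fixation index")
  }
  comp <- wc_components(gm, samples_A, samples_B, estimator)
  use <- comp$use & bi
  if (!any(use)) stop("no usable loci shared by the two sample sets")
  theta <- sum(comp$a[use]) / sum(comp$d[use])
  structure(list(theta = theta,
                 loci = tibble::tibble(id = gm$sites$id[use],
                                       a = unname(comp$a[use]),
                                       d = unname(comp$d[use])),
                 n_loci_used = sum(use), n_loci_skipped = sum(!use),
                 estimator = estimator,
                 pair = list(A = samples_A, B = samples_B)),
            class = "fst_estimate")
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("<fst_estimate> theta = %.6f (%s, %d loci used, %d skipped)\n",
              x$theta, x$estimator, x$n_loci_used, x$n_loci_skipped))
  invisible(x)
}

# per-locus numerators (a) and denominators (d) plus a usability mask
wc_components <- function(gm, samples_A, samples_B, estimator) {
  d <- dosage(gm)
  stats_of <- function(set) {
    ds <- d[set, , drop = FALSE]
    n <- colSums(!is.na(ds))
    p <- ifelse(n > 0, colSums(ds, na.rm = TRUE) / (2 * n), NA_real_)
    het <- colSums(gm$a1[set, , drop = FALSE] != gm$a2[set, , drop = FALSE],
                   na.rm = TRUE) / pmax(n, 1)
    list(n = n, p = p, het = het)
  }
  A <- stats_of(samples_A); B <- stats_of(samples_B)
  typed <- A$n > 0 & B$n > 0
  mono <- (A$p == 0 & B$p == 0) | (A$p == 1 & B$p == 1)
  poly <- typed & !is.na(mono) & !mono
  r <- 2
  if (estimator == "wc84") {
    nbar <- (A$n + B$n) / r
    use <- poly & nbar > 1
    nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
    pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
    s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
    hbar <- (A$n * A$het + B$n * B$het) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    list(a = a, d = a + b + cc, use = use & is.finite(a))
  } else {
    # ANOVA on allele copies: each diploid contributes 2 haploid observations
    m1 <- 2 * A$n; m2 <- 2 * B$n
    N <- m1 + m2
    use <- poly & A$n >= 1 & B$n >= 1
    pbar <- (m1 * A$p + m2 * B$p) / N
    msa <- (m1 * (A$p - pbar)^2 + m2 * (B$p - pbar)^2) / (r - 1)
    msw <- (m1 * A$p * (1 - A$p) + m2 * B$p * (1 - B$p)) / (N - r)
    nc <- (N - (m1^2 + m2^2) / N) / (r - 1)
    a <- msa - msw
    list(a = a, d = msa + (nc - 1) * msw, use = use & is.finite(a))
  }
}

#' Pairwise fixation indices among the groups of a partition
#'
#' Every unordered pair of groups is compared with [wc_fst_pair()] on the
#' groups' samples (the Table-2-style view).
#'
#' @param gm A [geno_matrix].
#' @param pm Popmap tibble.
#' @param partition A [group_partition] with `K >= 2` groups.
#' @param estimator Passed to [wc_fst_pair()].
#' @return A tibble of class `fst_pairwise` with columns `group1`, `group2`,
#'   `theta`, `n_loci`; the symmetric matrix is available via
#'   [fst_matrix()].
#' @export
pairwise_group_fst <- function(gm, pm, partition, estimator = "wc84") {
  groups <- unique(partition$group)
  stopifnot(length(groups) >= 2)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    est <- wc_fst_pair(gm, group_samples(gm, pm, partition, pr[1]),
                       group_samples(gm, pm, partition, pr[2]),
                       estimator = estimator)
    tibble::tibble(group1 = pr[1], group2 = pr[2], theta = est$theta,
                   n_loci = est$n_loci_used)
  })
  class(out) <- c("fst_pairwise", class(out))
  out
}

#' Symmetric matrix view of pairwise fixation indices
#' @param x An `fst_pairwise` tibble.
#' @return Symmetric numeric matrix with `NA` diagonal.
#' @export
fst_matrix <- function(x) {
  groups <- unique(c(x$group1, x$group2))
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  m[cbind(x$group1, x$group2)] <- x$theta
  m[cbind(x$group2, x$group1)] <- x$theta
  m
}

#' Accession-level pairwise fixation indices within each group
#'
#' Every unordered pair of accessions (populations of one diploid) within a
#' group is compared with the `copies` estimator (the Fig.-7-style view);
#' loci where either accession is untyped are skipped. Groups with fewer
#' than two accessions are skipped with a warning.
#'
#' @param gm A [geno_matrix].
#' @param pm Popmap tibble (accession = population).
#' @param partition A [group_partition].
#' @return A tibble of class `fst_within`: `group`, `acc1`, `acc2`, `theta`,
#'   plus a per-group `mean` attribute via [fst_within_means()].
#' @export
within_group_pairwise_fst <- function(gm, pm, partition) {
  sg <- sample_groups(pm, partition)
  out <- purrr::map_dfr(unique(partition$group), function(g) {
    accs <- gm$samples[gm$samples %in% names(sg)[!is.na(sg) & sg == g]]
    if (length(accs) < 2) {
      warning("group '", g, "' has fewer than 2 accessions; skipped")
      return(NULL)
    }
    prs <- utils::combn(accs, 2, simplify = FALSE)
    purrr::map_dfr(prs, function(pr) {
      est <- wc_fst_pair(gm, pr[1], pr[2], estimator = "copies")
      tibble::tibble(group = g, acc1 = pr[1], acc2 = pr[2],
                     theta = est$theta, n_loci = est$n_loci_used)
    })
  })
  class(out) <- c("fst_within", class(out))
  out
}

#' Per-group mean of within-group accession-pairwise fixation indices
#' @param x An `fst_within` tibble.
#' @return Tibble with `group`, `n_pairs`, `mean_theta`.
#' @export
fst_within_means <- function(x) {
  dplyr::summarise(dplyr::group_by(x, .data$group),
                   n_pairs = dplyr::n(),
                   mean_theta = mean(.data$theta), .groups = "drop")
}

#' Two-sided rank-sum comparison of two value collections
#'
#' Mann-Whitney U with midrank ties, normal approximation with tie and
#' continuity correction (the two-sided test used to compare within-group
#' fixation-index distributions at the 5% level).
#'
#' @param values_A,values_B Non-empty numeric vectors.
#' @return A tibble with `U` (A-side statistic), `z`, `p_value`, `n1`, `n2`
#'   and `direction` (`"A<B"`, `"A>B"` or `"none"`).
#' @export
rank_sum_test <- function(values_A, values_B) {
  stopifnot(length(values_A) > 0, length(values_B) > 0)
  wt <- suppressWarnings(stats::wilcox.test(values_A, values_B,
                                            exact = FALSE, correct = TRUE))
  U <- unname(wt$statistic)
  n1 <- length(values_A); n2 <- length(values_B)
  p <- min(1, wt$p.value)
  z <- stats::qnorm(p / 2) * sign(U - n1 * n2 / 2)
  if (U == n1 * n2 / 2) z <- 0
  tibble::tibble(U = U, z = z, p_value = p, n1 = n1, n2 = n2,
                 direction = if (U < n1 * n2 / 2) "A<B"
                 else if (U > n1 * n2 / 2) "A>B" else "none")
}

#' Compare within-group distributions between all group pairs
#' @param x An `fst_within` tibble.
#' @param alpha Two-sided significance level for the `significant` flag.
#' @return Tibble with one row per group pair and rank-sum columns.
#' @export
fst_within_comparisons <- function(x, alpha = 0.05) {
  groups <- unique(x$group)
  prs <- utils::combn(groups, 2, simplify = FALSE)
  purrr::map_dfr(prs, function(pr) {
    rs <- rank_sum_test(x$theta[x$group == pr[1]], x$theta[x$group == pr[2]])
    dplyr::mutate(rs, group1 = pr[1], group2 = pr[2],
                  significant = .data$p_value < alpha, .before = 1)
  })
}
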