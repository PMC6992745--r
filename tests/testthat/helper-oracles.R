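# Independent oracles and small fixture builders used across the suite.

# Brute-force single-locus Weir-Cockerham (1984) theta for two populations,
# transliterated from the a/b/c variance-component formulas for r = 2.
# gA, gB: dosage vectors (0/1/2, NA = missing) for ONE locus.
wc84_oracle <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  r <- 2
  n1 <- length(gA); n2 <- length(gB)
  p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
  h1 <- mean(gA == 1); h2 <- mean(gB == 1)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, d = a + b + cc, theta = a / (a + b + cc))
}

# geno_matrix from a dosage matrix (samples x sites, 0/1/2/NA), biallelic A/G
gm_from_dosage <- function(d, samples = NULL, chrom = "chr1") {
  n <- nrow(d); L <- ncol(d)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(n))
  sites <- tibble::tibble(chrom = chrom, pos = seq_len(L),
                          id = paste0(chrom, ":", seq_len(L)),
                          ref = "A", alt = "G")
  geno_matrix(samples, sites,
              ifelse(d == 2, 1L, 0L), ifelse(d >= 1, 1L, 0L))
}

# Exact two-sided rank-sum p by exhaustive enumeration of labelings
ranksum_exact_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v <- c(a, b)
  rk <- rank(v)
  u_of <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1, simplify = FALSE)
  us <- vapply(combos, u_of, 0)
  mu <- n1 * n2 / 2
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12))
}

# Procrustes residual (after centring, optimal rotation/reflection + scale)
procrustes_resid <- function(X, Y) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  s <- svd(t(Y) %*% X)
  R <- s$u %*% t(s$v)
  sc <- sum(s$d) / sum(Y^2)
  sqrt(sum((X - sc * Y %*% R)^2) / nrow(X))
}

# Random 3-group matrix with a controlled mix of fixed and variable sites,
# for brute-force comparison of the diagnostic searches.
random_three_group <- function(n_per = 4, L = 20, seed = 1) {
  set.seed(seed)
  groups <- rep(c("g1", "g2", "g3"), each = n_per)
  d <- matrix(NA_integer_, length(groups), L)
  for (l in seq_len(L)) {
    kind <- sample(c("fixed", "free"), 1, prob = c(0.5, 0.5))
    if (kind == "fixed") {
      al <- sample(0:1, 3, replace = TRUE)
      d[, l] <- rep(2L * al, each = n_per)
    } else {
      d[, l] <- sample(0:2, length(groups), replace = TRUE)
    }
  }
  gm <- gm_from_dosage(d)
  pm <- tibble::tibble(sample = gm$samples, pop = gm$samples)
  part <- group_partition(gm$samples, groups)
  list(gm = gm, pm = pm, partition = part)
}

# Brute-force per-group fixed allele (scalar re-derivation)
fixed_allele_oracle <- function(gm, rows, l) {
  a <- c(gm$a1[rows, l], gm$a2[rows, l])
  a <- a[!is.na(a)]
  if (length(a) == 0) return(NA_integer_)
  het <- any(gm$a1[rows, l] != gm$a2[rows, l], na.rm = TRUE)
  if (!het && length(unique(a)) == 1) a[1] else NA_integer_
}

# Brute-force enumeration of all minimal diagnostic site sets (size <= 2)
brute_force_k_sets <- function(gm, pm, partition, min_typed = 1) {
  groups <- unique(partition$group)
  sg <- radpopgen::sample_groups(pm, partition)[gm$samples]
  fx <- sapply(seq_len(n_sites(gm)), function(l) {
    vapply(groups, function(g) {
      rows <- which(sg == g)
      if (sum(!is.na(gm$a1[rows, l])) < min_typed) return(NA_integer_)
      fixed_allele_oracle(gm, rows, l)
    }, 1L)
  })
  singles <- which(apply(fx, 2, function(col)
    !anyNA(col) && length(unique(col)) == length(groups)))
  if (length(singles) > 0) return(lapply(singles, identity))
  out <- list()
  for (i in seq_len(n_sites(gm) - 1)) {
    for (j in (i + 1):n_sites(gm)) {
      if (anyNA(fx[, i]) || anyNA(fx[, j])) next
      pat <- paste(fx[, i], fx[, j])
      if (!anyDuplicated(pat)) out[[length(out) + 1]] <- c(i, j)
    }
  }
  out
}

# Whole-transcript substitute-and-translate oracle for a CDS SNP: rebuild
# the full coding sequence from the generator's gene table, substitute the
# alternate base, translate both with Biostrings, and diff the proteins.
transcript_effect_oracle <- function(genome, chrom, pos, ref, alt) {
  g <- genome$genes
  gi <- which(g$chrom == chrom & g$start <= pos & g$end >= pos)[1]
  cds <- g$cds[[gi]]
  seqchar <- genome$seq[[chrom]]
  get_cds_seq <- function(s) {
    pieces <- mapply(function(a, b) substring(s, a, b), cds$start, cds$end)
    full <- paste(pieces, collapse = "")
    if (g$strand[gi] == "-") {
      full <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(full)))
    }
    full
  }
  stopifnot(substring(seqchar, pos, pos) == ref)
  alt_seq <- seqchar
  substring(alt_seq, pos, pos) <- alt
  p_ref <- as.character(Biostrings::translate(Biostrings::DNAString(get_cds_seq(seqchar)),
                                              if.fuzzy.codon = "X"))
  p_alt <- as.character(Biostrings::translate(Biostrings::DNAString(get_cds_seq(alt_seq)),
                                              if.fuzzy.codon = "X"))
  if (p_ref == p_alt) "synonymous" else "nonsynonymous"
}

# fraction of samples whose cluster labels can be matched one-to-one to
# truth groups (1 = perfect agreement up to relabeling)
label_agreement <- function(cluster, truth) {
  tab <- table(cluster, truth)
  perms <- combinat_perms(seq_len(ncol(tab)))
  best <- 0
  for (p in perms) {
    hit <- sum(tab[cbind(p, seq_len(ncol(tab)))])
    best <- max(best, hit)
  }
  best / length(truth)
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}
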