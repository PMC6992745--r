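#' Genotype matrix
#'
#' The central container of the package: diploid genotype calls for a set of
#' samples at a set of SNP sites. Calls are stored as two allele-index
#' matrices (`a1 <= a2`, so phase is discarded: `0/1` and `1/0` are the same
#' call), with `NA` for missing genotypes. Site metadata lives in a tibble
#' with 1-based VCF coordinates.
#'
#' @param samples Character vector of unique sample identifiers.
#' @param sites Tibble with columns `chrom`, `pos` (1-based), `id`, `ref`,
#'   `alt` (comma-separated alternate alleles).
#' @param a1,a2 Integer matrices (`samples` x `sites`) of allele indices
#'   (0 = reference), `NA` where the call is missing. `a1 <= a2` cell-wise.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(samples, sites, a1, a2) {
  samples <- as.character(samples)
  stopifnot(!anyDuplicated(samples))
  sites <- tibble::as_tibble(sites)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(sites))) {
    stop("sites must have columns: ", paste(need, collapse = ", "))
  }
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == c(length(samples), nrow(sites))) ||
      !all(dim(a2) == dim(a1))) {
    stop("call matrices must be n_samples x n_sites")
  }
  if (any(is.na(a1) != is.na(a2))) stop("a1/a2 missingness must agree")
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }
  n_alleles <- 1L + ifelse(sites$alt == "" | is.na(sites$alt), 0L,
                           lengths(strsplit(sites$alt, ",", fixed = TRUE)))
  mx <- suppressWarnings(apply(a2, 2, max, na.rm = TRUE))
  mx[!is.finite(mx)] <- 0L
  if (any(mx >= n_alleles)) stop("allele index out of range for site alleles")
  dimnames(a1) <- dimnames(a2) <- list(samples, sites$id)
  structure(list(samples = samples, sites = sites, a1 = a1, a2 = a2),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d sites (%d biallelic, %.1f%% missing)\n",
              n_samples(x), n_sites(x), sum(is_biallelic(x)),
              100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @rdname geno_matrix
#' @param gm A `geno_matrix`.
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname geno_matrix
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Which sites are biallelic
#' @param gm A `geno_matrix`.
#' @return Logical vector over sites.
#' @export
is_biallelic <- function(gm) {
  !grepl(",", gm$sites$alt, fixed = TRUE) & gm$sites$alt != ""
}

#' Alternate-allele dosage matrix
#'
#' Counts of alternate-allele copies in `{0, 1, 2}` for biallelic sites;
#' multiallelic columns and missing calls are `NA`.
#'
#' @param gm A `geno_matrix`.
#' @return Numeric matrix, samples x sites.
#' @export
dosage <- function(gm) {
  d <- gm$a1 + gm$a2
  d[, !is_biallelic(gm)] <- NA_integer_
  storage.mode(d) <- "double"
  d
}

#' Subset a genotype matrix
#'
#' @param gm A `geno_matrix`.
#' @param samples Sample names or index vector (default all).
#' @param sites Site index or logical vector (default all).
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(gm, samples = NULL, sites = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(gm)) else samples
  if (is.character(si)) si <- match(si, gm$samples)
  if (anyNA(si)) stop("unknown sample in subset")
  li <- if (is.null(sites)) seq_len(n_sites(gm)) else sites
  geno_matrix(gm$samples[si], gm$sites[li, , drop = FALSE],
              gm$a1[si, li, drop = FALSE], gm$a2[si, li, drop = FALSE])
}

# genotype call strings ("0/1", "./.") for writing
format_calls <- function(gm) {
  g <- matrix("./.", n_samples(gm), n_sites(gm))
  ok <- !is.na(gm$a1)
  g[ok] <- paste0(gm$a1[ok], "/", gm$a2[ok])
  g
}

# nucleotide string for allele index k (0 = ref) at each given site row;
# a single site row is recycled across idx
allele_string <- function(sites, idx) {
  alleles <- purrr::map2(sites$ref, sites$alt, function(r, a) {
    c(r, strsplit(a, ",", fixed = TRUE)[[1]])
  })
  if (nrow(sites) == 1 && length(idx) > 1) {
    alleles <- rep(alleles, length(idx))
  }
  out <- rep(NA_character_, length(idx))
  ok <- !is.na(idx)
  out[ok] <- purrr::map2_chr(alleles[ok], idx[ok] + 1L, ~ .x[.y])
  out
}
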