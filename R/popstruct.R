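#' Genotype principal component analysis
#'
#' EIGENSTRAT-style PCA of the dosage matrix: each biallelic polymorphic
#' site is centred by twice its sample alternate-allele frequency `p` and
#' (by default) scaled by `sqrt(p (1 - p))`; missing calls contribute 0
#' after centring (mean imputation). Coordinates come from the singular
#' value decomposition of the standardised matrix; explained fractions are
#' the normalised squared singular values and sum to 1 over the full rank.
#' The sign of each component is fixed so its largest-magnitude site
#' loading is positive.
#'
#' @param gm A [geno_matrix] with at least 2 samples.
#' @param n_components Number of components to keep (default 10, capped at
#'   the rank).
#' @param scale Scale sites by `sqrt(p(1-p))` (default `TRUE`); `FALSE`
#'   gives plain centred PCA for sensitivity checks.
#' @param verbose Report excluded-site counts.
#' @return Object of class `genotype_pca`: list with `coordinates` (tibble:
#'   `sample`, `PC1` ...), `explained_fraction`, `n_sites_used`.
#' @export
genotype_pca <- function(gm, n_components = 10, scale = TRUE, verbose = FALSE) {
  stopifnot(n_samples(gm) >= 2)
  d <- dosage(gm)
  bi <- is_biallelic(gm)
  if (verbose && any(!bi)) {
    message(sum(!bi), " multiallelic site(s) excluded from PCA")
  }
  n_typed <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(n_typed, 1))
  poly <- bi & n_typed > 0 & p > 0 & p < 1
  if (sum(poly) < 2) stop("fewer than 2 polymorphic biallelic sites")
  x <- d[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(x, 2, 2 * p)
  if (scale) x <- sweep(x, 2, sqrt(p * (1 - p)), "/")
  x[is.na(x)] <- 0
  sv <- svd(x)
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  k <- min(n_components, rank)
  sgn <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  coords <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k, k), 2, sgn, "*")
  colnames(coords) <- paste0("PC", seq_len(k))
  ev <- sv$d^2
  structure(list(
    coordinates = dplyr::bind_cols(tibble::tibble(sample = gm$samples),
                                   tibble::as_tibble(coords)),
    explained_fraction = ev[seq_len(k)] / sum(ev),
    explained_all = ev / sum(ev),
    n_sites_used = sum(poly)), class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("<genotype_pca> %d samples, %d sites; PC1..PC3: %s%%\n",
              nrow(x$coordinates), x$n_sites_used,
              paste(round(100 * utils::head(x$explained_fraction, 3), 1),
                    collapse = " / ")))
  invisible(x)
}

#' Identity-by-state distance matrix
#'
#' `d(i, j) = 1 - (mean shared allele copies) / 2` over sites where both
#' samples are typed. Works for multiallelic sites via multiset overlap of
#' the two allele pairs. Errors if any pair has no co-typed site.
#'
#' @param gm A [geno_matrix] with at least 2 samples.
#' @return Symmetric matrix of class `dist`-compatible numeric with zero
#'   diagonal, dimnames = sample ids.
#' @export
ibs_distance <- function(gm) {
  n <- n_samples(gm)
  stopifnot(n >= 2)
  a1 <- gm$a1; a2 <- gm$a2
  D <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(a1[i, ]) & !is.na(a1[j, ])
      if (!any(ok)) {
        stop("samples '", gm$samples[i], "' and '", gm$samples[j],
             "' share no co-typed site")
      }
      shared <- (a1[i, ok] == a1[j, ok]) + (a2[i, ok] == a2[j, ok])
      D[i, j] <- D[j, i] <- 1 - mean(shared) / 2
    }
  }
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distance matrix and eigendecomposes it
#' (via [stats::cmdscale()]); negative eigenvalues are truncated to zero
#' with a warning, and if fewer than `k` positive eigenvalues exist the
#' returned dimension is reduced with a message.
#'
#' @param dm Symmetric distance matrix with zero diagonal.
#' @param k Number of dimensions requested.
#' @return Tibble with `sample` and `MDS1` ... columns; attribute
#'   `eigenvalues` carries the full spectrum.
#' @export
classical_mds <- function(dm, k = 3) {
  stopifnot(k >= 1, isTRUE(all.equal(dm, t(dm))), all(diag(dm) == 0))
  if (k > nrow(dm) - 1) {
    message("MDS dimension capped at n - 1 = ", nrow(dm) - 1)
    k <- nrow(dm) - 1
  }
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = k, eig = TRUE))
  if (any(fit$eig < -1e-9 * max(abs(fit$eig)))) {
    warning("negative eigenvalues truncated to zero (non-Euclidean distances)")
  }
  pts <- fit$points
  if (ncol(pts) < k) {
    message("MDS dimension reduced to ", ncol(pts),
            " (only that many positive eigenvalues)")
  }
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  out <- dplyr::bind_cols(tibble::tibble(sample = rownames(dm)),
                          tibble::as_tibble(pts))
  attr(out, "eigenvalues") <- fit$eig
  out
}
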