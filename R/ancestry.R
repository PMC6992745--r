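#' Estimate group allele frequencies with a pseudocount
#'
#' Per-group alternate-allele frequencies
#' `f = (alt copies + pseudocount) / (2 * typed + 2 * pseudocount)` at every
#' biallelic site; the default Jeffreys-like pseudocount 0.5 keeps
#' frequencies strictly inside (0, 1), which the ancestry likelihood
#' requires. Sites untyped in any group (or multiallelic) are dropped with a
#' reported count.
#'
#' @param gm A [geno_matrix].
#' @param pm Popmap tibble.
#' @param partition A [group_partition].
#' @param pseudocount Non-negative smoothing constant (default 0.5). A zero
#'   pseudocount errors as soon as any site is fixed within a group.
#' @param verbose Report dropped-site counts.
#' @return Object of class `group_freq`: list with `f` (groups x sites
#'   frequency matrix), `alt_copies`, `typed` (same shape, raw counts for
#'   leave-one-out adjustment), `site_ids`, `site_index` (columns of `gm`
#'   used) and `pseudocount`.
#' @export
estimate_group_frequencies <- function(gm, pm, partition, pseudocount = 0.5,
                                       verbose = FALSE) {
  stopifnot(pseudocount >= 0)
  sg <- sample_groups(pm, partition)[gm$samples]
  groups <- unique(partition$group)
  d <- dosage(gm)
  keep_samp <- !is.na(sg)
  d <- d[keep_samp, , drop = FALSE]
  g <- sg[keep_samp]
  typed <- rowsum((!is.na(d)) * 1L, g)[groups, , drop = FALSE]
  altc <- rowsum(ifelse(is.na(d), 0, d), g)[groups, , drop = FALSE]
  use <- is_biallelic(gm) & colSums(typed > 0) == length(groups)
  if (verbose && any(!use)) {
    message(sum(!use), " site(s) dropped from the reference panel ",
            "(multiallelic or untyped in some group)")
  }
  f <- (altc[, use, drop = FALSE] + pseudocount) /
    (2 * typed[, use, drop = FALSE] + 2 * pseudocount)
  if (any(f <= 0 | f >= 1)) {
    stop("group frequencies touch the boundary; use a pseudocount > 0")
  }
  structure(list(f = f, alt_copies = altc[, use, drop = FALSE],
                 typed = typed[, use, drop = FALSE],
                 site_ids = gm$sites$id[use], site_index = which(use),
                 pseudocount = pseudocount), class = "group_freq")
}

#' Supervised ancestry-fraction estimate for one sample
#'
#' Maximises the binomial mixture log-likelihood
#' `sum_l [g_l log(sum_k q_k f_kl) + (2 - g_l) log(sum_k q_k (1 - f_kl))]`
#' over the probability simplex by expectation-maximisation from a uniform
#' start. Missing genotypes are skipped. If the frequency table is flat
#' (identical across groups at every site) the likelihood is constant: the
#' uniform initialisation is returned, flagged uninformative.
#'
#' @param sample_calls Numeric dosage vector (0/1/2, `NA` missing) aligned
#'   with the sites of `freq_table`.
#' @param freq_table A `group_freq` object.
#' @param tol Stop when the log-likelihood gain drops below this
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 1000).
#' @return Object of class `ancestry_estimate`: list with `q` (named,
#'   sums to 1), `loglik`, `iterations`, `converged`, `uninformative` and
#'   `trace` (per-iteration log-likelihood).
#' @export
estimate_ancestry <- function(sample_calls, freq_table, tol = 1e-6,
                              max_iter = 1000) {
  f <- freq_table$f
  stopifnot(length(sample_calls) == ncol(f))
  ok <- !is.na(sample_calls)
  if (!any(ok)) stop("all calls missing for this sample")
  g <- sample_calls[ok]
  f <- f[, ok, drop = FALSE]
  K <- nrow(f)
  q <- rep(1 / K, K)
  if (all(apply(f, 2, function(col) max(col) - min(col)) < 1e-12)) {
    ll <- sum(g * log(colSums(q * f)) + (2 - g) * log(colSums(q * (1 - f))))
    return(structure(list(q = stats::setNames(q, rownames(f)), loglik = ll,
                          iterations = 0L, converged = TRUE,
                          uninformative = TRUE, trace = ll),
                     class = "ancestry_estimate"))
  }
  Lsites <- length(g)
  fc <- 1 - f
  gr <- 2 - g
  ll_of <- function(q) {
    sum(g * log(as.vector(q %*% f)) + gr * log(as.vector(q %*% fc)))
  }
  ll <- ll_of(q)
  trace <- ll
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    qf <- as.vector(q %*% f)   # site-wise mixture frequencies
    qc <- as.vector(q %*% fc)
    q <- q * as.vector(f %*% (g / qf) + fc %*% (gr / qc)) / (2 * Lsites)
    q <- q / sum(q)
    ll_new <- ll_of(q)
    trace <- c(trace, ll_new)
    if (ll_new - ll < tol) { ll <- ll_new; converged <- TRUE; break }
    ll <- ll_new
  }
  structure(list(q = stats::setNames(q, rownames(f)), loglik = ll,
                 iterations = iter, converged = converged,
                 uninformative = FALSE, trace = trace),
            class = "ancestry_estimate")
}

#' @export
print.ancestry_estimate <- function(x, ...) {
  cat("<ancestry_estimate> q:",
      paste(sprintf("%s=%.3f", names(x$q), x$q), collapse = " "),
      sprintf("(loglik %.2f, %d iter%s)\n", x$loglik, x$iterations,
              if (x$uninformative) ", uninformative" else ""))
  invisible(x)
}

#' Leave-one-out ancestry estimates for every sample
#'
#' Each sample is estimated against group frequencies recomputed with its
#' own genotypes removed from the reference panel (leave-one-out), so panel
#' members are never compared against themselves.
#'
#' @param gm A [geno_matrix].
#' @param pm Popmap tibble.
#' @param partition A [group_partition]; a sample's population group defines
#'   the panel cell its calls are removed from.
#' @inheritParams estimate_ancestry
#' @param pseudocount Passed to [estimate_group_frequencies()].
#' @return Tibble of class `ancestry_table`: `sample`, `sampled_group`, one
#'   `q_<group>` column per group, `loglik`, `iterations`, `uninformative`.
#' @export
estimate_ancestry_all <- function(gm, pm, partition, pseudocount = 0.5,
                                  tol = 1e-6, max_iter = 1000) {
  ft <- estimate_group_frequencies(gm, pm, partition, pseudocount)
  d <- dosage(gm)[, ft$site_index, drop = FALSE]
  sg <- sample_groups(pm, partition)[gm$samples]
  pc <- ft$pseudocount
  out <- purrr::map_dfr(seq_len(n_samples(gm)), function(i) {
    ft_i <- ft
    if (!is.na(sg[i])) {
      g <- sg[i]
      calls <- d[i, ]
      seen <- !is.na(calls)
      ft_i$alt_copies[g, seen] <- ft_i$alt_copies[g, seen] - calls[seen]
      ft_i$typed[g, seen] <- ft_i$typed[g, seen] - 1L
      ft_i$f <- (ft_i$alt_copies + pc) / (2 * ft_i$typed + 2 * pc)
    }
    est <- estimate_ancestry(d[i, ], ft_i, tol = tol, max_iter = max_iter)
    dplyr::bind_cols(
      tibble::tibble(sample = gm$samples[i], sampled_group = unname(sg[i])),
      tibble::as_tibble(as.list(stats::setNames(est$q,
                                                paste0("q_", names(est$q))))),
      tibble::tibble(loglik = est$loglik, iterations = est$iterations,
                     uninformative = est$uninformative))
  })
  class(out) <- c("ancestry_table", class(out))
  out
}

#' Classify samples as pure, admixed or transplant candidates
#'
#' A sample is `pure:<group>` when its largest ancestry fraction reaches
#' `purity_threshold`; a pure sample whose assigned group differs from the
#' group of its sampling location is a `transplant-candidate`; anything else
#' is `admixed`.
#'
#' @param estimates An `ancestry_table` from [estimate_ancestry_all()] (or
#'   any tibble with `sample`, `sampled_group` and `q_<group>` columns).
#' @param purity_threshold Largest-fraction cutoff (default 0.9).
#' @return The input with `assigned_group`, `max_q` and `call` columns.
#' @export
classify_introgression <- function(estimates, purity_threshold = 0.9) {
  qcols <- grep("^q_", names(estimates), value = TRUE)
  qm <- as.matrix(estimates[qcols])
  groups <- sub("^q_", "", qcols)
  top <- max.col(qm, ties.method = "first")
  maxq <- qm[cbind(seq_len(nrow(qm)), top)]
  assigned <- groups[top]
  call <- ifelse(maxq < purity_threshold, "admixed",
                 ifelse(!is.na(estimates$sampled_group) &
                          assigned != estimates$sampled_group,
                        "transplant-candidate", paste0("pure:", assigned)))
  dplyr::mutate(estimates, assigned_group = assigned, max_q = maxq,
                call = call)
}
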