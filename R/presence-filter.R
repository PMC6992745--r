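#' Stacks-style locus presence filter
#'
#' Retains a site iff at least `min_pops` populations are "present" at it,
#' where a population is present when it has at least one typed sample and
#' the typed fraction of its samples is `>= min_sample_fraction`. With one
#' population per sample and `min_sample_fraction = 0` this reduces to
#' "typed in at least `min_pops` samples" — the configuration used when the
#' `-p` option is set to half of the samples in a per-sample popmap.
#'
#' @param gm A [geno_matrix].
#' @param pm Popmap tibble covering every sample of `gm`.
#' @param min_pops Minimum number of present populations (default: half the
#'   number of populations, rounded up).
#' @param min_sample_fraction Typed-sample fraction required for a population
#'   to count as present (default 0, the Stacks `-r` analogue default).
#' @param verbose Report the dropped-site count.
#' @return A filtered [geno_matrix]; site order preserved.
#' @export
filter_by_presence <- function(gm, pm, min_pops = NULL,
                               min_sample_fraction = 0, verbose = TRUE) {
  pops <- pm$pop[match(gm$samples, pm$sample)]
  if (anyNA(pops)) stop("popmap does not cover all samples")
  n_pops <- length(unique(pops))
  if (is.null(min_pops)) min_pops <- ceiling(n_pops / 2)
  stopifnot(min_pops <= n_pops,
            min_sample_fraction >= 0, min_sample_fraction <= 1)
  if (n_sites(gm) == 0) return(gm)
  typed <- rowsum((!is.na(gm$a1)) * 1L, group = pops)     # pops x sites
  size <- as.vector(table(pops)[rownames(typed)])
  present <- typed >= 1L & typed >= min_sample_fraction * size
  keep <- colSums(present) >= min_pops
  if (verbose && any(!keep)) {
    message(sum(!keep), " site(s) dropped by presence filter (min_pops = ",
            min_pops, ", min_sample_fraction = ", min_sample_fraction, ")")
  }
  subset_geno(gm, sites = keep)
}
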