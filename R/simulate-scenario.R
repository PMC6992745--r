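#' Describe a synthetic three-group divergence scenario
#'
#' Fixes the study design the simulator emulates: three groups related by the
#' topology `((west, kyushu), east)` with Balding-Nichols drift on each
#' branch, optional accession-level substructure within groups, planted
#' fixed-difference diagnostic sites, admixed/transplanted individuals,
#' technical replicates, missing genotypes, and a small annotated reference
#' genome. Each sample is its own population in the popmap (one accession per
#' collection site, as in per-sample RAD-Seq designs).
#'
#' @param n_per_group Named integer vector, samples per group
#'   (`east`, `west`, `kyushu`).
#' @param L Number of SNP sites.
#' @param F_branch Named drift parameters in `[0, 1)` for the four branches:
#'   root to `east`, root to the west/kyushu ancestor (`wk_anc`), and the
#'   ancestor to `west` and `kyushu`. `0` means no drift.
#' @param F_within Named per-group accession-level drift: each sample's own
#'   site frequencies are a Balding-Nichols draw around the group frequency.
#'   `0` (default) means samples are i.i.d. draws from the group frequency;
#'   larger values model differentiated local demes and raise
#'   accession-pairwise fixation indices.
#' @param ancestral_freq_range Interval within `(0, 1)` for the ancestral
#'   alternate-allele frequency, drawn uniformly per site.
#' @param n_fixed_diagnostic Named counts of sites overwritten as fixed
#'   differences: `root` = east vs west+kyushu split, `wk` = west vs kyushu
#'   split (these also fix the east allele so that site pairs can jointly
#'   separate all three groups).
#' @param n_triallelic_diagnostic Number of triallelic sites where each group
#'   is fixed for a different allele (single-site three-group markers).
#' @param hybrids Tibble with columns `sample`, `parent1`, `parent2`,
#'   `alpha` (ancestry fraction of `parent1`), `sampled_group` (group of the
#'   collection area); or `NULL`.
#' @param missing_rate Per-call missingness probability.
#' @param replicate_of Sample ids to duplicate as technical replicates
#'   (`<id>_rep`).
#' @param replicate_error Per-allele-copy flip probability for replicates.
#' @param prevent_chance_fixation Break (by one heterozygote) any unplanted
#'   site that comes out as a fixed difference for the root or west/kyushu
#'   split, so planted-marker recall and precision are exactly testable.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list of class `synth_scenario`.
#' @export
synth_scenario <- function(n_per_group = c(east = 20, west = 20, kyushu = 20),
                           L = 2000,
                           F_branch = c(east = 0.40, wk_anc = 0.22,
                                        west = 0.06, kyushu = 0.35),
                           F_within = c(east = 0, west = 0, kyushu = 0),
                           ancestral_freq_range = c(0.1, 0.9),
                           n_fixed_diagnostic = c(root = 12, wk = 6),
                           n_triallelic_diagnostic = 0,
                           hybrids = NULL,
                           missing_rate = 0,
                           replicate_of = character(),
                           replicate_error = 0,
                           prevent_chance_fixation = TRUE,
                           seed = 1) {
  grp <- c("east", "west", "kyushu")
  stopifnot(all(grp %in% names(n_per_group)),
            all(c("east", "wk_anc", "west", "kyushu") %in% names(F_branch)),
            all(grp %in% names(F_within)))
  if (any(F_branch < 0 | F_branch >= 1) || any(F_within < 0 | F_within >= 1)) {
    stop("drift parameters must lie in [0, 1)")
  }
  stopifnot(length(ancestral_freq_range) == 2,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] <= ancestral_freq_range[2],
            missing_rate >= 0, missing_rate <= 1,
            replicate_error >= 0, replicate_error <= 1)
  nfd <- c(root = 0, wk = 0)
  nfd[names(n_fixed_diagnostic)] <- n_fixed_diagnostic
  if (sum(nfd) + n_triallelic_diagnostic > L) {
    stop("more planted diagnostic sites than sites (L)")
  }
  if (!is.null(hybrids)) {
    hybrids <- tibble::as_tibble(hybrids)
    if (!"sampled_group" %in% names(hybrids)) {
      hybrids$sampled_group <- hybrids$parent2
    }
    stopifnot(all(c("sample", "parent1", "parent2", "alpha") %in% names(hybrids)),
              all(hybrids$alpha > 0 & hybrids$alpha < 1 |
                    hybrids$alpha %in% c(0, 1)),
              all(hybrids$parent1 %in% grp), all(hybrids$parent2 %in% grp),
              all(hybrids$sampled_group %in% grp))
  }
  structure(list(
    n_per_group = n_per_group[grp], L = as.integer(L),
    F_branch = F_branch, F_within = F_within[grp],
    ancestral_freq_range = ancestral_freq_range,
    n_fixed_diagnostic = nfd,
    n_triallelic_diagnostic = as.integer(n_triallelic_diagnostic),
    hybrids = hybrids, missing_rate = missing_rate,
    replicate_of = replicate_of, replicate_error = replicate_error,
    prevent_chance_fixation = isTRUE(prevent_chance_fixation),
    seed = as.integer(seed)), class = "synth_scenario")
}

#' The firefly preset scenario
#'
#' Three groups with drift magnitudes ordered as in the empirical system
#' (east most diverged; west and kyushu closest), strong accession-level
#' substructure with the east group least diverse, planted diagnostic sites
#' for both splits, one transplant per misplaced direction, one 65/35
#' kyushu-by-west admixed individual, technical replicates and missing data.
#'
#' @param seed Integer seed.
#' @param L Number of sites (default 2000).
#' @param n_per_group Samples per group (default 20 each).
#' @return A `synth_scenario`.
#' @export
firefly_scenario <- function(seed = 1, L = 2000,
                             n_per_group = c(east = 20, west = 20, kyushu = 20)) {
  synth_scenario(
    n_per_group = n_per_group, L = L,
    F_within = c(east = 0.72, west = 0.82, kyushu = 0.82),
    n_fixed_diagnostic = c(root = 12, wk = 6),
    hybrids = tibble::tibble(
      sample = c("hyb_wk65", "transplant_w", "transplant_e"),
      parent1 = c("kyushu", "west", "east"),
      parent2 = c("west", "west", "east"),
      alpha = c(0.65, 1, 1),
      sampled_group = c("west", "east", "west")),
    missing_rate = 0.03,
    replicate_of = c("east01", "west01"),
    replicate_error = 0.002,
    seed = seed)
}
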