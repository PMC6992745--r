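---
title: "Methods: population structure and diagnostic markers from RAD-Seq SNPs"
author: "radpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure and diagnostic markers from RAD-Seq SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpopgen)
```

## Scope and model

`radpopgen` analyses diploid SNP genotypes of hierarchically structured
populations, the typical downstream situation of a reduced-representation
(RAD-Seq) study of a species split into a few geographic groups — here
modelled after the Japanese firefly system with three groups on the
topology `((west, kyushu), east)`. The pipeline starts at a VCF plus a
Stacks-style popmap; read QC, alignment and genotyping are upstream and out
of scope. Five analyses are provided behind one container, the
`geno_matrix`:

1. a Stacks-style presence filter,
2. genotype PCA and identity-by-state classical MDS,
3. pairwise Weir–Cockerham fixation indices at the group and accession
   level, with rank-sum comparisons of within-group distributions,
4. supervised ancestry-fraction estimation per sample, and
5. fixed-difference diagnostic marker discovery with region and
   amino-acid-effect annotation.

All user-facing results are tibbles (with `tidy()`, `glance()` and
`autoplot()` methods), so they compose with dplyr/ggplot2 workflows.

## Genotype container and presence filter

Genotypes are stored as two allele-index matrices with `NA` for missing
calls; phase is discarded (`0/1` and `1/0` are the same call), and
coordinates are 1-based VCF coordinates externally. Multiallelic sites are
kept in the matrix but excluded from biallelic-only statistics (PCA,
fixation indices, ancestry) with a reported count; the diagnostic-marker
search accepts them, because a single triallelic site can in principle
label three groups where no biallelic site can.

The presence filter retains a site when at least `min_pops` populations
have a typed fraction of samples `>= min_sample_fraction` (default 0, i.e.
one typed sample makes a population present — the Stacks `-r` analogue
default). With one population per sample, `min_pops = n/2` reduces to
"typed in at least half the samples", the configuration of the study this
package emulates, which used `-p 26` with 52 per-sample populations. The
filter is idempotent and monotone in `min_pops`, both tested.

## PCA and MDS

PCA uses EIGENSTRAT-style standardisation: each biallelic polymorphic site
is centred by `2p` and scaled by `sqrt(p(1-p))`, with `p` the sample
alternate-allele frequency; missing calls contribute 0 after centring
(mean imputation — a pairwise-complete alternative was rejected because it
does not guarantee a positive semi-definite covariance). Monomorphic sites
are dropped. Coordinates come from the SVD; explained fractions are the
normalised squared singular values and sum to one over the full rank. Each
component's sign is fixed so that its largest-magnitude site loading is
positive, making plots reproducible across platforms.

MDS is Torgerson's classical scaling (via `stats::cmdscale`) of the
identity-by-state distance `1 - (mean shared allele copies)/2` over
co-typed sites. The study this package emulates did not state its MDS
input distance; IBS is the assumption, documented here. Negative
eigenvalues (IBS matrices need not be Euclidean) are truncated to zero
with a warning.

## Fixation indices

Between groups the package computes Weir & Cockerham's (1984) theta from
the per-locus variance components for two populations, combined as a
ratio of sums over loci (never an average of per-locus ratios). Loci
monomorphic across both sets or untyped in either are skipped and counted;
negative per-locus components are retained. The upstream study used
Stacks' AMOVA-based estimator; numerical identity with its published
values is not promised (and is impossible without the original
accessions) — Weir–Cockerham was chosen because it is fully specified in
the literature and testable against an independently coded oracle, which
the suite does on random single-locus instances to 1e-12.

Accession-level comparisons (every pair of accessions within a group,
each accession a single diploid) cannot use the diploid WC84 components:
the within-population term carries a factor `1/(n̄-1)` that is undefined at
`n̄ = 1`. For these pairs the package uses a one-way analysis of variance
on the four allele copies (two per diploid) with the same
ratio-of-sums combination — a Weir–Cockerham-style moment estimator that
reproduces the expected limits exactly (fixed opposite homozygotes give 1,
identical heterozygotes give a non-positive value). Within-group
distributions are compared with a two-sided Mann–Whitney rank-sum test
(midrank ties, normal approximation with tie and continuity correction)
at the 5% level; the test identity behind the emulated study's figure was
unstated, and rank-sum is the documented assumption.

## Supervised ancestry estimation

Group allele frequencies are estimated with a Jeffreys-like pseudocount
(default 0.5) to keep them off the boundary:
`f = (alt + 0.5) / (2n + 1)`. Each sample's ancestry vector `q` over the
K groups maximises the binomial mixture log-likelihood
`sum_l [g log(qf) + (2-g) log(q(1-f))]` by EM from a uniform start;
the log-likelihood is non-decreasing at every iteration (asserted in
tests), iteration stops when the gain drops below `1e-6` or after 1000
iterations. Samples in the reference panel are estimated leave-one-out:
their own calls are subtracted from the panel counts first. A flat
frequency table (identical across groups) leaves the likelihood constant;
the uniform start is returned, flagged uninformative.

Supervised estimation — rather than unsupervised admixture with K
selection — is a deliberate choice: the number of groups is resolved by
the structure analyses, so fixing the source frequencies answers the same
question with a testable likelihood. A sample is `pure` when its largest
fraction reaches the purity threshold (default 0.9, mirroring the ">90%"
convention of the emulated study), a `transplant-candidate` when pure for
a group other than its sampling location, `admixed` otherwise.

At desk scale the supervised estimates carry a known few-percent
absorption effect: with a panel of ~20 diploids and ~2000 sites, panel
frequency noise lets a close sister group claim several percent of a pure
member's ancestry, so the own-group fraction of panel members floors
around 0.88 rather than approaching 1 (the emulated study used 435,165
RAD loci, where this vanishes). The parameter-recovery tests therefore
assert a ±0.05 band on mixture fractions and a 0.85/0.95 min/mean band on
leave-one-out purity.

## Diagnostic markers

A site is diagnostic for a two-group partition when both groups have at
least `min_typed_per_group` (default 3) typed samples, every typed
genotype in each group is homozygous for one allele, and the two alleles
differ — strict fixation, because the markers are meant for unambiguous
assignment. A relaxed frequency-differential mode was considered and left
out of the default path. For three groups the search first looks for
single sites whose per-group fixed alleles are pairwise distinct (only
possible at multiallelic sites, by pigeonhole), then exhaustively searches
site pairs whose group-to-allele-tuple map is injective; all
minimal-cardinality solutions are reported, ordered by position — no
arbitrary single pick. Known replicates and samples not classified pure by
the ancestry stage are excluded from the pipeline's search via the sample
blacklist.

## Annotation

GFF3 gene models are indexed with UTRs inferred as exon-minus-CDS when not
explicit and introns as within-transcript gaps. Overlaps resolve by the
precedence CDS > UTR > intron (the emulated study is silent on this;
the choice is configurable in the index structure), and a SNP is CDS if it
is CDS in any transcript. Transcripts whose CDS length is not a multiple
of three are excluded from effect calling. Effects use the standard
genetic code on the codon located through the transcript's ordered CDS
segments, reverse-complementing on the minus strand; stop gain/loss counts
as nonsynonymous with a distinguishing sub-label. Every effect call is
cross-checked in the tests against a whole-transcript
substitute-and-translate oracle.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the statistical
structure the analyses assume, not raw reads:

* **Divergence.** Ancestral frequencies are uniform on (0.1, 0.9); group
  frequencies follow Balding–Nichols draws along `((west, kyushu), east)`
  with branch drifts `F`. `F = 0` is the exact no-drift limit. The
  defaults (`east` 0.40, ancestor 0.22, `west` 0.06, `kyushu` 0.35) were
  calibrated once so the realized pairwise fixation indices approximate the
  magnitudes of the emulated study (≈0.30/0.44/0.19 for east–west,
  east–kyushu, west–kyushu); a strict bifurcating drift tree cannot fully
  reproduce that study's east–kyushu asymmetry while holding west–kyushu
  at 0.2, which is acceptable because only the ordering is asserted.
* **Accession substructure.** Each sample can receive its own
  Balding–Nichols draw around its group frequency (`F_within`), modelling
  accessions collected from differentiated local demes. This is the
  diversity knob: smaller `F_within` means accessions within the group
  resemble each other and the within-group pairwise fixation index drops.
  (Narrowing the ancestral frequency range does not move this statistic:
  numerator and denominator of a ratio-of-sums estimator both scale with
  `p(1-p)`.) The firefly preset gives the east analogue the smallest
  `F_within`, producing the "lowest diversity" rank-sum signature.
* **Planted truth.** Diagnostic sites are overwritten as fixed differences
  (rather than awaited by chance) and recorded, so recall and precision
  are exactly testable; sites that become fixed differences by chance are
  broken with a single heterozygote. West–kyushu planted sites also fix
  the east allele so that site pairs can jointly separate all three
  groups.
* **Hybrids, transplants, replicates, missingness.** Hybrids draw
  genotypes from the site-wise mixture `alpha f1 + (1-alpha) f2`;
  `alpha = 1` is a transplant. Technical replicates copy a sample with a
  per-allele-copy flip probability (genotyping noise); missingness is
  uniform per call and applied last. Everything is reproducible from one
  seed.
* **Toy genome.** Two contigs sized to the site count carry ≥3 gene models
  on both strands, each with UTR/CDS/intron structure; SNPs are placed
  with known category (~10% CDS, 5% UTR, 10% intron) and, for CDS SNPs,
  an alternate allele chosen to produce a known synonymous or
  nonsynonymous change.

What the generator does **not** emulate: linkage disequilibrium, allele
dropout and depth-dependent genotyping error, selection, and continuous
isolation-by-distance. Passing tests therefore demonstrate correctness of
the estimators and searches under the stated generative model, not
robustness to every artefact of real RAD-Seq data.

## Problem sizes and numerics

The test and acceptance workloads use desk-scale designs chosen to keep
the statistical claims sharp: 20–30 diploids per group and 1500–5000 sites
for calibration and recovery checks, 2000 sites for ancestry recovery, a
few hundred sites for pipeline round-trips. Calibration asserts
`|theta - F| < 0.03` at `F ∈ {0.05, 0.2, 0.5}` (n = 30/group, L = 5000);
ancestry asserts ±0.05 on `alpha ∈ {0, 0.25, 0.5, 0.65, 1}`. EM tolerance
is `1e-6` log-likelihood units; PCA rank is cut at a relative singular
value of `1e-12`; MDS truncates negative eigenvalues at zero. Ties in the
rank-sum test use midranks with the standard tie correction. Degenerate
inputs have defined behaviour throughout: empty filter results are legal,
all-monomorphic matrices error in PCA, sample pairs with no co-typed site
error in the IBS distance, and a zero pseudocount errors as soon as a
group is fixed at a site.

## Known limitations

* The fixation-index values are Weir–Cockerham theta, not Stacks' AMOVA
  values; orderings agree, magnitudes can differ.
* Supervised ancestry inherits the panel-noise absorption described above;
  fractions for very close source groups are a few percent conservative.
* The annotation module handles one level of transcript nesting
  (gene → mRNA → exon/CDS) and the standard genetic code only.
* The diagnostic search's strict-fixation rule is sensitive to genotyping
  errors in large samples; the blacklist mechanism (replicates, non-pure
  samples) is the intended mitigation.
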