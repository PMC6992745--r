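#' Write a synthetic dataset to a directory
#'
#' Emits everything as plain text: `genotypes.vcf`, `popmap.tsv`,
#' `partition.tsv`, `genome.fa`, `genome.gff3` and tab-separated truth
#' tables (`truth_sites.tsv`, `truth_ancestry.tsv`, `truth_replicates.tsv`,
#' `truth_snp_annotation.tsv`, `truth_group_freq.tsv`). All are re-readable
#' with the package's readers.
#'
#' @param ds A `synth_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_vcf(ds$gm, p("genotypes.vcf"))
  write_popmap(ds$popmap, p("popmap.tsv"))
  writeLines(paste(ds$partition$pop, ds$partition$group, sep = "\t"),
             p("partition.tsv"))
  write_genome(ds$genome, p("genome.fa"), p("genome.gff3"))
  readr::write_tsv(ds$truth$sites, p("truth_sites.tsv"))
  readr::write_tsv(ds$truth$ancestry, p("truth_ancestry.tsv"))
  readr::write_tsv(ds$truth$replicates, p("truth_replicates.tsv"))
  readr::write_tsv(ds$truth$snp_annotation, p("truth_snp_annotation.tsv"))
  readr::write_tsv(tibble::as_tibble(t(ds$truth$group_freq)) |>
                     dplyr::mutate(id = ds$gm$sites$id, .before = 1),
                   p("truth_group_freq.tsv"))
  invisible(list(vcf = p("genotypes.vcf"), popmap = p("popmap.tsv"),
                 partition = p("partition.tsv"), fasta = p("genome.fa"),
                 gff = p("genome.gff3")))
}
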