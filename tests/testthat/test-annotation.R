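toy_genome <- function(seed = 51, L = 400) {
  simulate_annotated_genome(synth_scenario(L = L, seed = seed))
}

write_toy_genome <- function(genome, dir) {
  fa <- file.path(dir, "g.fa"); gff <- file.path(dir, "g.gff3")
  write_genome(genome, fa, gff)
  list(fasta = fa, gff = gff)
}

test_that("index round-trips: every CDS base queried returns CDS", {
  genome <- toy_genome()
  dir <- withr::local_tempdir()
  p <- write_toy_genome(genome, dir)
  index <- build_annotation_index(p$gff)
  g1 <- genome$genes[1, ]
  cds_pos <- unlist(purrr::map2(g1$cds[[1]]$start, g1$cds[[1]]$end, seq))
  expect_true(all(classify_site(index, rep(g1$chrom, length(cds_pos)),
                                cds_pos) == "CDS"))
  # UTR and intron positions of the same gene
  expect_equal(classify_site(index, g1$chrom, g1$start), "UTR")
  intron_pos <- g1$cds[[1]]$end[1] + 1
  expect_equal(classify_site(index, g1$chrom, intron_pos), "intron")
  expect_equal(classify_site(index, g1$chrom, g1$end + 30L), "noncoding")
})

test_that("region classification matches the generator truth exactly", {
  genome <- toy_genome(seed = 52)
  dir <- withr::local_tempdir()
  p <- write_toy_genome(genome, dir)
  index <- build_annotation_index(p$gff)
  truth <- genome$snp_truth
  got <- classify_site(index, truth$chrom, truth$pos)
  expect_identical(got, truth$category)
})

test_that("codon effects: canonical synonymous / stop / minus-strand cases", {
  # hand-built single-gene genome, plus strand:  ATG GGT TGG TAA
  seqs <- c(chr1 = paste0(strrep("T", 10), "ATGGGTTGGTAA", strrep("T", 10)))
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "t.fa"); gff <- file.path(dir, "t.gff3")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t11\t22\t.\t+\t.\tID=g1",
               "chr1\tx\tmRNA\t11\t22\t.\t+\t.\tID=g1.t1;Parent=g1",
               "chr1\tx\texon\t11\t22\t.\t+\t.\tParent=g1.t1",
               "chr1\tx\tCDS\t11\t22\t.\t+\t0\tParent=g1.t1"), gff)
  index <- build_annotation_index(gff)
  fasta <- read_genome_fasta(fa)
  # GGT -> GGC at codon position 3: synonymous (G == G)
  syn <- amino_acid_effect(index, fasta, "chr1", 16, "T", "C")
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$ref_residue, "G")
  # TGG -> TGA: W -> stop, nonsynonymous with stop-gain sub-label
  stopg <- amino_acid_effect(index, fasta, "chr1", 19, "G", "A")
  expect_equal(stopg$effect, "nonsynonymous")
  expect_equal(stopg$sub_label, "stop-gain")
  # reference-mismatch sanity check
  expect_error(amino_acid_effect(index, fasta, "chr1", 16, "A", "C"),
               "reference mismatch")

  # minus strand: genomic CAT at 11..13 reads as ATG; genomic C->T gives
  # ATG -> ATA (M -> I), nonsynonymous
  seqs2 <- c(chr1 = paste0(strrep("G", 10), "TTACCACAT", strrep("G", 10)))
  fa2 <- file.path(dir, "m.fa"); gff2 <- file.path(dir, "m.gff3")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs2), fa2)
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t11\t19\t.\t-\t.\tID=g2",
               "chr1\tx\tmRNA\t11\t19\t.\t-\t.\tID=g2.t1;Parent=g2",
               "chr1\tx\texon\t11\t19\t.\t-\t.\tParent=g2.t1",
               "chr1\tx\tCDS\t11\t19\t.\t-\t0\tParent=g2.t1"), gff2)
  index2 <- build_annotation_index(gff2)
  fasta2 <- read_genome_fasta(fa2)
  minus <- amino_acid_effect(index2, fasta2, "chr1", 17, "C", "T")
  expect_equal(minus$ref_codon, "ATG")
  expect_equal(minus$alt_codon, "ATA")
  expect_equal(minus$ref_residue, "M")
  expect_equal(minus$alt_residue, "I")
  expect_equal(minus$effect, "nonsynonymous")
})

test_that("effects agree with the whole-transcript translate oracle on every
           CDS SNP of the toy genome", {
  genome <- toy_genome(seed = 53, L = 300)
  dir <- withr::local_tempdir()
  p <- write_toy_genome(genome, dir)
  index <- build_annotation_index(p$gff)
  fasta <- read_genome_fasta(p$fasta)
  cds_snps <- genome$snp_truth[genome$snp_truth$category == "CDS", ]
  expect_gt(nrow(cds_snps), 10)
  for (i in seq_len(nrow(cds_snps))) {
    s <- cds_snps[i, ]
    got <- amino_acid_effect(index, fasta, s$chrom, s$pos, s$ref, s$alt)
    orc <- transcript_effect_oracle(genome, s$chrom, s$pos, s$ref, s$alt)
    expect_equal(got$effect, orc)
    expect_equal(got$effect, s$effect)  # generator truth agrees too
  }
  expect_true(any(cds_snps$effect == "synonymous"))
  expect_true(any(cds_snps$effect == "nonsynonymous"))
})

test_that("frame-broken transcripts are excluded from effect calling", {
  dir <- withr::local_tempdir()
  seqs <- c(chr1 = strrep("ACGT", 20))
  fa <- file.path(dir, "f.fa"); gff <- file.path(dir, "f.gff3")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t5\t24\t.\t+\t.\tID=g1",
               "chr1\tx\tmRNA\t5\t24\t.\t+\t.\tID=g1.t1;Parent=g1",
               "chr1\tx\texon\t5\t24\t.\t+\t.\tParent=g1.t1",
               "chr1\tx\tCDS\t5\t24\t.\t+\t0\tParent=g1.t1"), gff)  # len 20
  expect_message(index <- build_annotation_index(gff), "multiple of 3")
  expect_false(index$transcripts$frame_ok)
  fasta <- read_genome_fasta(fa)
  eff <- amino_acid_effect(index, fasta, "chr1", 10,
                           substring(seqs[[1]], 10, 10), "A")
  expect_true(is.na(eff$effect))
})

test_that("summaries partition the marker set and count substitutions", {
  genome <- toy_genome(seed = 54, L = 250)
  dir <- withr::local_tempdir()
  p <- write_toy_genome(genome, dir)
  index <- build_annotation_index(p$gff)
  fasta <- read_genome_fasta(p$fasta)
  truth <- genome$snp_truth
  summ <- summarize_regions(truth, index, fasta)
  n <- function(cat) summ$counts$n[summ$counts$category == cat]
  expect_equal(n("CDS") + n("UTR") + n("intron") + n("noncoding"), n("total"))
  expect_equal(n("total"), nrow(truth))
  expect_equal(n("gene_region"), sum(truth$category != "noncoding"))
  expect_equal(n("nonsynonymous"),
               sum(truth$effect == "nonsynonymous", na.rm = TRUE))
  # per-category counts equal generator truth
  for (cat in c("CDS", "UTR", "intron", "noncoding")) {
    expect_equal(n(cat), sum(truth$category == cat))
  }
  # empty marker set: all zeros
  empty <- summarize_regions(truth[0, ], index, fasta)
  expect_true(all(empty$counts$n == 0))
})
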