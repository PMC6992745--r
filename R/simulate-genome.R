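#' Simulate an annotated toy reference genome with placed SNPs
#'
#' Builds a small multi-contig genome with gene models on both strands (each
#' with UTR, multi-exon CDS and introns), then places `scenario$L` SNP
#' positions with known region category (CDS / UTR / intron / noncoding) and,
#' for CDS SNPs, a synonymous or nonsynonymous alternate allele chosen by
#' construction from the standard genetic code.
#'
#' @param scenario A [synth_scenario].
#' @return A list of class `synth_genome` with elements `seq` (named
#'   character vector of contig sequences), `genes` (gene-model table),
#'   `gff` (GFF3 feature tibble) and `snp_truth` (placed-SNP truth tibble
#'   with columns `chrom`, `pos`, `ref`, `alt`, `category`, `effect`,
#'   `gene`).
#' @export
simulate_annotated_genome <- function(scenario) {
  set.seed((scenario$seed %% 100000L) * 13L + 7L)
  L <- scenario$L
  total_len <- max(4000L, 4L * L)
  contig_len <- c(chr1 = ceiling(0.6 * total_len),
                  chr2 = total_len - ceiling(0.6 * total_len))
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(contig_len, function(n)
    paste(sample(bases, n, replace = TRUE), collapse = ""), "")

  # gene template (span 290): 30 UTR | 45 CDS | 40 intron | 60 CDS |
  # 40 intron | 45 CDS | 30 UTR; CDS total 150 (divisible by 3)
  seg_len <- c(30L, 45L, 40L, 60L, 40L, 45L, 30L)
  span <- sum(seg_len)
  n_genes <- max(3L, min(24L, ceiling(L / 350)))
  cursor <- c(chr1 = 101L, chr2 = 101L)
  genes <- list()
  for (i in seq_len(n_genes)) {
    chrom <- if (i %% 2L == 1L) "chr1" else "chr2"
    if (cursor[chrom] + span + 100L > contig_len[chrom]) {
      chrom <- setdiff(names(contig_len), chrom)
      if (cursor[chrom] + span + 100L > contig_len[chrom]) break
    }
    start <- cursor[chrom]
    cursor[chrom] <- cursor[chrom] + span + 60L
    off <- cumsum(c(0L, seg_len))
    seg_start <- start + off[1:7]
    seg_end <- start + off[2:8] - 1L
    genes[[i]] <- tibble::tibble(
      gene = sprintf("gene%02d", i), chrom = chrom,
      start = start, end = start + span - 1L,
      strand = if (i %% 2L == 1L) "+" else "-",
      utr = list(tibble::tibble(start = seg_start[c(1, 7)],
                                end = seg_end[c(1, 7)])),
      cds = list(tibble::tibble(start = seg_start[c(2, 4, 6)],
                                end = seg_end[c(2, 4, 6)])),
      exons = list(tibble::tibble(start = seg_start[c(1, 4, 6)],
                                  end = seg_end[c(2, 4, 7)])))
  }
  genes <- dplyr::bind_rows(genes)
  if (nrow(genes) < 3) stop("genome too small to host 3 gene models")

  pos_of <- function(col) {
    dplyr::bind_rows(purrr::map2(genes[[col]], genes$chrom,
                                 ~ tibble::tibble(chrom = .y,
                                                  pos = unlist(purrr::map2(.x$start, .x$end, seq)))))
  }
  cds_pos <- pos_of("cds")
  utr_pos <- pos_of("utr")
  exon_pos <- pos_of("exons")
  gene_pos <- dplyr::bind_rows(purrr::pmap(genes[c("chrom", "start", "end")],
    function(chrom, start, end) tibble::tibble(chrom = chrom, pos = seq(start, end))))
  intron_pos <- dplyr::anti_join(gene_pos, exon_pos, by = c("chrom", "pos"))
  all_pos <- dplyr::bind_rows(purrr::imap(contig_len, function(n, nm)
    tibble::tibble(chrom = nm, pos = seq_len(n))))
  nonc_pos <- dplyr::anti_join(all_pos, gene_pos, by = c("chrom", "pos"))

  n_cds <- min(max(1L, round(0.10 * L)), nrow(cds_pos))
  n_utr <- min(max(1L, round(0.05 * L)), nrow(utr_pos))
  n_int <- min(max(1L, round(0.10 * L)), nrow(intron_pos))
  if (n_cds + n_utr + n_int > L - 1L) {   # tiny L: one of each, rest noncoding
    n_cds <- n_utr <- n_int <- min(1L, L %/% 4L)
  }
  n_non <- L - n_cds - n_utr - n_int
  if (n_non > nrow(nonc_pos)) stop("genome too small for requested L")
  pick <- function(df, n) df[sample(nrow(df), n), , drop = FALSE]
  placed <- dplyr::bind_rows(
    dplyr::mutate(pick(cds_pos, n_cds), category = "CDS"),
    dplyr::mutate(pick(utr_pos, n_utr), category = "UTR"),
    dplyr::mutate(pick(intron_pos, n_int), category = "intron"),
    dplyr::mutate(pick(nonc_pos, n_non), category = "noncoding"))
  placed$ref <- base_at(seqs, placed$chrom, placed$pos)
  placed$alt <- NA_character_
  placed$effect <- NA_character_
  placed$gene <- NA_character_

  cds_rows <- which(placed$category == "CDS")
  want_syn <- rep(c(TRUE, FALSE), length.out = length(cds_rows))
  for (j in seq_along(cds_rows)) {
    r <- cds_rows[j]
    gi <- which(genes$chrom == placed$chrom[r] & genes$start <= placed$pos[r] &
                  genes$end >= placed$pos[r])[1]
    ch <- choose_cds_alt(seqs, genes[gi, ], placed$pos[r], want_syn[j])
    placed$alt[r] <- ch$alt
    placed$effect[r] <- ch$effect
    placed$gene[r] <- genes$gene[gi]
  }
  other <- which(placed$category != "CDS")
  placed$alt[other] <- vapply(placed$ref[other], function(r)
    sample(setdiff(bases, r), 1), "")
  placed <- dplyr::arrange(placed, .data$chrom, .data$pos)

  structure(list(seq = seqs, genes = genes, gff = genome_gff(genes, contig_len),
                 snp_truth = placed), class = "synth_genome")
}

base_at <- function(seqs, chrom, pos) {
  substring(seqs[chrom], pos, pos)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# CDS coordinate vector in transcription order (5' -> 3')
cds_vector <- function(gene_row) {
  v <- unlist(purrr::map2(gene_row$cds[[1]]$start, gene_row$cds[[1]]$end, seq))
  if (gene_row$strand == "-") rev(v) else v
}

# codon containing genomic position `pos` in gene `gene_row`; returns the
# ref codon (transcribed strand), the offset of pos within it, and the
# transcription-order genomic positions of the codon
ref_codon_at <- function(seqs, gene_row, pos) {
  v <- cds_vector(gene_row)
  i <- match(pos, v)
  if (is.na(i)) stop("position not in CDS of gene")
  ci <- (i - 1L) %/% 3L
  idx <- v[(ci * 3L + 1L):(ci * 3L + 3L)]
  b <- base_at(seqs, gene_row$chrom, idx)
  if (gene_row$strand == "-") b <- COMPLEMENT[b]
  list(codon = paste(b, collapse = ""), offset = (i - 1L) %% 3L + 1L,
       positions = idx)
}

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# pick a genomic alt base at a CDS position, preferring the requested effect
choose_cds_alt <- function(seqs, gene_row, pos, want_syn) {
  rc <- ref_codon_at(seqs, gene_row, pos)
  ref_aa <- codon_aa(rc$codon)
  cand <- setdiff(c("A", "C", "G", "T"), base_at(seqs, gene_row$chrom, pos))
  eff <- vapply(cand, function(alt) {
    talt <- if (gene_row$strand == "-") COMPLEMENT[[alt]] else alt
    alt_codon <- rc$codon
    substr(alt_codon, rc$offset, rc$offset) <- talt
    if (codon_aa(alt_codon) == ref_aa) "synonymous" else "nonsynonymous"
  }, "")
  hit <- which(eff == (if (want_syn) "synonymous" else "nonsynonymous"))
  k <- if (length(hit) > 0) hit[1] else 1L
  list(alt = cand[k], effect = unname(eff[k]))
}

# GFF3 feature table for the toy gene models (no explicit UTR rows: readers
# infer UTRs as exon minus CDS)
genome_gff <- function(genes, contig_len) {
  rows <- purrr::pmap(genes, function(gene, chrom, start, end, strand,
                                      utr, cds, exons) {
    tid <- paste0(gene, ".t1")
    cds_tx <- if (strand == "-") cds[order(-cds$start), ] else cds
    cum <- cumsum(c(0L, cds_tx$end - cds_tx$start + 1L))
    phase <- (3L - cum[seq_len(nrow(cds_tx))] %% 3L) %% 3L
    dplyr::bind_rows(
      tibble::tibble(seqid = chrom, source = "radpopgen", type = "gene",
                     start = start, end = end, score = ".", strand = strand,
                     phase = ".", attributes = paste0("ID=", gene)),
      tibble::tibble(seqid = chrom, source = "radpopgen", type = "mRNA",
                     start = start, end = end, score = ".", strand = strand,
                     phase = ".", attributes = paste0("ID=", tid, ";Parent=", gene)),
      tibble::tibble(seqid = chrom, source = "radpopgen", type = "exon",
                     start = exons$start, end = exons$end, score = ".",
                     strand = strand, phase = ".",
                     attributes = paste0("Parent=", tid)),
      tibble::tibble(seqid = chrom, source = "radpopgen", type = "CDS",
                     start = cds_tx$start, end = cds_tx$end, score = ".",
                     strand = strand, phase = as.character(phase),
                     attributes = paste0("ID=", gene, ".cds;Parent=", tid)))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$seqid, .data$start,
                 dplyr::desc(.data$end))
}

#' Write a toy genome to FASTA and GFF3 files
#' @param genome A `synth_genome`.
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_genome <- function(genome, fasta_path, gff_path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), fasta_path)
  g <- genome$gff
  lines <- c("##gff-version 3",
             paste(g$seqid, g$source, g$type, g$start, g$end, g$score,
                   g$strand, g$phase, g$attributes, sep = "\t"))
  writeLines(lines, gff_path)
  invisible(list(fasta = fasta_path, gff = gff_path))
}
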