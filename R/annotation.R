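#' Read a genome FASTA into a named character vector
#' @param path FASTA path.
#' @return Named character vector of contig sequences (uppercase).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Build an annotation index from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features (via [ape::read.gff()]); UTRs are
#' inferred as exon minus CDS when no explicit UTR features exist, and
#' introns as within-transcript gaps between exons. Transcripts whose CDS
#' lengths do not sum to a multiple of 3 are flagged and excluded from
#' amino-acid effect calling; CDS rows without a parent transcript are
#' skipped with a message.
#'
#' @param gff_path Path to a GFF3 file.
#' @return Object of class `annotation_index`: list with `features` (tibble
#'   `chrom`, `start`, `end`, `type` in CDS/UTR/intron, `transcript`,
#'   `strand`) and `transcripts` (tibble with list-column `cds` ordered by
#'   transcription, `strand`, `frame_ok`).
#' @export
build_annotation_index <- function(gff_path) {
  g <- ape::read.gff(gff_path, GFF3 = TRUE)
  g <- tibble::as_tibble(g)
  g$attributes <- as.character(g$attributes)
  attr_field <- function(x, key) {
    m <- regmatches(x, regexec(paste0("(?:^|;)", key, "=([^;]+)"), x))
    vapply(m, function(v) if (length(v) == 2) v[2] else NA_character_, "")
  }
  mrna <- g[g$type %in% c("mRNA", "transcript"), ]
  tid <- attr_field(mrna$attributes, "ID")
  tx_strand <- stats::setNames(as.character(mrna$strand), tid)
  tx_chrom <- stats::setNames(as.character(mrna$seqid), tid)

  sub_rows <- function(type) {
    r <- g[g$type == type, ]
    parent <- attr_field(r$attributes, "Parent")
    orphan <- !parent %in% tid
    if (any(orphan)) {
      message(sum(orphan), " ", type, " feature(s) without a parent ",
              "transcript skipped")
      r <- r[!orphan, ]; parent <- parent[!orphan]
    }
    tibble::tibble(transcript = parent, chrom = as.character(r$seqid),
                   start = r$start, end = r$end)
  }
  exons <- sub_rows("exon")
  cds <- sub_rows("CDS")
  utr_explicit <- g[grepl("UTR", g$type, ignore.case = TRUE), ]

  transcripts <- purrr::map_dfr(unique(cds$transcript), function(t) {
    ct <- cds[cds$transcript == t, ]
    ct <- ct[order(ct$start), ]
    strand <- tx_strand[[t]]
    if (strand == "-") ct <- ct[order(-ct$start), ]
    len <- sum(ct$end - ct$start + 1)
    tibble::tibble(transcript = t, chrom = tx_chrom[[t]], strand = strand,
                   cds = list(ct[c("start", "end")]),
                   frame_ok = len %% 3 == 0)
  })
  bad <- transcripts$transcript[!transcripts$frame_ok]
  if (length(bad) > 0) {
    message("transcript(s) with CDS length not a multiple of 3 excluded ",
            "from effect calling: ", paste(bad, collapse = ", "))
  }

  feats <- list(dplyr::mutate(cds, type = "CDS"))
  if (nrow(utr_explicit) > 0) {
    feats <- c(feats, list(tibble::tibble(
      transcript = attr_field(utr_explicit$attributes, "Parent"),
      chrom = as.character(utr_explicit$seqid),
      start = utr_explicit$start, end = utr_explicit$end, type = "UTR")))
  } else {
    feats <- c(feats, list(infer_complement(exons, cds, "UTR")))
  }
  feats <- c(feats, list(infer_introns(exons)))
  structure(list(features = dplyr::bind_rows(feats),
                 transcripts = transcripts), class = "annotation_index")
}

# per-transcript set difference outer minus inner, as intervals
infer_complement <- function(outer, inner, type) {
  purrr::map_dfr(unique(outer$transcript), function(t) {
    ot <- outer[outer$transcript == t, ]
    it <- inner[inner$transcript == t, ]
    purrr::map_dfr(seq_len(nrow(ot)), function(i) {
      pos <- seq(ot$start[i], ot$end[i])
      for (j in seq_len(nrow(it))) pos <- pos[pos < it$start[j] | pos > it$end[j]]
      if (length(pos) == 0) return(NULL)
      runs <- split(pos, cumsum(c(1, diff(pos) != 1)))
      tibble::tibble(transcript = t, chrom = ot$chrom[i],
                     start = vapply(runs, min, 0),
                     end = vapply(runs, max, 0), type = type)
    })
  })
}

infer_introns <- function(exons) {
  purrr::map_dfr(unique(exons$transcript), function(t) {
    et <- exons[exons$transcript == t, ]
    et <- et[order(et$start), ]
    if (nrow(et) < 2) return(NULL)
    tibble::tibble(transcript = t, chrom = et$chrom[1],
                   start = et$end[-nrow(et)] + 1, end = et$start[-1] - 1,
                   type = "intron")
  })
}

#' Classify a genomic position into CDS / UTR / intron / noncoding
#'
#' Overlapping transcripts are resolved by the precedence CDS > UTR >
#' intron; positions covered by no feature are noncoding.
#'
#' @param index An `annotation_index`.
#' @param chrom,pos Vectors of contig names and 1-based positions.
#' @return Character vector of categories.
#' @export
classify_site <- function(index, chrom, pos) {
  f <- index$features
  prec <- c(CDS = 1, UTR = 2, intron = 3)
  vapply(seq_along(pos), function(i) {
    hit <- f$type[f$chrom == chrom[i] & f$start <= pos[i] & f$end >= pos[i]]
    if (length(hit) == 0) "noncoding" else hit[which.min(prec[hit])]
  }, "")
}

#' Amino-acid effect of a CDS SNP
#'
#' Locates the codon through the transcript's ordered CDS segments (on the
#' minus strand both alleles and the codon context are
#' reverse-complemented), translates reference and alternate codons with the
#' standard genetic code, and calls the substitution synonymous iff the
#' residues are equal. Stop gain/loss counts as nonsynonymous with a
#' distinguishing sub-label. The reference FASTA base at the position must
#' equal the site's reference allele (coordinate sanity check).
#'
#' @param index An `annotation_index`.
#' @param fasta Named character vector from [read_genome_fasta()].
#' @param chrom,pos,ref,alt The SNP (single alternate allele).
#' @return Tibble with `category`, `transcript`, `ref_codon`, `alt_codon`,
#'   `ref_residue`, `alt_residue`, `effect`
#'   (`synonymous` / `nonsynonymous`), `sub_label` (`missense`,
#'   `stop-gain`, `stop-loss` or `NA`).
#' @export
amino_acid_effect <- function(index, fasta, chrom, pos, ref, alt) {
  if (base_at(fasta, chrom, pos) != ref) {
    stop("reference mismatch at ", chrom, ":", pos, " (FASTA has ",
         base_at(fasta, chrom, pos), ", site says ", ref, ")")
  }
  tx <- index$transcripts
  cover <- vapply(seq_len(nrow(tx)), function(i) {
    tx$chrom[i] == chrom && any(tx$cds[[i]]$start <= pos & tx$cds[[i]]$end >= pos)
  }, TRUE)
  cover <- cover & tx$frame_ok
  if (!any(cover)) {
    return(tibble::tibble(category = "CDS", transcript = NA_character_,
                          ref_codon = NA_character_, alt_codon = NA_character_,
                          ref_residue = NA_character_,
                          alt_residue = NA_character_,
                          effect = NA_character_, sub_label = NA_character_))
  }
  i <- which(cover)[1]
  ct <- tx$cds[[i]]
  # ct rows are already in transcription order; on the minus strand walk
  # each segment from its genomic end to its start
  v <- if (tx$strand[i] == "-") unlist(purrr::map2(ct$end, ct$start, seq))
  else unlist(purrr::map2(ct$start, ct$end, seq))
  j <- match(pos, v)
  ci <- (j - 1L) %/% 3L
  idx <- v[(ci * 3L + 1L):(ci * 3L + 3L)]
  b <- vapply(idx, function(p) base_at(fasta, chrom, p), "")
  talt <- alt
  if (tx$strand[i] == "-") { b <- COMPLEMENT[b]; talt <- COMPLEMENT[[alt]] }
  ref_codon <- paste(b, collapse = "")
  off <- (j - 1L) %% 3L + 1L
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- talt
  if (grepl("[^ACGT]", ref_codon) || grepl("[^ACGT]", alt_codon)) {
    message("ambiguous base in codon context at ", chrom, ":", pos,
            "; effect undefined")
    return(tibble::tibble(category = "CDS", transcript = tx$transcript[i],
                          ref_codon = ref_codon, alt_codon = alt_codon,
                          ref_residue = NA_character_,
                          alt_residue = NA_character_,
                          effect = NA_character_, sub_label = NA_character_))
  }
  aa_r <- codon_aa(ref_codon); aa_a <- codon_aa(alt_codon)
  effect <- if (aa_r == aa_a) "synonymous" else "nonsynonymous"
  sub_label <- if (effect == "synonymous") NA_character_
  else if (aa_a == "*") "stop-gain" else if (aa_r == "*") "stop-loss"
  else "missense"
  tibble::tibble(category = "CDS", transcript = tx$transcript[i],
                 ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_residue = aa_r, alt_residue = aa_a,
                 effect = effect, sub_label = sub_label)
}

#' Region and effect summary for a marker set
#'
#' Classifies every marker into CDS / UTR / intron / noncoding (a partition:
#' category counts always sum to the total), and calls amino-acid effects
#' for CDS markers. The multiallelic effect call uses the first alternate
#' allele.
#'
#' @param markers Tibble with `chrom`, `pos`, `ref`, `alt` columns (e.g. a
#'   `diagnostic_markers` result).
#' @param index An `annotation_index`.
#' @param fasta Named character vector from [read_genome_fasta()].
#' @return Object of class `region_summary`: list with `counts` (tibble
#'   `category`, `n` over the four categories plus rows `gene_region`,
#'   `nonsynonymous`, `total`) and `details` (per-marker tibble).
#' @export
summarize_regions <- function(markers, index, fasta) {
  markers <- tibble::as_tibble(markers)
  if (nrow(markers) == 0) {
    details <- tibble::tibble(chrom = character(), pos = integer(),
                              category = character(), effect = character())
  } else {
    cat <- classify_site(index, markers$chrom, markers$pos)
    details <- dplyr::mutate(markers, category = cat, effect = NA_character_)
    for (i in which(cat == "CDS")) {
      alt1 <- strsplit(markers$alt[i], ",", fixed = TRUE)[[1]][1]
      eff <- amino_acid_effect(index, fasta, markers$chrom[i], markers$pos[i],
                               markers$ref[i], alt1)
      details$effect[i] <- eff$effect
    }
  }
  lev <- c("CDS", "UTR", "intron", "noncoding")
  n <- vapply(lev, function(l) sum(details$category == l), 0L)
  counts <- tibble::tibble(
    category = c(lev, "gene_region", "nonsynonymous", "total"),
    n = unname(c(n, sum(n[c("CDS", "UTR", "intron")]),
                 sum(details$effect == "nonsynonymous", na.rm = TRUE),
                 sum(n))))
  structure(list(counts = counts, details = details),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat("<region_summary>\n")
  print(tidyr::pivot_wider(x$counts, names_from = "category",
                           values_from = "n"))
  invisible(x)
}
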