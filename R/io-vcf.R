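#' Read a VCF file into a genotype matrix
#'
#' Loads all samples and all SNP records from a VCF v4.x file (only the GT
#' field is consumed; phase separators are ignored). Records whose REF or any
#' ALT allele is not a single A/C/G/T base — indels, symbolic and spanning
#' alleles — are dropped with a reported count.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param verbose Report dropped-record counts (default `TRUE`).
#' @return A [geno_matrix].
#' @export
read_vcf <- function(path, verbose = TRUE) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    samp <- colnames(v@gt)[-1]
    if (is.null(samp)) samp <- character(0)
    return(geno_matrix(samp, empty_sites(), matrix(NA_integer_, length(samp), 0),
                       matrix(NA_integer_, length(samp), 0)))
  }
  base <- "^[ACGT]$"
  alt_ok <- vapply(strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE),
                   function(a) length(a) > 0 && all(grepl(base, a)), logical(1))
  snp <- grepl(base, fix$REF) & alt_ok
  if (verbose && any(!snp)) {
    message(sum(!snp), " non-SNP record(s) dropped from ", basename(path))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  gt <- t(gt[snp, , drop = FALSE])  # samples x sites
  gt <- gsub("|", "/", gt, fixed = TRUE)
  bad <- !is.na(gt) & !grepl("^(\\.|[0-9]+)/(\\.|[0-9]+)$", gt)
  if (any(bad)) {
    stop("malformed GT field in '", path, "' at record ",
         which(colSums(bad) > 0)[1], call. = FALSE)
  }
  a1 <- suppressWarnings(array(as.integer(sub("/.*$", "", gt)), dim = dim(gt)))
  a2 <- suppressWarnings(array(as.integer(sub("^.*/", "", gt)), dim = dim(gt)))
  half <- is.na(a1) != is.na(a2)  # half-calls like ./1 -> missing
  a1[half] <- NA_integer_; a2[half] <- NA_integer_
  fix <- fix[snp, , drop = FALSE]
  sites <- tibble::tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    ref = fix$REF, alt = fix$ALT)
  geno_matrix(rownames(gt), sites, a1, a2)
}

empty_sites <- function() {
  tibble::tibble(chrom = character(), pos = integer(), id = character(),
                 ref = character(), alt = character())
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal VCF v4.2 with GT-only genotypes; missing calls become
#' `./.`. `read_vcf(write_vcf(gm))` reproduces calls, sample order and site
#' order exactly.
#'
#' @param gm A [geno_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=radpopgen",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (n_sites(gm) > 0) {
    calls <- format_calls(gm)
    body <- paste(gm$sites$chrom, gm$sites$pos, gm$sites$id, gm$sites$ref,
                  gm$sites$alt, ".", "PASS", ".", "GT",
                  apply(calls, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}
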