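#' Read a coverage ("covstats"-style) table
#'
#' Dialect: tab-separated with header
#' `#id  length  plus_reads  minus_reads  covered_bases`; extra columns
#' are ignored. This mirrors the per-reference coverage summaries emitted
#' by short-read mappers.
#'
#' @param path File path.
#' @return `data.frame` with `target_id`, `target_length`, `reads_plus`,
#'   `reads_minus`, `covered_bases`.
#' @export
read_coverage <- function(path) {
  header <- strsplit(sub("^#", "", readLines(path, n = 1)), "\t")[[1]]
  d <- read.delim(path, skip = 1, header = FALSE, stringsAsFactors = FALSE)
  names(d)[seq_along(header)] <- header
  need <- c("id", "length", "plus_reads", "minus_reads", "covered_bases")
  if (!all(need %in% names(d))) {
    stop_capkit(sprintf("coverage table %s lacks columns: %s", path,
                        paste(setdiff(need, names(d)), collapse = ", ")),
                "capkit_bad_coverage")
  }
  data.frame(target_id = as.character(d$id), target_length = d$length,
             reads_plus = d$plus_reads, reads_minus = d$minus_reads,
             covered_bases = d$covered_bases, stringsAsFactors = FALSE)
}

#' Write a coverage table
#'
#' @param coverage Coverage `data.frame` (see [read_coverage()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(coverage, path) {
  out <- data.frame(id = coverage$target_id, length = coverage$target_length,
                    plus_reads = coverage$reads_plus,
                    minus_reads = coverage$reads_minus,
                    covered_bases = coverage$covered_bases)
  writeLines(paste0("#", paste(names(out), collapse = "\t")), path)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read / write a per-base pileup table
#'
#' Dialect: tab-separated `pos  A  C  G  T` with one row per reference
#' position.
#'
#' @param path File path.
#' @return `read_pileup`: `data.frame` with `pos`, `A`, `C`, `G`, `T`.
#' @export
read_pileup <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  check_pileup(d)
}

#' @rdname read_pileup
#' @param pileup Pileup `data.frame`.
#' @export
write_pileup <- function(pileup, path) {
  write.table(pileup[, c("pos", "A", "C", "G", "T")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings with the 70-column line width used for
#' consensus output.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences Named character vector (or `DNAStringSet`).
#' @export
write_fasta <- function(sequences, path) {
  if (!inherits(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(unlist(sequences))
  }
  Biostrings::writeXStringSet(sequences, path, width = 70)
  invisible(path)
}

#' Write a variant set as a VCF v4.2 document
#'
#' Emits fixed columns, QUAL, and a GT-only FORMAT block; missing
#' genotypes are coded `./.`.
#'
#' @param variants A [variant_set()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  sites <- variants$sites
  gt <- variants$gt
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=capkit",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t")
  ), con)
  body <- cbind(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                sites$qual, "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotypes from a VCF into a variant set
#'
#' Parses a VCF v4.2 file (via vcfR) into the in-memory [variant_set()]
#' used by the SNP diagnostics stage. Requires QUAL and the GT FORMAT
#' field.
#'
#' @param path File path.
#' @return A [variant_set()].
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop_capkit("VCF lacks GT field", "capkit_bad_vcf")
  gt[is.na(gt)] <- "./."
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  sites <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, qual = as.numeric(fix$QUAL), stringsAsFactors = FALSE
  )
  rownames(gt) <- NULL
  variant_set(sites, gt)
}

#' Read an aligned FASTA file
#'
#' @param path File path.
#' @return Named character vector of equal-length aligned sequences
#'   (gaps preserved).
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}
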