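#' Call a reference-guided consensus from a per-base pileup
#'
#' Each position receives the plurality base when its total depth reaches
#' `min_depth`, and `N` otherwise (the minimum-depth masking rule; the
#' default of 2X reflects that a single read cannot corroborate a base).
#' Ties for the plurality base are conservatively called `N`.
#'
#' @param pileup `data.frame` with columns `pos` (1-based, contiguous
#'   from 1) and base counts `A`, `C`, `G`, `T`.
#' @param min_depth Minimum depth for a base call (default 2).
#' @return List with `sequence` (character scalar over ACGTN), `depth`
#'   (per-position totals).
#' @export
call_consensus <- function(pileup, min_depth = 2) {
  check_pileup(pileup)
  counts <- as.matrix(pileup[, c("A", "C", "G", "T")])
  depth <- rowSums(counts)
  top <- max.col(counts, ties.method = "first")
  top_count <- counts[cbind(seq_len(nrow(counts)), top)]
  tied <- rowSums(counts == top_count) > 1 & top_count > 0
  base <- c("A", "C", "G", "T")[top]
  base[depth < min_depth | tied] <- "N"
  list(sequence = paste(base, collapse = ""), depth = depth)
}

#' Coverage statistics for a pileup
#'
#' @param pileup `data.frame` as in [call_consensus()].
#' @return List with `base_count` (total mapped base observations, a
#'   read-count proxy), `mean_depth` and `pct_covered` (share of
#'   positions at >= 1X, to 1 decimal).
#' @export
coverage_stats <- function(pileup) {
  check_pileup(pileup)
  depth <- rowSums(pileup[, c("A", "C", "G", "T")])
  list(
    base_count = sum(depth),
    mean_depth = mean(depth),
    pct_covered = round_half_out(100 * mean(depth >= 1), 1)
  )
}

check_pileup <- function(pileup) {
  stopifnot(is.data.frame(pileup))
  need <- c("pos", "A", "C", "G", "T")
  if (!all(need %in% names(pileup))) {
    stop_capkit(paste("pileup must have columns:", paste(need, collapse = ", ")),
                "capkit_bad_pileup")
  }
  if (nrow(pileup) == 0) stop_capkit("empty pileup", "capkit_empty")
  if (!identical(as.integer(pileup$pos), seq_len(nrow(pileup)))) {
    stop_capkit("pileup positions must run 1..L without gaps", "capkit_bad_pileup")
  }
  if (any(pileup[, c("A", "C", "G", "T")] < 0)) {
    stop_capkit("negative base counts", "capkit_bad_pileup")
  }
  invisible(pileup)
}

#' Percentage of ambiguous (N) bases in a sequence
#'
#' @param sequence Nonempty character scalar.
#' @return Percent N, to 1 decimal.
#' @export
#' @examples
#' count_n_bases("NNAA") # 50
count_n_bases <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) stop_capkit("empty sequence", "capkit_empty")
  b <- strsplit(sequence, "")[[1]]
  round_half_out(100 * mean(b %in% c("N", "n")), 1)
}

#' Join assembly contigs with an N spacer
#'
#' When the true gap size between ordered contigs is unknown, junctions
#' are padded with a fixed run of `N` bases (default 100) so downstream
#' alignment and annotation see an explicit gap.
#'
#' @param contigs Character vector of contig sequences, in final order.
#' @param spacer_n Number of `N` bases between consecutive contigs.
#' @return Single scaffold sequence.
#' @export
join_contigs <- function(contigs, spacer_n = 100) {
  if (length(contigs) == 0) stop_capkit("no contigs to join", "capkit_empty")
  paste(contigs, collapse = strrep("N", spacer_n))
}

#' Count variable sites in a multiple alignment
#'
#' A column is variable when it contains at least two distinct unambiguous
#' bases (A/C/G/T) within the chosen taxon subset; `N` and gap characters
#' are ignored entirely, so a column differing only by missing data is not
#' a SNP.
#'
#' @param alignment Named character vector (or `Biostrings::DNAStringSet`)
#'   of equal-length aligned sequences over `{A,C,G,T,N,-}`.
#' @param subset Optional character vector of taxon names restricting the
#'   count.
#' @return Number of variable columns.
#' @export
count_alignment_snps <- function(alignment, subset = NULL) {
  seqs <- as_named_sequences(alignment)
  seqs <- setNames(toupper(seqs), names(seqs))
  if (!is.null(subset)) {
    missing <- setdiff(subset, names(seqs))
    if (length(missing) > 0) {
      stop_capkit(paste("subset taxa not in alignment:",
                        paste(missing, collapse = ", ")),
                  "capkit_bad_subset")
    }
    seqs <- seqs[subset]
  }
  if (length(unique(nchar(seqs))) != 1) {
    stop_capkit("ragged alignment: sequences differ in length", "capkit_ragged")
  }
  m <- do.call(rbind, strsplit(seqs, ""))
  sum(apply(m, 2, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2
  }))
}
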