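#' Mapped reads per kilobase (RPK) of a gene model
#'
#' RPK normalizes the number of genomic reads mapped to a transcript model
#' by model length, as a proxy for genomic copy number: when shotgun reads
#' from the same genome are mapped to a transcriptome, high-copy gene
#' families accumulate proportionally more reads per kilobase than
#' single-copy genes.
#'
#' @param reads_plus,reads_minus Non-negative read counts mapped to the
#'   plus and minus strand of each target.
#' @param target_length Target length in bp (must be >= 1).
#' @return Numeric vector: `(reads_plus + reads_minus) / (target_length / 1000)`.
#' @export
#' @examples
#' compute_rpk(6, 4, 2000) # 5
compute_rpk <- function(reads_plus, reads_minus, target_length) {
  if (any(target_length < 1)) {
    stop_capkit("target_length must be >= 1 bp", "capkit_bad_length")
  }
  if (any(reads_plus < 0) || any(reads_minus < 0)) {
    stop_capkit("read counts must be non-negative", "capkit_bad_counts")
  }
  (reads_plus + reads_minus) / (target_length / 1000)
}

#' Rank a coverage table by ascending RPK
#'
#' Sorts targets by RPK in ascending order; ties are broken by
#' lexicographic target id so the ranking (and any window selected from
#' it) is fully reproducible. Ranks are 1-based and gap-free.
#'
#' @param coverage A coverage table (`data.frame`) with columns
#'   `target_id`, `target_length`, `reads_plus`, `reads_minus` and
#'   optionally `covered_bases` (see [read_coverage()]).
#' @return A `data.frame` with columns `target_id`, `rpk`, `rank`,
#'   ordered by rank.
#' @export
rank_by_rpk <- function(coverage) {
  stopifnot(is.data.frame(coverage))
  if (nrow(coverage) == 0) stop_capkit("empty coverage table", "capkit_empty")
  if (anyDuplicated(coverage$target_id)) {
    stop_capkit("duplicate target ids in coverage table", "capkit_duplicate_ids")
  }
  rpk <- compute_rpk(coverage$reads_plus, coverage$reads_minus,
                     coverage$target_length)
  ord <- order(rpk, as.character(coverage$target_id), method = "radix")
  data.frame(
    target_id = as.character(coverage$target_id)[ord],
    rpk = rpk[ord],
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
}

#' Select gene targets inside an inclusive rank window
#'
#' The low end of the RPK ranking is dominated by unmappable or
#' contaminant models and the high end by multi-copy gene families;
#' an interior rank window (the study default is ranks 5000 to 15,000)
#' selects putatively low-copy gene targets. Both bounds are inclusive,
#' so the window `[lo, hi]` always yields `hi - lo + 1` targets.
#'
#' @param ranking Output of [rank_by_rpk()].
#' @param lo,hi 1-based inclusive rank bounds, `1 <= lo <= hi <= N`.
#' @return The rows of `ranking` with rank in `[lo, hi]`.
#' @export
select_rank_window <- function(ranking, lo, hi) {
  n <- nrow(ranking)
  if (!(lo >= 1 && lo <= hi && hi <= n)) {
    stop_capkit(sprintf("rank window [%s, %s] outside 1..%d", lo, hi, n),
                "capkit_bad_window")
  }
  ranking[ranking$rank >= lo & ranking$rank <= hi, , drop = FALSE]
}

#' Summarize RPK over a ranking or a selected subset
#'
#' @param ranking Output of [rank_by_rpk()].
#' @param subset Optional character vector of target ids (e.g. a selected
#'   target set) restricting the summary.
#' @return A list with `mean`, `min`, `max` of RPK.
#' @export
rpk_summary <- function(ranking, subset = NULL) {
  x <- ranking
  if (!is.null(subset)) x <- x[x$target_id %in% subset, , drop = FALSE]
  if (nrow(x) == 0) stop_capkit("empty RPK subset", "capkit_empty")
  list(mean = mean(x$rpk), min = min(x$rpk), max = max(x$rpk))
}

#' Attach sequences to a selected rank window
#'
#' Builds a target set (ids, sequences, lengths) from a window selection
#' and the transcriptome. Repeat masking is an upstream step; as a
#' convenience, targets whose fraction of masked bases (lower-case or `N`)
#' exceeds `max_masked_frac` can be dropped here.
#'
#' @param selection Output of [select_rank_window()].
#' @param transcripts Named character vector or `Biostrings::DNAStringSet`
#'   of transcript sequences (possibly soft-masked).
#' @param max_masked_frac Drop targets with a masked-base fraction above
#'   this value; `NULL` disables the filter. Default 0.5.
#' @return A `data.frame` with `target_id`, `sequence`, `length`.
#' @export
extract_targets <- function(selection, transcripts, max_masked_frac = 0.5) {
  seqs <- as_named_sequences(transcripts)
  missing <- setdiff(selection$target_id, names(seqs))
  if (length(missing) > 0) {
    stop_capkit(sprintf("%d selected targets missing from transcriptome (e.g. %s)",
                        length(missing), missing[1]), "capkit_missing_targets")
  }
  out <- data.frame(
    target_id = selection$target_id,
    sequence = unname(seqs[selection$target_id]),
    stringsAsFactors = FALSE
  )
  out$length <- nchar(out$sequence)
  if (!is.null(max_masked_frac)) {
    masked <- vapply(strsplit(out$sequence, ""), function(b) {
      mean(b %in% c("a", "c", "g", "t", "n", "N"))
    }, numeric(1))
    out <- out[masked <= max_masked_frac, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
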