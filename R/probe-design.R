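#' Tile fixed-length hybridization probes across gene targets
#'
#' Probes are tiled end-to-end (no overlap, no gap) starting at the 5'
#' end of each target: tile k covers `[k * probe_length, (k+1) * probe_length)`
#' in 0-based half-open coordinates. At most `probes_per_target` tiles are
#' emitted per target, and only full-length tiles are kept (a 150-bp
#' target yields a single 100-bp probe). Probe ids are
#' `<target_id>_p<k>` with `k` the 1-based tile index.
#'
#' Probes containing characters other than upper-case A/C/G/T (Ns or
#' soft-masked bases) are flagged in the `ambiguous` column; set
#' `drop_ambiguous = TRUE` to remove them.
#'
#' @param targets Named character vector, `Biostrings::DNAStringSet`, or a
#'   `data.frame` with `target_id` and `sequence` columns (as returned by
#'   [extract_targets()]).
#' @param probe_length Probe length in bp (default 100).
#' @param probes_per_target Maximum tiles per target (default 2).
#' @param drop_ambiguous Drop probes containing non-ACGT characters.
#' @return A `data.frame` with columns `probe_id`, `target_id`, `start`,
#'   `end` (0-based half-open), `sequence`, `ambiguous`.
#' @export
#' @examples
#' tile_probes(c(t1 = strrep("ACGT", 50)))  # 200 bp -> 2 probes
tile_probes <- function(targets, probe_length = 100, probes_per_target = 2,
                        drop_ambiguous = FALSE) {
  if (is.data.frame(targets)) {
    seqs <- setNames(targets$sequence, targets$target_id)
  } else {
    seqs <- as_named_sequences(targets)
  }
  if (length(seqs) == 0) {
    return(data.frame(probe_id = character(), target_id = character(),
                      start = integer(), end = integer(),
                      sequence = character(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop_capkit("targets must be named", "capkit_unnamed_targets")
  }
  stopifnot(probe_length >= 1, probes_per_target >= 1)
  len <- nchar(seqs)
  short <- len < probe_length
  if (any(short)) {
    stop_capkit(sprintf("target '%s' (%d bp) is shorter than one probe length (%d bp)",
                        names(seqs)[short][1], len[short][1], probe_length),
                "capkit_target_too_short")
  }
  n_tiles <- pmin(len %/% probe_length, probes_per_target)
  out <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    k <- seq_len(n_tiles[i])
    start <- (k - 1L) * probe_length
    data.frame(
      probe_id = sprintf("%s_p%d", names(seqs)[i], k),
      target_id = names(seqs)[i],
      start = start,
      end = start + probe_length,
      sequence = substring(seqs[i], start + 1L, start + probe_length),
      stringsAsFactors = FALSE
    )
  }))
  out$ambiguous <- grepl("[^ACGT]", out$sequence)
  if (drop_ambiguous) out <- out[!out$ambiguous, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a probe panel
#'
#' @param probes Output of [tile_probes()].
#' @return A list with `n_probes`, `n_targets` and, for non-empty panels,
#'   `mean_probes_per_target`.
#' @export
probe_panel_summary <- function(probes) {
  n_probes <- nrow(probes)
  n_targets <- length(unique(probes$target_id))
  out <- list(n_probes = n_probes, n_targets = n_targets)
  if (n_targets > 0) out$mean_probes_per_target <- n_probes / n_targets
  out
}
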