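#' Total on-target read yield from a coverage table
#'
#' Sum of reads mapped to gene targets on either strand, the per-library
#' on-target yield.
#'
#' @param coverage Coverage table with `reads_plus` and `reads_minus`
#'   columns; may be empty.
#' @return A single count.
#' @export
on_target_yield <- function(coverage) {
  if (nrow(coverage) == 0) return(0)
  sum(coverage$reads_plus) + sum(coverage$reads_minus)
}

#' Percentage of a library that is on-target (or any category share)
#'
#' Reported to one decimal, rounding half away from zero, matching the
#' presentation convention of capture QC tables.
#'
#' @param count Category read count (e.g. on-target or organelle reads).
#' @param total Total sequenced reads; must be > 0.
#' @return `100 * count / total`, rounded to 1 decimal.
#' @export
#' @examples
#' percent_on_target(488207, 1515526) # 32.2
percent_on_target <- function(count, total) {
  if (any(total <= 0)) stop_capkit("total must be > 0", "capkit_bad_total")
  round_half_out(100 * count / total, 1)
}

#' Per-target depth of coverage from read counts
#'
#' Depth is estimated as read length times the number of mapped reads
#' (both strands) divided by the covered target length, i.e. bases
#' sequenced per covered base. Targets with no mapped reads have depth 0.
#'
#' @param mapped_reads Reads mapped to the target (plus + minus).
#' @param covered_bases Covered target length in bp; must be > 0 wherever
#'   `mapped_reads > 0`.
#' @param read_length Sequence read length in bp (default 101).
#' @return Numeric depth (X) vector.
#' @export
#' @examples
#' target_depth(100, 1010) # 10
target_depth <- function(mapped_reads, covered_bases, read_length = 101) {
  bad <- mapped_reads > 0 & covered_bases <= 0
  if (any(bad)) {
    stop_capkit("covered_bases must be > 0 where mapped_reads > 0",
                "capkit_bad_covered")
  }
  ifelse(mapped_reads > 0, read_length * mapped_reads / covered_bases, 0)
}

#' Per-target depth matrix across specimens
#'
#' @param coverage_list Named list of per-specimen coverage tables (names
#'   are specimen ids) sharing a common target universe.
#' @param read_length Read length for [target_depth()].
#' @return Matrix of depths, targets x specimens; targets absent from a
#'   specimen's table get depth 0.
#' @export
depth_matrix <- function(coverage_list, read_length = 101) {
  stopifnot(is.list(coverage_list), length(coverage_list) > 0,
            !is.null(names(coverage_list)))
  targets <- sort(unique(unlist(lapply(coverage_list, `[[`, "target_id"))))
  m <- matrix(0, nrow = length(targets), ncol = length(coverage_list),
              dimnames = list(targets, names(coverage_list)))
  for (sp in names(coverage_list)) {
    cov <- coverage_list[[sp]]
    d <- target_depth(cov$reads_plus + cov$reads_minus, cov$covered_bases,
                      read_length)
    m[as.character(cov$target_id), sp] <- d
  }
  m
}

#' Reliably enriched targets per species
#'
#' A target is reliably enriched for a species when its depth strictly
#' exceeds `threshold` in every specimen of that species -- a conservative
#' rule chosen so that retained targets have a high expectation of
#' genotyping success in downstream (e.g. wood identification) assays.
#'
#' @param depths Depth matrix, targets x specimens (see [depth_matrix()]).
#' @param species Named character vector mapping specimen id to species;
#'   every column of `depths` must be assigned.
#' @param threshold Depth threshold (default 10); comparison is strict `>`.
#' @return Named list (one element per species) of retained target ids.
#' @export
reliably_enriched_targets <- function(depths, species, threshold = 10) {
  stopifnot(is.matrix(depths))
  unassigned <- setdiff(colnames(depths), names(species))
  if (length(unassigned) > 0) {
    stop_capkit(sprintf("specimens without species assignment: %s",
                        paste(unassigned, collapse = ", ")),
                "capkit_unassigned_specimen")
  }
  species <- species[colnames(depths)]
  out <- lapply(split(colnames(depths), species), function(cols) {
    if (length(cols) == 0) stop_capkit("empty species group", "capkit_empty_group")
    keep <- rowSums(depths[, cols, drop = FALSE] > threshold) == length(cols)
    rownames(depths)[keep]
  })
  out[unique(species)]
}

#' Deplete organelle reads and subsample a library
#'
#' Cross-taxon capture-efficiency comparisons are biased by library size
#' and organelle genome abundance; both are removed by discarding
#' organelle-labelled reads and drawing a fixed-size uniform subsample of
#' what remains. Read classification (e.g. 90% identity mapping to a
#' chloroplast reference) happens upstream; this function consumes
#' per-read category labels.
#'
#' @param labels Character vector of per-read labels; reads labelled
#'   `"organelle"` are removed first.
#' @param n Subsample size (default 1e6).
#' @param seed Integer seed; the subsample is deterministic per seed.
#' @return Integer vector of retained read indices into `labels` (length
#'   exactly `n`, sorted).
#' @section Errors: signals a condition of class `capkit_shortfall` when
#'   fewer than `n` non-organelle reads are available; such libraries are
#'   typically excluded from normalized-efficiency analyses.
#' @export
deplete_and_subsample <- function(labels, n = 1e6, seed) {
  keep <- which(labels != "organelle")
  if (length(keep) < n) {
    stop_capkit(sprintf("library yields %d non-organelle reads, fewer than the %d required",
                        length(keep), as.integer(n)),
                "capkit_shortfall")
  }
  with_seed(seed, sort(sample(keep, n)))
}

#' Welch's unequal-variance two-sample t-test
#'
#' The unpaired t-test with the Welch-Satterthwaite degrees-of-freedom
#' approximation, used to compare mean on-target yield (or depth) between
#' specimen groups whose variances differ by orders of magnitude.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2, with
#'   nonzero variance in at least one group.
#' @return A list with `t`, `df` (non-integer in general) and two-sided `p`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_capkit("each group needs at least 2 observations", "capkit_degenerate_group")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    stop_capkit("both groups have zero variance", "capkit_degenerate_group")
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Per-specimen enrichment summary and group means
#'
#' Builds one row per specimen from category tallies (and optional
#' organelle consensus statistics), recomputing the percent columns from
#' the count columns, then appends arithmetic group means of every
#' numeric column.
#'
#' @param tallies `data.frame` with columns `specimen`, `species`,
#'   `group`, `total_reads`, `on_target_reads`, `organelle_reads`.
#' @return List with `specimens` (per-specimen rows incl. `on_target_pct`
#'   and `organelle_pct`) and `group_means` (one row per group).
#' @export
panel_summary <- function(tallies) {
  need <- c("specimen", "species", "group", "total_reads",
            "on_target_reads", "organelle_reads")
  missing <- setdiff(need, names(tallies))
  if (length(missing) > 0) {
    stop_capkit(paste("tallies missing columns:", paste(missing, collapse = ", ")),
                "capkit_bad_tallies")
  }
  rows <- tallies
  rows$on_target_pct <- percent_on_target(rows$on_target_reads, rows$total_reads)
  rows$organelle_pct <- percent_on_target(rows$organelle_reads, rows$total_reads)
  num <- names(rows)[vapply(rows, is.numeric, logical(1))]
  gm <- do.call(rbind, lapply(split(rows, rows$group), function(g) {
    cbind(data.frame(group = g$group[1], n = nrow(g)),
          as.data.frame(as.list(colMeans(g[num]))))
  }))
  rownames(gm) <- NULL
  list(specimens = rows, group_means = gm)
}

#' Load the shipped 43-specimen Meliaceae capture panel metrics
#'
#' Published per-specimen sequencing and capture metrics for a diversity
#' panel of 43 Meliaceae specimens (24 *Cedrela*, 19 from three other
#' genera): sequence yield, on-target yield and percentage, chloroplast
#' yield, percentage, depth and reference coverage, and the percentage of
#' N bases in each reference-guided chloroplast assembly. Used as the
#' desk-scale fixture for enrichment statistics.
#'
#' @param path Path to the TSV; defaults to the copy installed with the
#'   package.
#' @return A `data.frame`, one row per specimen.
#' @export
read_panel_metrics <- function(path = system.file("extdata",
                                                  "meliaceae_capture_panel.tsv",
                                                  package = "capkit")) {
  read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
}
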