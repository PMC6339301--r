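#' Run the capture-analysis stages end to end
#'
#' Executes the dependent stages in order -- target selection, probe
#' design, capture QC, per-site F_ST -- plus the independent organelle
#' consensus stage, from a single configuration, writing every stage
#' output and a run manifest (config hash, per-file MD5 checksums,
#' timestamps) under `out_dir`. Deterministic stages reproduce identical
#' checksums on re-run; when `force = FALSE` a stage whose outputs already
#' exist is skipped unless an upstream stage re-executed.
#'
#' @param config Named list. Recognized entries: `coverage` (path to a
#'   coverage TSV; required for selection), `transcriptome` (FASTA path,
#'   optional -- enables sequence extraction and probe design),
#'   `rank_window` (default `c(5000, 15000)`), `max_masked_frac` (0.5),
#'   `probe_length` (100), `probes_per_target` (2), `specimen_coverage`
#'   (named list of per-specimen coverage TSV paths), `groups` (path to a
#'   TSV `specimen  species  group`), `depth_threshold` (10), `read_length`
#'   (101), `vcf` (path), `pop_map` (path to `specimen  population` TSV),
#'   `maf_min` (0.05), `qual_min` (500), `min_pop_size` (2), `pileup`
#'   (path), `consensus_min_depth` (2), `fst_threshold` (0.5), `seed`.
#' @param out_dir Output directory (created if needed).
#' @param force Re-run stages whose outputs already exist.
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  defaults <- list(rank_window = c(5000, 15000), max_masked_frac = 0.5,
                   probe_length = 100, probes_per_target = 2,
                   depth_threshold = 10, read_length = 101,
                   maf_min = 0.05, qual_min = 500, min_pop_size = 2,
                   consensus_min_depth = 2, fst_threshold = 0.5, seed = 1)
  provenance <- ifelse(names(defaults) %in% names(config), "config", "default")
  names(provenance) <- names(defaults)
  cfg <- utils::modifyList(defaults, config)
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "capkit", version = as.character(utils::packageVersion("capkit")),
                   config = cfg[order(names(cfg))],
                   parameter_provenance = as.list(provenance),
                   stages = list())
  ran_upstream <- FALSE

  run_stage <- function(name, outputs, fun) {
    exists_all <- all(file.exists(file.path(out_dir, outputs)))
    if (exists_all && !force && !ran_upstream) {
      manifest$stages[[name]] <<- list(status = "skipped",
                                       outputs = file.path(out_dir, outputs))
      return(invisible(NULL))
    }
    t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    res <- tryCatch(fun(), error = function(e) {
      stop_capkit(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                  "capkit_stage_failure")
    })
    paths <- file.path(out_dir, outputs)
    manifest$stages[[name]] <<- list(
      status = "ran", started = t0,
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      outputs = paths,
      checksums = as.list(tools::md5sum(paths))
    )
    ran_upstream <<- TRUE
    invisible(res)
  }

  state <- new.env()
  if (!is.null(cfg$coverage)) {
    run_stage("select_targets", c("ranking.tsv", "targets.tsv"), function() {
      cov <- read_coverage(cfg$coverage)
      ranking <- rank_by_rpk(cov)
      sel <- select_rank_window(ranking, cfg$rank_window[1], cfg$rank_window[2])
      ranking$selected <- ranking$target_id %in% sel$target_id
      write.table(ranking, file.path(out_dir, "ranking.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      if (!is.null(cfg$transcriptome)) {
        tx <- read_fasta(cfg$transcriptome)
        state$targets <- extract_targets(sel, tx, cfg$max_masked_frac)
      } else {
        state$targets <- data.frame(target_id = sel$target_id,
                                    sequence = NA_character_,
                                    length = NA_integer_)
      }
      write.table(state$targets[, c("target_id", "length")],
                  file.path(out_dir, "targets.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    })
    if (!is.null(cfg$transcriptome)) {
      run_stage("design_probes", c("probes.fasta", "probes.bed"), function() {
        if (is.null(state$targets)) {
          tx <- read_fasta(cfg$transcriptome)
          ranking <- rank_by_rpk(read_coverage(cfg$coverage))
          sel <- select_rank_window(ranking, cfg$rank_window[1], cfg$rank_window[2])
          state$targets <- extract_targets(sel, tx, cfg$max_masked_frac)
        }
        probes <- tile_probes(state$targets, cfg$probe_length, cfg$probes_per_target)
        write_fasta(setNames(probes$sequence, probes$probe_id),
                    file.path(out_dir, "probes.fasta"))
        write.table(probes[, c("target_id", "start", "end", "probe_id")],
                    file.path(out_dir, "probes.bed"), sep = "\t",
                    quote = FALSE, row.names = FALSE, col.names = FALSE)
      })
    }
  }
  if (!is.null(cfg$specimen_coverage) && !is.null(cfg$groups)) {
    run_stage("capture_qc", c("depth_matrix.tsv", "reliably_enriched.tsv"), function() {
      covs <- lapply(cfg$specimen_coverage, read_coverage)
      groups <- read.delim(cfg$groups, stringsAsFactors = FALSE)
      dm <- depth_matrix(covs, cfg$read_length)
      write.table(data.frame(target_id = rownames(dm), dm, check.names = FALSE),
                  file.path(out_dir, "depth_matrix.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      rel <- reliably_enriched_targets(dm, setNames(groups$species, groups$specimen),
                                       cfg$depth_threshold)
      out <- data.frame(
        species = rep(names(rel), lengths(rel)),
        target_id = unlist(rel, use.names = FALSE)
      )
      write.table(out, file.path(out_dir, "reliably_enriched.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    })
  }
  if (!is.null(cfg$vcf) && !is.null(cfg$pop_map)) {
    run_stage("snp_fst", c("fst.tsv", "fst_summary.json", "candidates.tsv"), function() {
      vs <- read_vcf_genotypes(cfg$vcf)
      pm <- read.delim(cfg$pop_map, stringsAsFactors = FALSE)
      pops <- setNames(pm$population, pm$specimen)
      filt <- stringent_filter(vs, cfg$maf_min, cfg$qual_min)
      fst <- weir_cockerham_fst(filt, pops, cfg$min_pop_size)
      write.table(fst, file.path(out_dir, "fst.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      summ <- fst_distribution(fst)
      jsonlite::write_json(summ, file.path(out_dir, "fst_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      cand <- candidate_diagnostic_snps(fst, cfg$fst_threshold)
      write.table(cand, file.path(out_dir, "candidates.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    })
  }
  if (!is.null(cfg$pileup)) {
    run_stage("consensus", c("consensus.fasta", "consensus_stats.json"), function() {
      p <- read_pileup(cfg$pileup)
      cons <- call_consensus(p, cfg$consensus_min_depth)
      write_fasta(setNames(cons$sequence, "consensus"),
                  file.path(out_dir, "consensus.fasta"))
      stats <- coverage_stats(p)
      stats$n_base_pct <- count_n_bases(cons$sequence)
      jsonlite::write_json(stats, file.path(out_dir, "consensus_stats.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }

  cfg_json <- jsonlite::toJSON(manifest$config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest$config_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

validate_config <- function(cfg) {
  w <- cfg$rank_window
  if (length(w) != 2 || w[1] > w[2] || w[1] < 1) {
    stop_capkit("invalid rank_window: need 1 <= lo <= hi", "capkit_bad_config")
  }
  if (cfg$maf_min < 0 || cfg$maf_min > 0.5) {
    stop_capkit("maf_min must be in [0, 0.5]", "capkit_bad_config")
  }
  for (nm in c("probe_length", "probes_per_target", "min_pop_size",
               "consensus_min_depth")) {
    if (cfg[[nm]] < 1) stop_capkit(sprintf("%s must be >= 1", nm), "capkit_bad_config")
  }
  invisible(cfg)
}

#' Validate input file formats
#'
#' Checks FASTA, VCF, coverage-TSV and pileup-TSV dialect rules and
#' reports violations with line numbers. An empty report means all files
#' passed.
#'
#' @param paths Character vector of file paths; format is inferred from
#'   the extension (`.fa`/`.fasta`, `.vcf`, `.tsv` by header).
#' @return `data.frame` with `path`, `line`, `message` (zero rows when
#'   clean).
#' @export
validate_formats <- function(paths) {
  probs <- list()
  note <- function(path, line, msg) {
    probs[[length(probs) + 1]] <<- data.frame(path = path, line = line,
                                              message = msg,
                                              stringsAsFactors = FALSE)
  }
  for (path in paths) {
    if (!file.exists(path)) { note(path, NA, "unreadable: file not found"); next }
    lines <- readLines(path, warn = FALSE)
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("fa", "fasta", "fna")) {
      if (length(lines) == 0 || !startsWith(lines[1], ">")) {
        note(path, 1, "FASTA must start with a '>' header")
      }
      hdr <- which(startsWith(lines, ">"))
      for (h in hdr) {
        if (h == length(lines) || startsWith(lines[h + 1], ">")) {
          note(path, h, "truncated FASTA record: header with no sequence")
        }
      }
      seq_lines <- setdiff(seq_along(lines), hdr)
      bad <- seq_lines[grepl("[^ACGTNacgtn-]", lines[seq_lines])]
      for (b in bad) note(path, b, "non-nucleotide characters in sequence")
    } else if (ext == "vcf") {
      if (length(lines) == 0 || lines[1] != "##fileformat=VCFv4.2") {
        note(path, 1, "missing ##fileformat=VCFv4.2 header")
      }
      chrom <- which(startsWith(lines, "#CHROM"))
      if (length(chrom) != 1) {
        note(path, NA, "missing #CHROM column header")
      } else {
        cols <- strsplit(lines[chrom], "\t")[[1]]
        if (length(cols) < 10 || cols[9] != "FORMAT") {
          note(path, chrom, "no FORMAT column: GT field unavailable")
        } else {
          body <- lines[seq.int(chrom + 1, length.out = length(lines) - chrom)]
          no_gt <- which(!grepl("(^|:)GT($|:)",
                                vapply(strsplit(body, "\t"), function(x)
                                  if (length(x) >= 9) x[9] else "", character(1))))
          for (b in no_gt) note(path, chrom + b, "record FORMAT lacks GT field")
        }
      }
    } else if (ext == "tsv") {
      if (length(lines) == 0) { note(path, 1, "empty TSV"); next }
      header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
      ncol_expected <- length(strsplit(lines[1], "\t")[[1]])
      bad <- which(lengths(strsplit(lines, "\t")) != ncol_expected)
      for (b in setdiff(bad, 1)) {
        note(path, b, sprintf("expected %d tab-separated fields", ncol_expected))
      }
      if (identical(header[1:2], c("pos", "A")) || identical(header[1], "id")) {
        # recognized capkit dialects; no further checks beyond rectangularity
      }
    } else {
      note(path, NA, sprintf("unrecognized format: .%s", ext))
    }
  }
  if (length(probs) == 0) {
    return(data.frame(path = character(), line = integer(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, probs)
}
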