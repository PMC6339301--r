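#' Generate a synthetic transcriptome with planted copy numbers
#'
#' Emulates a de novo leaf transcriptome assembly: transcript models of
#' variable length (all >= 200 bp, the usual assembly length cut-off),
#' each carrying a true genomic copy number drawn from
#' `copy_number_weights`. The copy number is the planted truth that
#' coverage simulation and low-copy target selection are tested against.
#'
#' @param n_transcripts Number of transcript models (>= 1).
#' @param length_range Integer pair, min/max transcript length in bp;
#'   minimum must be >= 200.
#' @param copy_number_weights Named numeric vector of sampling weights;
#'   names are copy numbers (e.g. `c("1" = 0.8, "10" = 0.2)`). Default:
#'   all single-copy.
#' @param seed Integer seed; output is byte-identical per seed.
#' @param emit_sequences Generate nucleotide sequences (default `TRUE`);
#'   set `FALSE` when only lengths/copy numbers are needed (large
#'   ranking experiments).
#' @return List with `info` (`data.frame`: `id`, `length`,
#'   `true_copy_number`), `sequences` (named character vector, or `NULL`),
#'   `seed`.
#' @export
make_transcriptome <- function(n_transcripts, length_range = c(200, 2000),
                               copy_number_weights = c("1" = 1), seed,
                               emit_sequences = TRUE) {
  stopifnot(n_transcripts >= 1, length(length_range) == 2)
  if (length_range[1] < 200) {
    stop_capkit("minimum transcript length must be >= 200 bp", "capkit_bad_length")
  }
  if (length_range[1] > length_range[2]) {
    stop_capkit("invalid length range", "capkit_bad_length")
  }
  copies <- as.integer(names(copy_number_weights))
  if (anyNA(copies) || any(copies < 1)) {
    stop_capkit("copy_number_weights names must be positive integers",
                "capkit_bad_weights")
  }
  with_seed(seed, {
    len <- length_range[1] - 1L +
      sample.int(length_range[2] - length_range[1] + 1L, n_transcripts,
                 replace = TRUE)
    cn <- copies[sample.int(length(copies), n_transcripts, replace = TRUE,
                            prob = copy_number_weights)]
    seqs <- NULL
    if (emit_sequences) {
      bases <- sample(c("A", "C", "G", "T"), sum(len), replace = TRUE)
      ends <- cumsum(len)
      seqs <- substring(paste(bases, collapse = ""), ends - len + 1, ends)
    }
    ids <- sprintf("tx%0*d", max(5, nchar(n_transcripts)), seq_len(n_transcripts))
    if (!is.null(seqs)) names(seqs) <- ids
    list(
      info = data.frame(id = ids, length = len, true_copy_number = cn,
                        stringsAsFactors = FALSE),
      sequences = seqs,
      seed = seed
    )
  })
}

#' Simulate genomic-read coverage over a transcriptome
#'
#' Emulates mapping short genomic shotgun reads to a transcriptome: the
#' expected mapped reads for transcript t are
#' `rate * (length_t / 1000) * copy_number_t`, drawn from a negative
#' binomial with the given dispersion (`size` parameterization;
#' `dispersion = Inf` gives Poisson counts). Negative binomial is used
#' because empirical per-target read counts are heavily overdispersed --
#' RPK in real panels spans several orders of magnitude. Covered bases
#' follow the Lander-Waterman expectation for the given read length,
#' capped at the transcript length.
#'
#' @param fixture Output of [make_transcriptome()].
#' @param reads_per_kbp_per_copy Expected mapped reads per kbp per genomic
#'   copy (must be > 0).
#' @param dispersion Negative-binomial size parameter; `Inf` for Poisson.
#' @param read_length Read length used for the covered-bases model
#'   (default 50, i.e. truncated subreads).
#' @param seed Integer seed.
#' @return Coverage table: `data.frame` with `target_id`, `target_length`,
#'   `reads_plus`, `reads_minus`, `covered_bases`.
#' @export
simulate_genomic_coverage <- function(fixture, reads_per_kbp_per_copy,
                                      dispersion = 10, read_length = 50, seed) {
  if (reads_per_kbp_per_copy <= 0) {
    stop_capkit("rate must be > 0", "capkit_bad_rate")
  }
  info <- fixture$info
  mu <- reads_per_kbp_per_copy * (info$length / 1000) * info$true_copy_number
  with_seed(seed, {
    reads <- if (is.finite(dispersion)) {
      rnbinom(nrow(info), mu = mu, size = dispersion)
    } else {
      rpois(nrow(info), mu)
    }
    plus <- rbinom(nrow(info), reads, 0.5)
    covered <- pmin(info$length,
                    round(info$length * (1 - exp(-reads * read_length / info$length))))
    data.frame(
      target_id = info$id,
      target_length = info$length,
      reads_plus = plus,
      reads_minus = reads - plus,
      covered_bases = covered,
      stringsAsFactors = FALSE
    )
  })
}

#' Specify a capture diversity panel
#'
#' @param specimens `data.frame` with `specimen_id`, `species_id`,
#'   `genus_group` (`"in_genus"` or `"out_genus"`: within the probe-design
#'   genus or a more distant relative).
#' @param library_size Sequenced reads per specimen (> 0).
#' @param organelle_fraction Expected organelle read share in `[0, 1]`.
#' @param enrichment_bias Named pair of capture probabilities in `(0, 1]`
#'   for `in_genus` / `out_genus`; out-genus must not exceed in-genus
#'   (probes transfer imperfectly to divergent genomes).
#' @param seed Integer seed.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(specimens, library_size, organelle_fraction,
                       enrichment_bias = c(in_genus = 0.35, out_genus = 0.015),
                       seed) {
  stopifnot(is.data.frame(specimens))
  if (nrow(specimens) == 0) stop_capkit("empty panel", "capkit_empty")
  if (anyDuplicated(specimens$specimen_id)) {
    stop_capkit("duplicate specimen ids", "capkit_duplicate_ids")
  }
  stopifnot(all(specimens$genus_group %in% c("in_genus", "out_genus")),
            library_size > 0,
            organelle_fraction >= 0, organelle_fraction <= 1,
            all(enrichment_bias > 0), all(enrichment_bias <= 1))
  if (enrichment_bias[["out_genus"]] > enrichment_bias[["in_genus"]]) {
    stop_capkit("out-genus enrichment bias must be <= in-genus",
                "capkit_bad_bias")
  }
  structure(list(specimens = specimens, library_size = library_size,
                 organelle_fraction = organelle_fraction,
                 enrichment_bias = enrichment_bias, seed = seed),
            class = "panel_spec")
}

#' Simulate a target-capture experiment over a diversity panel
#'
#' Per specimen, each sequenced read falls into one of three categories:
#' organelle (probability `organelle_fraction`), on-target (probability
#' `enrichment_bias[group]` among non-organelle reads), or off-target.
#' On-target reads are spread over targets in proportion to target length,
#' yielding a per-specimen coverage table. Category tallies always sum to
#' the library size; the tallies are also returned as a truth sidecar for
#' downstream QC tests.
#'
#' @param targets Target set: `data.frame` with `target_id` and `length`
#'   (or `target_length`) columns.
#' @param panel A [panel_spec()].
#' @param read_length Read length for the covered-bases model (default 101).
#' @return List with `tallies` (`data.frame`: specimen, species, group,
#'   total_reads, on_target_reads, organelle_reads, other_reads) and
#'   `coverage` (named list of per-specimen coverage tables).
#' @export
simulate_capture_experiment <- function(targets, panel, read_length = 101) {
  stopifnot(inherits(panel, "panel_spec"))
  if (nrow(targets) == 0) stop_capkit("empty target set", "capkit_empty")
  tlen <- if ("target_length" %in% names(targets)) targets$target_length else targets$length
  sp <- panel$specimens
  with_seed(panel$seed, {
    tallies <- do.call(rbind, lapply(seq_len(nrow(sp)), function(i) {
      L <- panel$library_size
      n_org <- rbinom(1, L, panel$organelle_fraction)
      bias <- panel$enrichment_bias[[sp$genus_group[i]]]
      n_on <- rbinom(1, L - n_org, bias)
      data.frame(specimen = sp$specimen_id[i], species = sp$species_id[i],
                 group = sp$genus_group[i], total_reads = L,
                 on_target_reads = n_on, organelle_reads = n_org,
                 other_reads = L - n_org - n_on, stringsAsFactors = FALSE)
    }))
    coverage <- lapply(seq_len(nrow(sp)), function(i) {
      reads <- as.vector(rmultinom(1, tallies$on_target_reads[i],
                                   prob = tlen / sum(tlen)))
      plus <- rbinom(length(reads), reads, 0.5)
      data.frame(
        target_id = targets$target_id,
        target_length = tlen,
        reads_plus = plus,
        reads_minus = reads - plus,
        covered_bases = pmin(tlen, round(tlen * (1 - exp(-reads * read_length / tlen)))),
        stringsAsFactors = FALSE
      )
    })
    names(coverage) <- sp$specimen_id
    list(tallies = tallies, coverage = coverage)
  })
}

#' Plant per-species allele-frequency truth for a SNP panel
#'
#' Sites fall in three classes: `fixed` (frequency 1 in one species, 0 in
#' all others -- a fixed species difference, the diagnostic class),
#' `shared` (one common frequency in all species), and `private`
#' (intermediate frequency in one species, 0 elsewhere).
#'
#' @param n_sites Number of sites.
#' @param species Character vector of species names (>= 2).
#' @param class_probs Named probabilities over `fixed`, `shared`,
#'   `private`.
#' @param shared_freq_range,private_freq_range Frequency ranges for the
#'   non-fixed classes.
#' @param seed Integer seed.
#' @return List of class `genotype_truth`: `sites` (`data.frame` with
#'   `site_id`, `chrom`, `pos`, `class`), `freqs` (sites x species matrix),
#'   `species`.
#' @export
make_genotype_truth <- function(n_sites, species,
                                class_probs = c(fixed = 0.2, shared = 0.6,
                                                private = 0.2),
                                shared_freq_range = c(0.2, 0.8),
                                private_freq_range = c(0.3, 0.7),
                                seed) {
  stopifnot(length(species) >= 2, n_sites >= 1)
  with_seed(seed, {
    cls <- sample(names(class_probs), n_sites, replace = TRUE,
                  prob = class_probs)
    freqs <- matrix(0, n_sites, length(species),
                    dimnames = list(NULL, species))
    for (i in seq_len(n_sites)) {
      if (cls[i] == "fixed") {
        freqs[i, sample(length(species), 1)] <- 1
      } else if (cls[i] == "shared") {
        freqs[i, ] <- runif(1, shared_freq_range[1], shared_freq_range[2])
      } else {
        freqs[i, sample(length(species), 1)] <-
          runif(1, private_freq_range[1], private_freq_range[2])
      }
    }
    sites <- data.frame(
      site_id = sprintf("site%05d", seq_len(n_sites)),
      chrom = sprintf("tgt%05d", ((seq_len(n_sites) - 1) %/% 10) + 1),
      pos = ((seq_len(n_sites) - 1) %% 10) * 50 + 1,
      class = cls, stringsAsFactors = FALSE
    )
    structure(list(sites = sites, freqs = freqs, species = species),
              class = "genotype_truth")
  })
}

#' Simulate a multi-sample VCF from planted allele frequencies
#'
#' Draws diploid genotypes per specimen from its species' planted allele
#' frequency (two Bernoulli allele draws), optionally masking genotypes at
#' `missing_rate` and assigning site qualities uniformly over
#' `qual_range`. With `exact_freqs = TRUE` genotype counts are assigned
#' deterministically so that each species' sample allele frequency equals
#' the planted frequency as closely as 2n alleles allow ("full sampling");
#' this is the regime in which planted fixed differences are exactly the
#' theta = 1 sites downstream.
#'
#' @param truth Output of [make_genotype_truth()].
#' @param n_per_species Specimens per species: single number or named
#'   vector (each >= 1).
#' @param missing_rate Per-genotype missingness probability.
#' @param qual_range Site quality range (phred-scaled).
#' @param exact_freqs Deterministic genotype counts (see above).
#' @param seed Integer seed.
#' @param path Optional file path; when given, a VCF v4.2 document is
#'   written there.
#' @return A [variant_set()] with attributes `populations` (named vector
#'   specimen -> species) and `truth_class` (per-site planted class).
#' @export
simulate_genotype_vcf <- function(truth, n_per_species, missing_rate = 0,
                                  qual_range = c(600, 3000),
                                  exact_freqs = FALSE, seed, path = NULL) {
  stopifnot(inherits(truth, "genotype_truth"))
  species <- truth$species
  if (length(n_per_species) == 1 && is.null(names(n_per_species))) {
    n_per_species <- setNames(rep(n_per_species, length(species)), species)
  }
  stopifnot(all(species %in% names(n_per_species)),
            all(n_per_species >= 1))
  specimens <- unlist(lapply(species, function(s) {
    sprintf("%s_%02d", s, seq_len(n_per_species[[s]]))
  }))
  pops <- setNames(rep(species, n_per_species[species]), specimens)
  n_sites <- nrow(truth$sites)
  with_seed(seed, {
    gt <- matrix("", n_sites, length(specimens),
                 dimnames = list(NULL, specimens))
    for (s in species) {
      cols <- which(pops == s)
      n <- length(cols)
      for (i in seq_len(n_sites)) {
        p <- truth$freqs[i, s]
        if (exact_freqs) {
          n_alt <- round(2 * n * p)
          g <- c(rep("1/1", n_alt %/% 2), rep("0/1", n_alt %% 2))
          g <- c(g, rep("0/0", n - length(g)))
        } else {
          a1 <- rbinom(n, 1, p)
          a2 <- rbinom(n, 1, p)
          g <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
        }
        gt[i, cols] <- g
      }
    }
    if (missing_rate > 0) {
      gt[matrix(rbinom(length(gt), 1, missing_rate) == 1, nrow(gt))] <- "./."
    }
    qual <- round(runif(n_sites, qual_range[1], qual_range[2]), 1)
    sites <- data.frame(
      chrom = truth$sites$chrom, pos = truth$sites$pos,
      ref = "A", alt = "G", qual = qual, stringsAsFactors = FALSE
    )
    vs <- variant_set(sites, gt)
    attr(vs, "populations") <- pops
    attr(vs, "truth_class") <- truth$sites$class
    if (!is.null(path)) write_vcf(vs, path)
    vs
  })
}

#' Simulate an organelle pileup with planted substitutions
#'
#' Per-position depth is Poisson with the given rate profile; every read
#' reports the true base (read-level error models are out of scope), so
#' the pileup at position i carries `depth_i` counts of the true base.
#' The truth consensus equals the reference with the substitutions
#' applied and `N` wherever simulated depth is below 2.
#'
#' @param reference Nonempty reference sequence (character scalar, ACGT).
#' @param depth_profile Per-base expected depth: scalar or length-L vector.
#' @param variants Optional `data.frame` with `pos`, `base` planting
#'   substitutions relative to the reference.
#' @param seed Integer seed.
#' @return List with `pileup` (`pos`, `A`, `C`, `G`, `T`),
#'   `truth_consensus`, `depth`.
#' @export
simulate_organelle_pileup <- function(reference, depth_profile,
                                      variants = NULL, seed) {
  stopifnot(is.character(reference), length(reference) == 1)
  L <- nchar(reference)
  if (L == 0) stop_capkit("empty reference", "capkit_empty")
  rate <- rep_len(depth_profile, L)
  true_seq <- strsplit(toupper(reference), "")[[1]]
  if (!is.null(variants) && nrow(variants) > 0) {
    if (any(variants$pos < 1 | variants$pos > L)) {
      stop_capkit("variant position outside reference", "capkit_bad_position")
    }
    true_seq[variants$pos] <- toupper(variants$base)
  }
  with_seed(seed, {
    depth <- rpois(L, rate)
    counts <- matrix(0L, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    counts[cbind(seq_len(L), match(true_seq, c("A", "C", "G", "T")))] <- depth
    truth <- true_seq
    truth[depth < 2] <- "N"
    list(
      pileup = data.frame(pos = seq_len(L), counts),
      truth_consensus = paste(truth, collapse = ""),
      depth = depth
    )
  })
}

#' Simulate a variant table with planted variant classes
#'
#' Generates sites whose alleles realize a planted class label --
#' biallelic SNP, indel, or multi-allelic SNP -- for testing variant
#' classification, together with simple diploid genotypes.
#'
#' @param n_sites Number of sites.
#' @param class_probs Named probabilities over the three classes.
#' @param n_specimens Number of specimens in the genotype matrix.
#' @param seed Integer seed.
#' @return A [variant_set()] with attribute `truth_class`.
#' @export
simulate_variant_table <- function(n_sites,
                                   class_probs = c(biallelic_snp = 0.897,
                                                   indel = 0.063,
                                                   multiallelic_snp = 0.040),
                                   n_specimens = 4, seed) {
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    cls <- sample(names(class_probs), n_sites, replace = TRUE,
                  prob = class_probs)
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(seq_len(n_sites), function(i) {
      others <- setdiff(bases, ref[i])
      switch(cls[i],
        biallelic_snp = sample(others, 1),
        indel = paste0(ref[i], sample(bases, 1)),
        multiallelic_snp = paste(sample(others, 2), collapse = ","))
    }, character(1))
    n_alt <- 1L + (cls == "multiallelic_snp")
    gt <- matrix(
      paste(sample(0:1, n_sites * n_specimens, replace = TRUE),
            sample(0:1, n_sites * n_specimens, replace = TRUE), sep = "/"),
      n_sites, n_specimens,
      dimnames = list(NULL, sprintf("sp%02d", seq_len(n_specimens)))
    )
    sites <- data.frame(
      chrom = sprintf("tgt%05d", ((seq_len(n_sites) - 1) %/% 20) + 1),
      pos = ((seq_len(n_sites) - 1) %% 20) * 37 + 1,
      ref = ref, alt = alt,
      qual = round(runif(n_sites, 10, 3000), 1),
      stringsAsFactors = FALSE
    )
    vs <- variant_set(sites, gt)
    attr(vs, "truth_class") <- cls
    vs
  })
}
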