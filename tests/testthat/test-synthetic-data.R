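test_that("transcriptome generation is deterministic and respects constraints", {
  f1 <- make_transcriptome(10, c(200, 1000), seed = 7)
  f2 <- make_transcriptome(10, c(200, 1000), seed = 7)
  expect_identical(f1, f2)
  f3 <- make_transcriptome(10, c(200, 1000), seed = 8)
  expect_false(identical(f1$sequences, f3$sequences))
  expect_true(all(f1$info$length >= 200))
  expect_true(all(f1$info$true_copy_number == 1))
  expect_false(anyDuplicated(f1$info$id) > 0)
  expect_true(all(grepl("^[ACGT]+$", f1$sequences)))
  expect_equal(nchar(f1$sequences), setNames(f1$info$length, f1$info$id))
  # degenerate size: one 200-bp transcript with planted copy 5
  f4 <- make_transcriptome(1, c(200, 200), c("5" = 1), seed = 1)
  expect_equal(f4$info$length, 200)
  expect_equal(f4$info$true_copy_number, 5L)
  expect_error(make_transcriptome(5, c(100, 500), seed = 1),
               class = "capkit_bad_length")
})

test_that("copy-number histogram matches the generating weights", {
  w <- c("1" = 0.5, "2" = 0.3, "10" = 0.2)
  f <- make_transcriptome(1000, c(200, 400), w, seed = 3,
                          emit_sequences = FALSE)
  obs <- table(factor(f$info$true_copy_number, levels = c(1, 2, 10)))
  chi <- suppressWarnings(chisq.test(obs, p = w / sum(w)))
  expect_gt(chi$p.value, 0.001)
})

test_that("coverage counts follow the rate x length x copy mean", {
  # copy 1, length 1000, rate 1: mean over many transcripts ~ 1
  f <- make_transcriptome(5000, c(1000, 1000), seed = 2,
                          emit_sequences = FALSE)
  cov <- simulate_genomic_coverage(f, reads_per_kbp_per_copy = 1,
                                   dispersion = Inf, seed = 4)
  reads <- cov$reads_plus + cov$reads_minus
  expect_equal(mean(reads), 1, tolerance = 0.05)
  expect_true(all(cov$covered_bases <= cov$target_length))
  # RPK of a rate-0.8 record has expectation 0.8 (the selected-target RPK
  # regime)
  cov08 <- simulate_genomic_coverage(f, reads_per_kbp_per_copy = 0.8,
                                     dispersion = Inf, seed = 9)
  rpk <- compute_rpk(cov08$reads_plus, cov08$reads_minus, cov08$target_length)
  expect_equal(mean(rpk), 0.8, tolerance = 0.05)
  expect_error(simulate_genomic_coverage(f, 0, seed = 1),
               class = "capkit_bad_rate")
})

test_that("ten-copy transcripts draw ~10x the reads of single-copy ones", {
  f <- make_transcriptome(10000, c(1000, 1000),
                          c("1" = 0.5, "10" = 0.5), seed = 5,
                          emit_sequences = FALSE)
  cov <- simulate_genomic_coverage(f, reads_per_kbp_per_copy = 2,
                                   dispersion = 10, seed = 6)
  reads <- cov$reads_plus + cov$reads_minus
  one <- f$info$true_copy_number == 1
  expect_equal(mean(reads[!one]) / mean(reads[one]), 10, tolerance = 0.1)
})

test_that("capture tallies sum to library size and respect the planted fractions", {
  spec <- data.frame(specimen_id = c("i1", "i2", "o1"),
                     species_id = c("A", "A", "B"),
                     genus_group = c("in_genus", "in_genus", "out_genus"))
  tgt <- data.frame(target_id = sprintf("t%02d", 1:20),
                    length = rep(500, 20))
  p <- panel_spec(spec, library_size = 1e5, organelle_fraction = 0.1,
                  enrichment_bias = c(in_genus = 0.4, out_genus = 0.02),
                  seed = 11)
  sim <- simulate_capture_experiment(tgt, p)
  with(sim$tallies, expect_equal(on_target_reads + organelle_reads + other_reads,
                                 total_reads))
  # coverage table reads agree with the tally (truth sidecar comparison)
  for (s in sim$tallies$specimen) {
    expect_equal(on_target_yield(sim$coverage[[s]]),
                 sim$tallies$on_target_reads[sim$tallies$specimen == s])
  }
  # organelle_fraction 0 -> no organelle reads
  p0 <- panel_spec(spec, 1e4, organelle_fraction = 0, seed = 12)
  expect_true(all(simulate_capture_experiment(tgt, p0)$tallies$organelle_reads == 0))
  expect_error(simulate_capture_experiment(tgt[0, ], p0), class = "capkit_empty")
  expect_error(panel_spec(spec, 1e4, 0,
                          c(in_genus = 0.1, out_genus = 0.5), seed = 1),
               class = "capkit_bad_bias")
})

test_that("on-target fraction tracks enrichment bias", {
  spec <- data.frame(specimen_id = "s", species_id = "A",
                     genus_group = "in_genus")
  tgt <- data.frame(target_id = "t1", length = 1000)
  frac_at <- function(bias, seed) {
    p <- panel_spec(spec, 2e4, 0,
                    c(in_genus = bias, out_genus = bias), seed = seed)
    t <- simulate_capture_experiment(tgt, p)$tallies
    t$on_target_reads / t$total_reads
  }
  hi <- vapply(1:30, function(s) frac_at(1.0, s), numeric(1))
  lo <- vapply(1:30, function(s) frac_at(0.05, 100 + s), numeric(1))
  expect_true(all(hi > lo))
  # library 1e6, bias 0.4: binomial 99.9% interval around 0.4
  p <- panel_spec(spec, 1e6, 0, c(in_genus = 0.4, out_genus = 0.4), seed = 2)
  f <- with(simulate_capture_experiment(tgt, p)$tallies,
            on_target_reads / total_reads)
  ci <- qbinom(c(5e-4, 1 - 5e-4), 1e6, 0.4) / 1e6
  expect_gte(f, ci[1]); expect_lte(f, ci[2])
})

test_that("genotype truth plants the advertised class structure", {
  tr <- make_genotype_truth(500, c("sp1", "sp2", "sp3"), seed = 13)
  expect_true(all(tr$freqs >= 0 & tr$freqs <= 1))
  fixed <- tr$sites$class == "fixed"
  # fixed sites: frequency 1 in exactly one species, 0 elsewhere
  expect_true(all(rowSums(tr$freqs[fixed, ] == 1) == 1))
  expect_true(all(rowSums(tr$freqs[fixed, ] == 0) == 2))
  shared <- tr$sites$class == "shared"
  expect_true(all(apply(tr$freqs[shared, ], 1, function(x)
    length(unique(x)) == 1)))
})

test_that("simulated genotypes follow the planted frequencies and missingness", {
  tr <- make_genotype_truth(200, c("sp1", "sp2"), seed = 14)
  vs <- simulate_genotype_vcf(tr, n_per_species = 4, seed = 15)
  expect_equal(dim(vs$gt), c(200L, 8L))
  # missing_rate 1 -> everything missing, stringent filter retains nothing
  vs_miss <- simulate_genotype_vcf(tr, n_per_species = 4, missing_rate = 1,
                                   seed = 16)
  expect_true(all(vs_miss$gt == "./."))
  expect_equal(nrow(stringent_filter(vs_miss)$sites), 0)
  # determinism
  expect_identical(vs$gt,
                   simulate_genotype_vcf(tr, n_per_species = 4, seed = 15)$gt)
})

test_that("planted fixed sites yield theta 1 downstream under full sampling", {
  tr <- make_genotype_truth(300, c("sp1", "sp2", "sp3", "sp4"),
                            class_probs = c(fixed = 0.2, shared = 0.6,
                                            private = 0.2), seed = 18)
  vs <- simulate_genotype_vcf(tr, n_per_species = 4, exact_freqs = TRUE,
                              seed = 19)
  fst <- weir_cockerham_fst(vs, attr(vs, "populations"))
  fixed_truth <- which(attr(vs, "truth_class") == "fixed")
  theta_one <- which(!is.na(fst$theta) & abs(fst$theta - 1) <= 1e-9)
  expect_equal(theta_one, fixed_truth)
})

test_that("organelle pileup plants depth, variants and the 2X truth rule", {
  ref <- strrep("ACGT", 250)
  sim <- simulate_organelle_pileup(ref, depth_profile = 100, seed = 20)
  expect_equal(sim$truth_consensus, ref)
  expect_equal(nrow(sim$pileup), 1000)
  # zero-depth stretch is N in the truth consensus exactly there
  prof <- rep(100, 1000); prof[10:19] <- 0
  sim2 <- simulate_organelle_pileup(ref, prof, seed = 21)
  n_pos <- which(strsplit(sim2$truth_consensus, "")[[1]] == "N")
  expect_true(all(10:19 %in% n_pos))
  expect_true(all(sim2$depth[n_pos] < 2))
  expect_error(
    simulate_organelle_pileup("ACGT", 10,
                              variants = data.frame(pos = 9, base = "A"),
                              seed = 1),
    class = "capkit_bad_position")
})

test_that("child seeds differ across operations but are stable", {
  expect_identical(child_seed(1, "coverage"), child_seed(1, "coverage"))
  expect_false(child_seed(1, "coverage") == child_seed(1, "genotypes"))
  expect_false(child_seed(1, "coverage") == child_seed(2, "coverage"))
  expect_true(child_seed(2147483000, "x") < .Machine$integer.max)
})
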