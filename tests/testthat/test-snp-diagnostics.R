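make_vs <- function(ref, alt, qual = 1000, gt = NULL, n_spec = 2) {
  n <- length(ref)
  if (is.null(gt)) {
    gt <- matrix("0/1", n, n_spec,
                 dimnames = list(NULL, sprintf("s%d", seq_len(n_spec))))
  }
  variant_set(
    data.frame(chrom = sprintf("c%d", seq_len(n)), pos = seq_len(n),
               ref = ref, alt = alt, qual = rep_len(qual, n),
               stringsAsFactors = FALSE),
    gt
  )
}

test_that("variant classification separates SNPs, indels and multi-allelics", {
  empty <- classify_variants(make_vs(character(0), character(0))$sites)
  expect_equal(unname(empty$counts), c(0L, 0L, 0L))
  vs <- make_vs(c("A", "A", "A"), c("G", "G,T", "AG"))
  cl <- classify_variants(vs)
  expect_equal(cl$class, c("biallelic_snp", "multiallelic_snp", "indel"))
  expect_equal(cl$counts,
               c(biallelic_snp = 1L, indel = 1L, multiallelic_snp = 1L))
  # deletions (length-changing ref) are indels too
  expect_equal(classify_variants(make_vs("AT", "A"))$class, "indel")
  expect_error(classify_variants(make_vs("A", "Z")),
               class = "capkit_bad_alleles")
})

test_that("classification counts match planted truth on a synthetic table", {
  vs <- simulate_variant_table(1000, seed = 17)
  cl <- classify_variants(vs)
  truth <- attr(vs, "truth_class")
  expect_equal(cl$class, truth)
  expect_equal(unname(cl$counts[names(table(truth))]),
               unname(as.integer(table(truth))))
})

test_that("minor allele frequency counts called alleles only", {
  expect_equal(minor_allele_frequency(rep("0/1", 8)), 0.5)
  expect_equal(minor_allele_frequency(c(rep("0/0", 9), "0/1")), 0.05)
  # missing genotypes leave the denominator
  expect_equal(minor_allele_frequency(c("0/0", "1/1", "./.")), 0.5)
  expect_error(minor_allele_frequency(c("./.", "./.")),
               class = "capkit_all_missing")
  # brute-force recount over random draws
  set.seed(8)
  for (i in 1:20) {
    g <- random_gt_row(12, runif(1), missing_rate = 0.2)
    if (all(grepl("\\.", g))) next
    alleles <- unlist(strsplit(g[!grepl("\\.", g)], "/"))
    p <- mean(alleles == "1")
    expect_equal(minor_allele_frequency(g), min(p, 1 - p))
  }
})

test_that("stringent filter applies the biallelic / no-missing / MAF / qual rules", {
  gt_ok <- matrix(c("0/0", "0/1", "1/1", "0/1"), 1)
  colnames(gt_ok) <- sprintf("s%d", 1:4)
  sites <- data.frame(chrom = "c", pos = 1:5, ref = "A",
                      alt = c("G", "G", "G,T", "G", "G"),
                      qual = c(900, 900, 900, 400, 900))
  gt <- rbind(gt_ok,                               # passes
              c("0/0", "0/1", "./.", "0/1"),       # missing -> fails
              gt_ok,                               # multiallelic -> fails
              gt_ok,                               # qual 400 -> fails
              c("0/0", "0/0", "0/0", "0/1"))       # maf 1/8 = 0.125 passes
  vs <- variant_set(sites, gt)
  out <- stringent_filter(vs)
  expect_equal(out$sites$pos, c(1, 5))
  fc <- attr(out, "filter_counts")
  expect_equal(fc[["missing_gt"]], 1L)
  expect_equal(fc[["not_biallelic"]], 1L)
  expect_equal(fc[["low_qual"]], 1L)
  # boundary semantics: MAF inclusive at the cutoff, qual strictly above
  gt_b <- matrix(c(rep("0/0", 9), "0/1"), 1)
  colnames(gt_b) <- sprintf("s%d", 1:10)
  b <- variant_set(data.frame(chrom = "c", pos = 1, ref = "A", alt = "G",
                              qual = 500), gt_b)
  expect_equal(nrow(stringent_filter(b, maf_min = 0.05)$sites), 0)  # qual == 500
  b$sites$qual <- 501
  expect_equal(nrow(stringent_filter(b, maf_min = 0.05)$sites), 1)  # maf == 0.05
  # empty input passes through empty
  expect_equal(nrow(stringent_filter(make_vs(character(0), character(0),
                                             gt = matrix("", 0, 2)))$sites), 0)
})

test_that("stringent filter is order-invariant and idempotent", {
  vs <- simulate_variant_table(300, n_specimens = 6, seed = 23)
  gt <- vs$gt
  set.seed(2)
  gt[runif(length(gt)) < 0.1] <- "./."
  vs <- variant_set(vs$sites, gt)
  out <- stringent_filter(vs)
  # idempotent
  again <- stringent_filter(out)
  expect_equal(again$sites, out$sites)
  expect_equal(again$gt, out$gt)
  # permuting input rows permutes output rows only
  set.seed(1); perm <- sample(nrow(vs$sites))
  vs_p <- variant_set(vs$sites[perm, ], vs$gt[perm, , drop = FALSE])
  out_p <- stringent_filter(vs_p)
  key <- function(s) sort(paste(s$chrom, s$pos))
  expect_equal(key(out_p$sites), key(out$sites))
})

test_that("theta is 1 at complete fixation and undefined for monomorphic sites", {
  gt <- matrix(c("0/0", "0/0", "1/1", "1/1"), 1)
  colnames(gt) <- c("a1", "a2", "b1", "b2")
  pops <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  vs <- variant_set(data.frame(chrom = "c", pos = 1, ref = "A", alt = "G",
                               qual = 1000), gt)
  fst <- weir_cockerham_fst(vs, pops)
  expect_equal(fst$theta, 1)
  mono <- variant_set(vs$sites, matrix("0/0", 1, 4, dimnames = dimnames(gt)))
  expect_true(is.na(weir_cockerham_fst(mono, pops)$theta))
  # single population rejected
  expect_error(weir_cockerham_fst(vs, c(a1 = "A", a2 = "A", b1 = "A", b2 = "A")),
               class = "capkit_single_population")
})

test_that("variance components match the hand-derived 6-genotype configuration", {
  # pop1 = {AA, AA, Aa}, pop2 = {aa, Aa, aa}: worked through the
  # population/individual/gamete component formulas by hand:
  # a = 7/36, b = 0, c = 1/6, theta = 7/13
  gt <- matrix(c("0/0", "0/0", "0/1", "1/1", "0/1", "1/1"), 1)
  colnames(gt) <- c("p1a", "p1b", "p1c", "p2a", "p2b", "p2c")
  pops <- setNames(rep(c("P1", "P2"), each = 3), colnames(gt))
  vs <- variant_set(data.frame(chrom = "c", pos = 1, ref = "A", alt = "G",
                               qual = 1000), gt)
  fst <- weir_cockerham_fst(vs, pops)
  expect_equal(fst$a, 7 / 36, tolerance = 1e-12)
  expect_equal(fst$b, 0, tolerance = 1e-12)
  expect_equal(fst$c, 1 / 6, tolerance = 1e-12)
  expect_equal(fst$theta, 7 / 13, tolerance = 1e-12)
  # the independent ANOVA oracle agrees on the same configuration
  o <- oracle_wc_anova(gt[1, ], pops)
  expect_equal(o$a, 7 / 36, tolerance = 1e-12)
  expect_equal(o$theta, 7 / 13, tolerance = 1e-12)
})

test_that("estimator agrees with the ANOVA oracle on random configurations", {
  set.seed(99)
  pops <- setNames(rep(c("A", "B", "C"), times = c(4, 3, 5)),
                   sprintf("s%02d", 1:12))
  for (i in 1:40) {
    row <- unlist(lapply(c(A = 4, B = 3, C = 5), function(n)
      random_gt_row(n, runif(1, 0.05, 0.95))))
    names(row) <- names(pops)
    vs <- variant_set(data.frame(chrom = "c", pos = 1, ref = "A", alt = "G",
                                 qual = 1000),
                      matrix(row, 1, dimnames = list(NULL, names(pops))))
    got <- weir_cockerham_fst(vs, pops)
    want <- oracle_wc_anova(row, pops)
    expect_equal(got$a, want$a, tolerance = 1e-10)
    expect_equal(got$b, want$b, tolerance = 1e-10)
    expect_equal(got$c, want$c, tolerance = 1e-10)
    if (is.na(want$theta)) expect_true(is.na(got$theta))
    else expect_equal(got$theta, want$theta, tolerance = 1e-10)
  }
})

test_that("theta is exchangeable under within-population relabelling", {
  set.seed(12)
  pops <- setNames(rep(c("A", "B"), each = 5), sprintf("s%02d", 1:10))
  row <- c(random_gt_row(5, 0.3), random_gt_row(5, 0.8))
  names(row) <- names(pops)
  base_vs <- function(r) variant_set(
    data.frame(chrom = "c", pos = 1, ref = "A", alt = "G", qual = 1000),
    matrix(r, 1, dimnames = list(NULL, names(r))))
  t0 <- weir_cockerham_fst(base_vs(row), pops)$theta
  for (i in 1:10) {
    r2 <- c(sample(row[1:5]), sample(row[6:10]))
    names(r2) <- names(pops)
    expect_equal(weir_cockerham_fst(base_vs(r2), pops)$theta, t0)
  }
})

test_that("theta concentrates near zero for equal-frequency populations", {
  set.seed(77)
  pops <- setNames(rep(c("A", "B"), each = 60), sprintf("s%03d", 1:120))
  thetas <- vapply(1:60, function(i) {
    row <- random_gt_row(120, 0.4)
    names(row) <- names(pops)
    vs <- variant_set(data.frame(chrom = "c", pos = 1, ref = "A", alt = "G",
                                 qual = 1000),
                      matrix(row, 1, dimnames = list(NULL, names(pops))))
    weir_cockerham_fst(vs, pops)$theta
  }, numeric(1))
  expect_lt(abs(mean(thetas, na.rm = TRUE)), 0.02)
  # negative estimates occur and are retained, not clamped
  expect_true(any(thetas < 0, na.rm = TRUE))
})

test_that("mean theta rises with the planted between-species frequency differential", {
  mean_theta_at <- function(delta) {
    set.seed(31)
    pops <- setNames(rep(c("A", "B"), each = 10), sprintf("s%02d", 1:20))
    mean(vapply(1:40, function(i) {
      row <- c(random_gt_row(10, 0.5 - delta / 2),
               random_gt_row(10, 0.5 + delta / 2))
      names(row) <- names(pops)
      vs <- variant_set(data.frame(chrom = "c", pos = 1, ref = "A",
                                   alt = "G", qual = 1000),
                        matrix(row, 1, dimnames = list(NULL, names(pops))))
      weir_cockerham_fst(vs, pops)$theta
    }, numeric(1)), na.rm = TRUE)
  }
  m <- vapply(c(0.1, 0.4, 0.8), mean_theta_at, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("small populations are excluded with a warning", {
  gt <- matrix(c("0/0", "0/0", "1/1", "1/1", "0/1"), 1)
  colnames(gt) <- c("a1", "a2", "b1", "b2", "c1")
  pops <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C")
  vs <- variant_set(data.frame(chrom = "c", pos = 1, ref = "A", alt = "G",
                               qual = 1000), gt)
  expect_warning(fst <- weir_cockerham_fst(vs, pops, min_pop_size = 2),
                 "excluding populations")
  expect_equal(fst$theta, 1)  # singleton C dropped; A vs B fully fixed
})

test_that("fst_distribution summarizes defined thetas and flags fixation", {
  d <- fst_distribution(c(0, 0.5, 1))
  expect_equal(d$mean_theta, 0.5)
  expect_equal(d$n_ge_0.5, 2)
  expect_equal(d$n_fixed, 1)
  expect_equal(sum(d$histogram), 3)
  d2 <- fst_distribution(c(NA, 0.2, NA))
  expect_equal(d2$n_undefined, 2)
  expect_equal(d2$n_defined, 1)
  expect_error(fst_distribution(c(NA_real_, NA_real_)),
               class = "capkit_all_undefined")
})

test_that("candidate ranking returns defined thetas above threshold, sorted", {
  fst <- data.frame(chrom = c("c1", "c1", "c2", "c2"), pos = c(1, 2, 1, 2),
                    a = 1, b = 0, c = 0,
                    theta = c(0.9, 1.0, NA, 0.4))
  top <- candidate_diagnostic_snps(fst, threshold = 1.0)
  expect_equal(nrow(top), 1)
  expect_equal(top$pos, 2)
  all_def <- candidate_diagnostic_snps(fst, threshold = 0)
  expect_equal(all_def$theta, c(1.0, 0.9, 0.4))
})

test_that("a VCF document round-trips through write_vcf / read_vcf_genotypes", {
  truth <- make_genotype_truth(40, c("spX", "spY", "spZ"), seed = 5)
  path <- tempfile(fileext = ".vcf")
  vs <- simulate_genotype_vcf(truth, n_per_species = 3, missing_rate = 0.1,
                              seed = 6, path = path)
  back <- read_vcf_genotypes(path)
  expect_equal(back$sites$chrom, vs$sites$chrom)
  expect_equal(back$sites$qual, vs$sites$qual)
  expect_equal(unname(back$gt), unname(vs$gt))
  expect_equal(colnames(back$gt), colnames(vs$gt))
})
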