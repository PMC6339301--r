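#' Construct a multi-sample variant set
#'
#' The in-memory form of a multi-sample VCF used throughout the SNP
#' diagnostics stage: a site table plus a genotype matrix of diploid GT
#' strings (`"0/0"`, `"0/1"`, `"1/1"`, ..., missing as `"./."`).
#' Genotypes are kept exactly as called upstream; no ploidy correction is
#' attempted even for polyploid organisms whose callers emit diploid codes.
#'
#' @param sites `data.frame` with columns `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated for multi-allelic sites), `qual` (phred-scaled site
#'   quality, -10*log10 of the probability the site call is wrong).
#' @param gt Character matrix, sites x specimens, of GT strings; column
#'   names are specimen ids.
#' @return A list of class `variant_set` with elements `sites`, `gt`.
#' @export
variant_set <- function(sites, gt) {
  stopifnot(is.data.frame(sites), is.matrix(gt), nrow(sites) == nrow(gt))
  need <- c("chrom", "pos", "ref", "alt", "qual")
  if (!all(need %in% names(sites))) {
    stop_capkit(paste("sites must have columns:", paste(need, collapse = ", ")),
                "capkit_bad_sites")
  }
  if (any(sites$pos < 1)) stop_capkit("pos must be >= 1", "capkit_bad_sites")
  if (any(!nzchar(sites$alt))) stop_capkit("alt alleles must be nonempty", "capkit_bad_sites")
  structure(list(sites = sites, gt = gt), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d sites x %d specimens\n",
              nrow(x$sites), ncol(x$gt)))
  invisible(x)
}

#' Classify variant records as biallelic SNPs, indels, or multi-allelic SNPs
#'
#' A site with any length-changing allele is an indel; a substitution-only
#' site with a single alternate allele is a biallelic SNP; substitution-only
#' sites with several alternates are multi-allelic SNPs. Every record falls
#' in exactly one class.
#'
#' @param variants A `variant_set` (or its `sites` data.frame).
#' @return A list with `class` (character vector per site) and `counts`
#'   (named integer vector over the three classes).
#' @export
classify_variants <- function(variants) {
  sites <- if (inherits(variants, "variant_set")) variants$sites else variants
  alts <- strsplit(as.character(sites$alt), ",", fixed = TRUE)
  ref <- as.character(sites$ref)
  if (nrow(sites) > 0 &&
      (any(!grepl("^[ACGTN]+$", ref)) ||
       any(!vapply(alts, function(a) all(grepl("^[ACGTN]+$", a)), logical(1))))) {
    stop_capkit("malformed alleles (expected ACGTN strings)", "capkit_bad_alleles")
  }
  cls <- vapply(seq_along(alts), function(i) {
    a <- alts[[i]]
    if (any(nchar(a) != nchar(ref[i]))) "indel"
    else if (length(a) == 1) "biallelic_snp"
    else "multiallelic_snp"
  }, character(1))
  lv <- c("biallelic_snp", "indel", "multiallelic_snp")
  list(class = cls, counts = setNames(as.integer(table(factor(cls, lv))), lv))
}

# Parse diploid GT strings into allele-count summaries. Returns per-site
# lists of (n called, alt allele count, het count). Accepts "/" or "|"
# separators; anything containing "." is missing.
parse_gt <- function(gt_row) {
  miss <- grepl("\\.", gt_row)
  parts <- strsplit(gt_row[!miss], "[/|]")
  bad <- vapply(parts, length, integer(1)) != 2
  if (any(bad)) stop_capkit("non-diploid genotype encountered", "capkit_bad_gt")
  al <- vapply(parts, function(p) as.integer(p), integer(2))
  list(
    n = sum(!miss),
    n_missing = sum(miss),
    alt_count = if (length(parts)) sum(al) else 0L,
    het_count = if (length(parts)) sum(al[1, ] != al[2, ]) else 0L
  )
}

#' Minor allele frequency at a biallelic site
#'
#' Computed over called alleles only: missing genotypes are excluded from
#' the denominator.
#'
#' @param gt_row Character vector of GT strings for one site.
#' @return `min(p, 1 - p)` in `[0, 0.5]`.
#' @export
#' @examples
#' minor_allele_frequency(c(rep("0/0", 9), "0/1")) # 0.05
minor_allele_frequency <- function(gt_row) {
  g <- parse_gt(gt_row)
  if (g$n == 0) stop_capkit("all genotypes missing at site", "capkit_all_missing")
  p <- g$alt_count / (2 * g$n)
  min(p, 1 - p)
}

#' Stringent variant filter for high-confidence diagnostic SNPs
#'
#' Retains biallelic SNPs with no missing genotype, minor allele
#' frequency >= `maf_min`, and site quality strictly > `qual_min`;
#' input order is preserved. Default boundaries (MAF inclusive at 0.05,
#' quality exclusive at 500) are configurable.
#'
#' @param variants A `variant_set`.
#' @param maf_min Minimum minor allele frequency (inclusive; default 0.05).
#' @param qual_min Site quality threshold (exclusive; default 500).
#' @return The filtered `variant_set`. Attribute `filter_counts` records,
#'   for each criterion, how many input sites fail it (counted
#'   independently, so a site can fail several).
#' @export
stringent_filter <- function(variants, maf_min = 0.05, qual_min = 500) {
  sites <- variants$sites
  n <- nrow(sites)
  if (n == 0) {
    out <- variants
    attr(out, "filter_counts") <- c(not_biallelic = 0L, missing_gt = 0L,
                                    low_maf = 0L, low_qual = 0L)
    return(out)
  }
  biallelic <- classify_variants(variants)$class == "biallelic_snp"
  no_missing <- !apply(variants$gt, 1, function(r) any(grepl("\\.", r)))
  callable <- apply(variants$gt, 1, function(r) !all(grepl("\\.", r)))
  maf <- rep(NA_real_, n)
  if (any(callable)) {
    maf[callable] <- apply(variants$gt[callable, , drop = FALSE], 1,
                           minor_allele_frequency)
  }
  maf_ok <- !is.na(maf) & maf >= maf_min
  qual_ok <- sites$qual > qual_min
  keep <- biallelic & no_missing & maf_ok & qual_ok
  out <- variant_set(sites[keep, , drop = FALSE],
                     variants$gt[keep, , drop = FALSE])
  attr(out, "filter_counts") <- c(
    not_biallelic = sum(!biallelic),
    missing_gt = sum(!no_missing),
    low_maf = sum(!maf_ok),
    low_qual = sum(!qual_ok)
  )
  out
}

# Weir & Cockerham (1984) per-site variance components for one biallelic
# site. pop_n: called diploid sample sizes; pop_p: alt allele frequencies;
# pop_h: observed heterozygote proportions. Returns c(a, b, c).
wc_components <- function(pop_n, pop_p, pop_h) {
  r <- length(pop_n)
  nbar <- mean(pop_n)
  if (nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nc <- (r * nbar - sum(pop_n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(pop_n * pop_p) / (r * nbar)
  s2 <- sum(pop_n * (pop_p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(pop_n * pop_h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

#' Per-site Weir & Cockerham F_ST with species as populations
#'
#' Computes the 1984 variance-components estimator theta-hat per site:
#' `a` (among populations), `b` (among individuals within populations),
#' `c` (within individuals, from observed heterozygosity), with
#' `theta = a / (a + b + c)`. The unequal-sample-size weighting
#' (`n-bar`, `n_c`) of the original estimator is used. Monomorphic sites
#' have a zero denominator and an undefined theta, reported as `NA`
#' rather than dropped. Negative estimates (expected for undifferentiated
#' populations) are reported as computed, not clamped.
#'
#' Populations whose assigned roster is below `min_pop_size` are excluded
#' with a warning: singleton populations inflate the count of apparently
#' fixed (theta = 1) sites because within-species variation cannot be
#' estimated from one individual.
#'
#' @param variants A `variant_set` of biallelic sites (typically the
#'   output of [stringent_filter()]).
#' @param populations Named character vector mapping specimen id to
#'   population (species).
#' @param min_pop_size Minimum specimens per population (default 2).
#' @return A `data.frame` with `chrom`, `pos`, `a`, `b`, `c`, `theta`.
#' @export
weir_cockerham_fst <- function(variants, populations, min_pop_size = 2) {
  gt <- variants$gt
  unassigned <- setdiff(colnames(gt), names(populations))
  if (length(unassigned) > 0) {
    stop_capkit(sprintf("specimens without population: %s",
                        paste(unassigned, collapse = ", ")),
                "capkit_unassigned_specimen")
  }
  pops <- populations[colnames(gt)]
  sizes <- table(pops)
  small <- names(sizes)[sizes < min_pop_size]
  if (length(small) > 0) {
    warning(sprintf("excluding populations below %d specimens: %s",
                    min_pop_size, paste(small, collapse = ", ")))
    keep <- !(pops %in% small)
    gt <- gt[, keep, drop = FALSE]
    pops <- pops[keep]
  }
  if (length(unique(pops)) < 2) {
    stop_capkit("need at least 2 populations", "capkit_single_population")
  }
  pop_levels <- unique(pops)
  comp <- t(apply(gt, 1, function(row) {
    per_pop <- lapply(pop_levels, function(p) parse_gt(row[pops == p]))
    n <- vapply(per_pop, `[[`, numeric(1), "n")
    ok <- n > 0
    if (sum(ok) < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
    n <- n[ok]
    p_i <- vapply(per_pop[ok], function(g) g$alt_count / (2 * g$n), numeric(1))
    h_i <- vapply(per_pop[ok], function(g) g$het_count / g$n, numeric(1))
    wc_components(n, p_i, h_i)
  }))
  denom <- comp[, "a"] + comp[, "b"] + comp[, "c"]
  theta <- ifelse(is.na(denom) | denom == 0, NA_real_, comp[, "a"] / denom)
  data.frame(chrom = variants$sites$chrom, pos = variants$sites$pos,
             a = comp[, "a"], b = comp[, "b"], c = comp[, "c"],
             theta = theta, stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize a per-site F_ST distribution
#'
#' Undefined estimates (monomorphic sites) are excluded from every summary
#' and reported separately. Complete fixation (`theta = 1`) is tested with
#' tolerance 1e-9; histogram bins have width 0.05 and clip at
#' `[-0.05, 1]`.
#'
#' @param fst Output of [weir_cockerham_fst()] (or a numeric theta vector).
#' @return List with `n_defined`, `n_undefined`, `mean_theta`,
#'   `n_ge_0.5`, `n_fixed`, and `histogram` (counts named by bin left edge).
#' @export
fst_distribution <- function(fst) {
  theta <- if (is.data.frame(fst)) fst$theta else fst
  defined <- theta[!is.na(theta)]
  if (length(defined) == 0) {
    stop_capkit("no defined theta values", "capkit_all_undefined")
  }
  breaks <- seq(-0.05, 1, by = 0.05)
  clipped <- pmin(pmax(defined, -0.05), 1)
  h <- hist(clipped, breaks = breaks, plot = FALSE, include.lowest = TRUE,
            right = FALSE)
  # right = FALSE gives [lo, hi) bins except the last, which is [0.95, 1]
  list(
    n_defined = length(defined),
    n_undefined = sum(is.na(theta)),
    mean_theta = mean(defined),
    n_ge_0.5 = sum(defined >= 0.5),
    n_fixed = sum(abs(defined - 1) <= 1e-9),
    histogram = setNames(h$counts, sprintf("%.2f", breaks[-length(breaks)]))
  )
}

#' Candidate species-diagnostic SNPs
#'
#' Sites with a defined theta at or above `threshold`, sorted by theta
#' descending then by site key -- the shortlist a genotyping assay for
#' species identification would draw from. At `threshold = 1` the list is
#' the fully fixed differences between species.
#'
#' @param fst Output of [weir_cockerham_fst()].
#' @param threshold Minimum theta (default 0.5); compared with a 1e-9
#'   tolerance so exact fixation passes `threshold = 1`.
#' @return Rows of `fst` passing the threshold, ranked.
#' @export
candidate_diagnostic_snps <- function(fst, threshold = 0.5) {
  keep <- !is.na(fst$theta) & fst$theta >= threshold - 1e-9
  out <- fst[keep, , drop = FALSE]
  out <- out[order(-out$theta, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
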