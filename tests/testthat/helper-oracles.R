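# Independent oracles used to cross-check package implementations.
# These deliberately use different computational routes than the package.

# Weir-Cockerham per-site estimator via the nested-ANOVA mean-squares
# route on raw allele indicator variables (alleles within individuals
# within populations), rather than the closed-form component formulas
# used in the package.
oracle_wc_anova <- function(gt_row, pops) {
  called <- !grepl("\\.", gt_row)
  gt_row <- gt_row[called]
  pops <- pops[called]
  al <- t(vapply(strsplit(gt_row, "[/|]"),
                 function(p) as.integer(p), integer(2)))
  n_i <- as.vector(table(pops)[unique(pops)])
  r <- length(n_i)
  N <- sum(n_i)
  ybar <- mean(al)
  pop_means <- tapply(rowMeans(al), pops, mean)[unique(pops)]
  ind_means <- rowMeans(al)
  SSP <- sum(2 * n_i * (pop_means - ybar)^2)
  SSI <- sum(2 * (ind_means - pop_means[pops])^2)
  SSG <- sum((al - ind_means)^2)
  MSP <- SSP / (r - 1)
  MSI <- SSI / (N - r)
  MSG <- SSG / N
  nbar <- N / r
  nc <- (N - sum(n_i^2) / N) / (r - 1)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  cc <- MSG
  denom <- a + b + cc
  list(a = a, b = b, c = cc,
       theta = if (denom == 0) NA_real_ else a / denom)
}

# Welch t and Satterthwaite df straight from the textbook formulas.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  list(
    t = (mean(a) - mean(b)) / sqrt(va + vb),
    df = (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  )
}

# Brute-force ascending sort by rpk with lexicographic id tie-break,
# built from repeated minimum extraction (independent of order()).
oracle_rank <- function(ids, rpk) {
  ids <- as.character(ids)
  out <- character(0)
  while (length(ids) > 0) {
    m <- min(rpk)
    cand <- sort(ids[rpk == m])[1]
    out <- c(out, cand)
    keep <- ids != cand
    ids <- ids[keep]; rpk <- rpk[keep]
  }
  out
}

# Small random genotype row at a biallelic site.
random_gt_row <- function(n, p, missing_rate = 0) {
  a1 <- rbinom(n, 1, p); a2 <- rbinom(n, 1, p)
  g <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  g[runif(n) < missing_rate] <- "./."
  g
}
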