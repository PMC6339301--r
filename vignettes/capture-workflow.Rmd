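---
title: "Target-capture panel design and diagnostic SNP analysis with capkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-capture panel design and diagnostic SNP analysis with capkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capkit)
```

## The problem

Tropical timber genera such as *Cedrela* (Meliaceae) contain CITES-listed
species whose processed wood cannot be reliably identified by anatomy
alone. A genomic route is to enrich thousands of nuclear gene targets by
hybridization capture, genotype a diversity panel of specimens across
species, and shortlist SNPs that are fixed differences between species —
candidate markers for assigning a wood specimen to species. capkit
implements the computational stages of that workflow: low-copy target
selection, probe tiling, capture enrichment QC, per-site F~ST~ ranking of
SNPs, and reference-guided organelle consensus building. Upstream steps
that established tools already do well — read trimming, assembly,
alignment, variant calling — are consumed as their standard outputs
(coverage tables, VCF, pileups, alignments), not reimplemented.

## Low-copy target selection by RPK

When genomic shotgun reads from the same individual are mapped back to a
transcriptome, the mapped reads per kilobase of transcript model (RPK)

$$\mathrm{RPK}_t = \frac{r^{+}_t + r^{-}_t}{L_t / 1000}$$

is a proxy for genomic copy number: multi-copy gene families attract
proportionally more reads. Sorting models by ascending RPK and taking an
interior rank window avoids, at the low end, unmappable or contaminant
models and, at the high end, repetitive and high-copy families. The
default window of ranks 5000–15,000 is inclusive on both ends (it yields
exactly 10,001 targets), and ties are broken by lexicographic target id
so the selection is reproducible. Repeat masking is an external step; as
a convenience `extract_targets()` can drop targets whose soft-masked
fraction exceeds a threshold (default 0.5).

```{r rpk}
cov <- data.frame(target_id = c("a", "b", "c"), target_length = 1000,
                  reads_plus = c(9, 1, 4), reads_minus = c(1, 0, 4),
                  covered_bases = 900)
rank_by_rpk(cov)
```

## Probe tiling

Two 100-bp probes are tiled per target, end-to-end from the 5' end, with
no partial tiles: fixed-length probes match synthesis constraints and the
behaviour for sub-probe-length remainders is therefore "emit nothing".
A 200-bp target (the minimum transcript length) carries exactly two
probes; a 150-bp target would carry one. Probes containing N or
soft-masked bases are flagged rather than silently dropped, since
vendor-side QC rules vary.

## Capture enrichment QC

Per specimen, enrichment is summarized by on-target yield (the sum of
plus- and minus-strand reads mapped to targets), its percentage of the
library, and per-target depth

$$d_t = \frac{\ell \,(r^{+}_t + r^{-}_t)}{\text{covered bases}_t},$$

with read length $\ell = 101$ bp by default. "Reliably enriched" targets
for a species are those with $d_t > 10$ in *every* specimen of the
species — a deliberately strict rule (strict inequality, every specimen)
because downstream wood-identification assays need loci with a high
expectation of genotyping success. Cross-taxon transferability is
compared after removing two biases: organelle-labelled reads are
discarded and a fixed-size subsample (default $10^6$ reads) is drawn, so
libraries differ neither in size nor in organelle content. Libraries that
cannot supply the subsample raise a typed shortfall error and are
excluded. Group contrasts use the unequal-variance (Welch) t-test with
Satterthwaite degrees of freedom; on-target yields differ in variance by
orders of magnitude between in-genus and out-genus specimens, so the
equal-variance test would be miscalibrated. Percentages are reported to
one decimal, rounding half away from zero, matching the presentation of
published capture QC tables.

The package ships a 43-specimen Meliaceae panel metrics table
(`read_panel_metrics()`) as a desk-scale fixture; the Welch t-test on its
on-target yields (24 *Cedrela* vs 19 other-genera rows) gives t = 4.95,
df = 23.86:

```{r ttest}
panel <- read_panel_metrics()
welch_t_test(panel$on_target_yield[panel$genus_group == "Cedrela"],
             panel$on_target_yield[panel$genus_group == "other"])[c("t", "df")]
```

## Stringent SNP filtering and Weir–Cockerham F~ST~

Variants are classified into biallelic SNPs, indels (any length-changing
allele) and multi-allelic SNPs. The stringent filter retains biallelic
SNPs with no missing genotype, minor allele frequency ≥ 0.05 and site
quality > 500. The source conventions for the two boundaries are
genuinely ambiguous (inclusive and exclusive readings both appear in the
field's reports); we fix MAF as inclusive and quality as exclusive, and
both thresholds are arguments.

Per retained site, `weir_cockerham_fst()` computes the 1984
variance-components estimator with species as populations: components
$a$ (among populations), $b$ (among individuals within populations) and
$c$ (within individuals), using the unequal-sample-size weights
($\bar n$, $n_c$), and $\hat\theta = a/(a+b+c)$. Monomorphic sites have a
zero denominator and are reported as undefined rather than dropped;
negative estimates, expected for undifferentiated populations, are
retained unclamped. Populations below a minimum roster size (default 2)
are excluded with a warning: a singleton species contributes no
within-species variance and inflates the count of apparently fixed sites.
Genotypes are used exactly as the upstream caller emitted them — diploid
codes even for a tetraploid organism — because the estimator is defined
on the called genotypes, not on an inferred ploidy.

Candidate diagnostic SNPs are the sites with $\hat\theta$ at or above a
threshold (1.0 for fixed differences), ranked by $\hat\theta$.

```{r fst}
gt <- matrix(c("0/0", "0/0", "0/1", "1/1", "0/1", "1/1"), 1,
             dimnames = list(NULL, sprintf("s%d", 1:6)))
vs <- variant_set(data.frame(chrom = "tgt1", pos = 10, ref = "A",
                             alt = "G", qual = 1200), gt)
weir_cockerham_fst(vs, setNames(rep(c("P1", "P2"), each = 3), colnames(gt)))
```

## Organelle consensus

Reference-guided consensus calling uses a per-base pileup: a position is
called as the plurality base when total depth reaches the minimum
(default 2X) and `N` otherwise. A single read cannot corroborate a base,
hence the 2X floor. Ties between top base counts are called `N` — the
conservative choice, since the tie-breaking behaviour of interactive
assembly tools is undocumented. Contigs whose junction gap size is
unknown are joined with a fixed 100-N spacer. Alignment variable-site
counting treats a column as a SNP only when it shows at least two
distinct unambiguous bases within the chosen taxon subset; `N` and gaps
are ignored entirely, so missing data alone never creates a SNP. All
pileup and report coordinates are 1-based, matching VCF convention.

## Synthetic data: what it emulates, and what it does not

Every stage is exercised against generators with planted ground truth
(`make_transcriptome()`, `simulate_genomic_coverage()`,
`simulate_capture_experiment()`, `make_genotype_truth()` /
`simulate_genotype_vcf()`, `simulate_organelle_pileup()`):

* Read counts per transcript are negative binomial with mean
  $\text{rate} \times L/1000 \times \text{copy number}$. Overdispersion
  is essential: empirical RPK distributions span zero to thousands, far
  beyond Poisson spread. `dispersion = Inf` recovers Poisson.
* The default low-copy generative rate is 0.8 reads/kbp per copy, the
  RPK regime of a selected low-copy target block; full-transcriptome
  simulations use a mixture of copy numbers (75% single-copy with 2-,
  5- and 20-copy minorities) so the ranking has the heavy right tail
  that motivates the interior window.
* Capture reads fall into organelle / on-target / off-target categories
  with probabilities given by the panel's organelle fraction and the
  genus-dependent enrichment bias; tallies always sum to the library
  size.
* Genotypes are drawn per species from planted allele frequencies, in
  three site classes: `fixed` (frequency 1 in one species, 0 elsewhere),
  `shared`, and `private`. With `exact_freqs = TRUE` genotype counts are
  assigned deterministically so sample frequencies realize the planted
  frequencies exactly ("full sampling"); only in that regime is the set
  of $\hat\theta = 1$ sites exactly the planted fixed class, because
  stochastic sampling can fix a non-fixed site by chance in small
  panels.
* Organelle pileups are error-free by construction (read-level error
  modelling is out of scope), so consensus recovery can be asserted
  exactly.

None of this emulates mapping artefacts, paralog collapse, reference
bias, index hopping, or base-calling error — passing tests demonstrate
the correctness of the estimators and selection logic on their stated
inputs, not robustness of an end-to-end wet-lab protocol.

One master seed fans out to per-operation child seeds by a stable string
hash (`child_seed()`), so stages are reproducible individually without
sharing an RNG stream.

## Numerical and design choices

* Rank windows are inclusive on both ends; window cardinality is always
  `hi - lo + 1`.
* Ties: RPK ranking breaks ties by target id; consensus base ties become
  `N`; candidate SNPs tie-break by site key.
* $\hat\theta = 1$ is tested with tolerance $10^{-9}$; F~ST~ histograms
  use 0.05-wide bins clipped to $[-0.05, 1]$.
* Depth thresholds are strict (`> 10`); a depth of exactly 10 fails.
* Percent columns round half away from zero to one decimal; group means
  quoted in prose use two significant figures.
* Problem sizes in the shipped analyses: a 52,181-model ranking, a
  12-specimen capture panel at $10^6$ reads, an 800-site VCF over four
  species of four specimens, and a 20-kb organelle reference at ~40X —
  desk-scale versions of the study design that run in seconds.

## Known limitations

* Per-site F~ST~ with few specimens per species is noisy, and fixed
  differences found in panels of 2–4 specimens per species
  overrepresent the most divergent lineage; the candidate list is a
  screening pool, not a validated assay.
* The probe count for a full panel is `2 x n_targets` by construction;
  vendor-side probe QC (which can remove a few percent of tiles) is not
  modelled.
* `validate_formats()` checks dialect structure, not semantic
  consistency between files (e.g. that a population map covers every
  VCF sample); the analysis functions themselves check that.
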