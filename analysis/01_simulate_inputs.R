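#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream stages consume,
# with planted ground truth, under results/data/. A single master seed
# fans out to per-stage child seeds so stages are independently
# reproducible.

suppressPackageStartupMessages(library(capkit))
master_seed <- 2018
data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

## Transcriptome: 52,181 models, mostly single-copy with a multi-copy
## minority, mirroring a leaf transcriptome with its high-copy gene
## families. Sequences are kept only for a 2000-model subset used by the
## probe-design stage; the full set carries lengths and copy numbers.
message("Simulating transcriptome (52,181 models) and genomic coverage ...")
fix <- make_transcriptome(52181, c(200, 8118),
                          c("1" = 0.75, "2" = 0.10, "5" = 0.10, "20" = 0.05),
                          seed = child_seed(master_seed, "transcriptome"),
                          emit_sequences = FALSE)
cov <- simulate_genomic_coverage(fix, reads_per_kbp_per_copy = 0.8,
                                 dispersion = 2,
                                 seed = child_seed(master_seed, "coverage"))
write_coverage(cov, file.path(data_dir, "genomic_coverage.tsv"))
write.table(fix$info, file.path(data_dir, "transcriptome_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sub <- make_transcriptome(2000, c(200, 2000),
                          seed = child_seed(master_seed, "sequences"))
write_fasta(sub$sequences, file.path(data_dir, "transcripts_subset.fasta"))

## Capture experiment: a 12-specimen diversity panel, 8 in-genus and 4
## out-genus, with organelle contamination and genus-dependent
## enrichment bias.
message("Simulating capture experiment over a 12-specimen panel ...")
specimens <- data.frame(
  specimen_id = sprintf("s%02d", 1:12),
  species_id = rep(c("spA", "spB", "spC", "outX", "outY"), c(3, 3, 2, 2, 2)),
  genus_group = rep(c("in_genus", "out_genus"), c(8, 4))
)
targets <- data.frame(target_id = sub$info$id, length = sub$info$length)
capture <- simulate_capture_experiment(
  targets,
  panel_spec(specimens, library_size = 1e6, organelle_fraction = 0.05,
             enrichment_bias = c(in_genus = 0.35, out_genus = 0.015),
             seed = child_seed(master_seed, "capture")))
write.table(capture$tallies, file.path(data_dir, "capture_tallies.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (s in names(capture$coverage)) {
  write_coverage(capture$coverage[[s]],
                 file.path(data_dir, sprintf("capture_%s.cov.tsv", s)))
}
write.table(specimens, file.path(data_dir, "panel_groups.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## Genotypes: 800 sites across four in-genus species with 20% planted
## fixed differences, written as VCF v4.2 plus a truth sidecar.
message("Simulating multi-sample VCF (800 sites, 4 species x 4) ...")
truth <- make_genotype_truth(800, c("spA", "spB", "spC", "spD"),
                             class_probs = c(fixed = 0.2, shared = 0.6,
                                             private = 0.2),
                             seed = child_seed(master_seed, "truth"))
vs <- simulate_genotype_vcf(truth, n_per_species = 4, missing_rate = 0.05,
                            seed = child_seed(master_seed, "genotypes"),
                            path = file.path(data_dir, "variants.vcf"))
write.table(data.frame(specimen = colnames(vs$gt),
                       population = attr(vs, "populations")),
            file.path(data_dir, "population_map.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(truth$sites, truth$freqs),
            file.path(data_dir, "genotype_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## Organelle pileup: a 20-kb reference at ~40X with low-coverage patches
## and 60 planted substitutions.
message("Simulating organelle pileup (20 kb reference) ...")
set.seed(child_seed(master_seed, "organelle_ref"))
ref <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
             collapse = "")
prof <- rep(40, 20000)
for (k in 1:40) {
  at <- sample(19900, 1)
  prof[at:(at + sample(5:60, 1))] <- sample(0:1, 1)
}
vars <- data.frame(pos = sort(sample(20000, 60)),
                   base = sample(c("A", "C", "G", "T"), 60, replace = TRUE))
sim <- simulate_organelle_pileup(ref, prof, variants = vars,
                                 seed = child_seed(master_seed, "pileup"))
write_fasta(c(cp_ref = ref), file.path(data_dir, "organelle_ref.fasta"))
write_pileup(sim$pileup, file.path(data_dir, "organelle_pileup.tsv"))
write_fasta(c(cp_truth = sim$truth_consensus),
            file.path(data_dir, "organelle_truth.fasta"))
write.table(vars, file.path(data_dir, "organelle_variants_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("Inputs written under ", data_dir)
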