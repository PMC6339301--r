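#!/usr/bin/env Rscript
# Stage 3: tile two 100-bp hybridization probes per selected gene target,
# end-to-end from the 5' end, and write the probe FASTA and BED panel.
# Uses the 2000-model sequence subset as the designable target pool.

suppressPackageStartupMessages(library(capkit))
data_dir <- "results/data"
out_dir <- "results/probes"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

tx <- read_fasta(file.path(data_dir, "transcripts_subset.fasta"))
targets <- data.frame(target_id = names(tx), sequence = unname(tx),
                      length = nchar(tx))

probes <- tile_probes(targets, probe_length = 100, probes_per_target = 2)
write_fasta(setNames(probes$sequence, probes$probe_id),
            file.path(out_dir, "probes.fasta"))
write.table(probes[, c("target_id", "start", "end", "probe_id")],
            file.path(out_dir, "probes.bed"), sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)

s <- probe_panel_summary(probes)
message(sprintf("Designed %d probes over %d targets (%.2f probes/target)",
                s$n_probes, s$n_targets, s$mean_probes_per_target))
message(sprintf("%d probes flagged ambiguous", sum(probes$ambiguous)))
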