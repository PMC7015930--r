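#!/usr/bin/env Rscript
# Stage 1: generate the demonstration study — a 100 kb genome with 20
# CpG-dense promoters, four tissue groups (normal, ADH, DCIS, invasive)
# with three replicates each, and directional RRBS reads at 30x per
# fragment end. Eight promoters carry +/-0.5 methylation effects in
# stage-specific patterns (invasive-only, DCIS+invasive, DCIS-only,
# opposite-direction); twelve are null. Ground truth goes to TSV
# sidecars, never into the FASTQ.
suppressMessages(library(rrbstage))

seed <- 42L
out <- "results/demo"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- progression_demo_config(seed = seed)
sg <- generate_genome(cfg)
truth <- assign_methylation(cfg, sg)
sim <- simulate_reads(cfg, sg, truth)

write_fasta(sg$genome, file.path(out, "genome.fa"))
write_tsv(sg$genes, file.path(out, "genes.tsv"))
design <- write_simulation(sim, truth, file.path(out, "sim"))

n_reads <- vapply(sim$reads, length, integer(1))
message(sprintf("simulated %d samples; %d-%d reads each (median %d)",
                nrow(design), min(n_reads), max(n_reads),
                as.integer(stats::median(n_reads))))
message(sprintf("%d genes with true effects: %s",
                length(unique(cfg$effect_table$gene)),
                paste(unique(cfg$effect_table$gene), collapse = ", ")))
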