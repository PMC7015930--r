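#!/usr/bin/env Rscript
# Stage 3: three-letter alignment of every sample's reads against the
# converted fragment-end reference (second-best uniqueness rule), per-CpG
# pileup of methylated (C) vs converted (T) evidence with strand merging,
# the >= 5-read coverage filter, CpG-island detection, and promoter /
# gene-body / island annotation.
suppressMessages(library(rrbstage))

out <- "results/demo"
reference <- read_reference(file.path(out, "reference.tsv"))
genome <- read_fasta(file.path(out, "genome.fa"))
genes <- read_tsv(file.path(out, "genes.tsv"))
design <- read_tsv(file.path(out, "sim", "design.tsv"))

calls <- list()
for (i in seq_len(nrow(design))) {
  s <- design$sample[i]
  reads <- read_fastq(design$fastq[i])
  res <- align_sample(reads, reference)
  calls[[s]] <- pileup_cpg(res$alignments, reference, reads, sample_id = s)
  message(sprintf("%s: %d reads, %.1f%% unique, %.1f%% discarded as non-unique",
                  s, res$summary[["n_reads"]],
                  100 * res$summary[["unique"]] / res$summary[["n_reads"]],
                  100 * res$summary[["ambiguous_discarded"]] / res$summary[["n_reads"]]))
}
calls <- data.table::rbindlist(calls)
calls <- filter_coverage(calls, min_reads = 5)

islands <- detect_cpg_islands(genome)
calls <- annotate_cpgs(calls, genes, islands)
write_bed(islands, file.path(out, "cpg_islands.bed"))
write_tsv(calls, file.path(out, "cpg_calls.tsv"))

message(sprintf("%d CpG-by-sample calls pass the coverage filter; %d CpG islands (%d bp total)",
                nrow(calls), nrow(islands), sum(islands$end - islands$start)))
message(sprintf("%.1f%% of calls fall inside promoters",
                100 * mean(!is.na(calls$promoter))))
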