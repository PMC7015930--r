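#!/usr/bin/env Rscript
# Stage 2: in-silico TaqI + MspI double digestion of the simulated genome,
# 40-350 bp size selection, and construction of the C-to-T converted
# 50 bp fragment-end reference the bisulfite aligner matches against.
suppressMessages(library(rrbstage))

out <- "results/demo"
genome <- read_fasta(file.path(out, "genome.fa"))

frags <- predict_fragments(genome, min_len = 40, max_len = 350)
reference <- build_reference(frags, genome, end_len = 50)
write_reference(reference, file.path(out, "reference.fa"),
                file.path(out, "reference.tsv"))

genes <- read_tsv(file.path(out, "genes.tsv"))
in_prom <- vapply(seq_len(nrow(genes)), function(i) {
  any(frags$chrom == genes$chrom[i] &
        frags$end > genes$promoter_start[i] &
        frags$start < genes$promoter_end[i])
}, logical(1))
n_cpg <- sum(lengths(reference$cpg_offsets[reference$strand == "top"]))

message(sprintf("digestion: %d in-range fragments (median %d bp) -> %d reference entries",
                nrow(frags), as.integer(stats::median(frags$length)),
                nrow(reference)))
message(sprintf("%d/%d promoters overlap at least one in-range fragment; %d CpGs on top-strand fragment ends",
                sum(in_prom), nrow(genes), n_cpg))
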