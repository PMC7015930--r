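#!/usr/bin/env Rscript
# Stage 6: direction-concordance between invasive-stage promoter calls and
# gene expression. No expression assay exists for the simulated genes, so
# a synthetic expression table is generated from the simulation truth:
# log2 fold-changes anti-correlated with the true methylation change
# (hypermethylation silences, hypomethylation activates) plus noise, with
# a fraction of genes missing, mimicking an external table joined by gene
# symbol.
suppressMessages(library(rrbstage))

out <- "results/demo"
set.seed(substream_seed(42L, "expression"))

inv <- read_tsv(file.path(out, "promoter_diff_invasive.tsv"))
truth <- read_tsv(file.path(out, "sim", "truth_gene_levels.tsv"))
tr_inv <- truth[truth$group == "invasive", ]

expr <- data.frame(
  gene = tr_inv$gene,
  log2fc = -3 * tr_inv$diffmeth_truth + stats::rnorm(nrow(tr_inv), sd = 0.4))
expr <- expr[sample(nrow(expr), round(0.9 * nrow(expr))), ]  # 10% "no data"
write_tsv(expr, file.path(out, "expression_synthetic.tsv"))

sig <- inv[inv$direction != "ns", ]
if (nrow(sig) == 0) stop("no significant invasive promoters to score")
sc <- score_concordance(sig, expr, t = 0.5)
write_tsv(sc$records, file.path(out, "concordance_records.tsv"))
write_json_summary(sc$summary, file.path(out, "concordance_summary.json"))

for (i in seq_len(nrow(sc$summary))) {
  s <- sc$summary[i, ]
  message(sprintf("%smethylated promoters: %d/%d concordant with expression (%d%%)",
                  s$meth_direction, s$n_concordant, s$n, s$percent))
}
print(table(sc$records$status))
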