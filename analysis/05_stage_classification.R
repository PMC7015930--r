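#!/usr/bin/env Rscript
# Stage 5: combine the three per-stage comparisons into progression
# categories (single-stage, late-stage, consistent, opposite-direction,
# mixed), the per-stage Venn counts with their hypo/hyper splits, and the
# DiffMeth heat-map matrix (rendered if pheatmap is available).
suppressMessages(library(rrbstage))

out <- "results/demo"
adh <- read_tsv(file.path(out, "promoter_diff_ADH.tsv"))
dcis <- read_tsv(file.path(out, "promoter_diff_DCIS.tsv"))
inv <- read_tsv(file.path(out, "promoter_diff_invasive.tsv"))

records <- stage_categories(adh, dcis, inv)
write_tsv(records, file.path(out, "stage_categories.tsv"))

v <- venn_counts(records)
write_tsv(v$per_stage, file.path(out, "venn_per_stage.tsv"))
write_tsv(data.frame(region = names(v$overlaps),
                     count = as.integer(v$overlaps)),
          file.path(out, "venn_overlaps.tsv"))

hm <- heatmap_matrix(records, select = setdiff(unique(records$category), "none"))
write_heatmap_tsv(hm, file.path(out, "heatmap.tsv"))
if (requireNamespace("pheatmap", quietly = TRUE) && nrow(hm$diffmeth) > 1) {
  grDevices::png(file.path(out, "heatmap.png"), width = 480, height = 640)
  pheatmap::pheatmap(hm$diffmeth, cluster_rows = FALSE, cluster_cols = FALSE,
                     main = "Promoter DiffMeth vs normal")
  grDevices::dev.off()
}

message("category counts:")
print(table(records$category))
message("per-stage significant promoters (hypo + hyper = total):")
print(v$per_stage)
message(sprintf("significant in both DCIS and invasive: %d; exclusively invasive: %d",
                v$overlaps[["DCIS_INV"]], v$overlaps[["INV_only"]]))
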