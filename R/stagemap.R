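# Stage-progression classification. Each gene's per-stage direction calls
# (ADH, DCIS, invasive — each hyper/hypo/ns versus normal) are combined
# into one progression category: significant in a single stage
# (adh_only/dcis_only/invasive_only), in DCIS and invasive with the same
# sign (late_stage), in all three stages with one sign
# (all_stages_consistent), in two or more stages with conflicting signs
# (opposite_direction), any other multi-stage pattern (mixed), or nowhere
# (none). The categories drive the Venn counts and the heat-map matrix.

STAGE_CATEGORIES <- c("none", "adh_only", "dcis_only", "invasive_only",
                      "late_stage", "all_stages_consistent",
                      "opposite_direction", "mixed")

#' Classify one gene's stage-direction triple
#'
#' @param status_adh,status_dcis,status_inv Each `"hyper"`, `"hypo"` or
#'   `"ns"`.
#' @return One of: none, adh_only, dcis_only, invasive_only, late_stage,
#'   all_stages_consistent, opposite_direction, mixed.
#' @export
#' @examples
#' classify_gene("ns", "hyper", "hyper")  # late_stage
#' classify_gene("ns", "ns", "hypo")      # invasive_only
#' classify_gene("hyper", "ns", "hypo")   # opposite_direction
classify_gene <- function(status_adh, status_dcis, status_inv) {
  st <- c(status_adh, status_dcis, status_inv)
  stopifnot(all(st %in% c("hyper", "hypo", "ns")))
  sig <- st != "ns"
  n_sig <- sum(sig)
  if (n_sig == 0L) return("none")
  signs <- unique(st[sig])
  if (length(signs) > 1L) return("opposite_direction")
  if (n_sig == 1L) {
    return(c("adh_only", "dcis_only", "invasive_only")[which(sig)])
  }
  if (n_sig == 3L) return("all_stages_consistent")
  if (!sig[1L] && sig[2L] && sig[3L]) return("late_stage")
  "mixed"
}

#' Build per-gene stage-category records from three comparisons
#'
#' @param adh,dcis,inv Promoter results from [promoter_diff()] for the
#'   ADH, DCIS and invasive comparisons (must cover the same genes).
#' @return data.table: gene, status_ADH, status_DCIS, status_INV,
#'   diffmeth_ADH, diffmeth_DCIS, diffmeth_INV, category.
#' @export
stage_categories <- function(adh, dcis, inv) {
  genes <- adh$gene
  if (!identical(sort(genes), sort(dcis$gene)) ||
      !identical(sort(genes), sort(inv$gene))) {
    stop("the three comparisons must report the same gene set", call. = FALSE)
  }
  d <- data.table::data.table(
    gene = genes,
    status_ADH = adh$direction,
    status_DCIS = dcis$direction[match(genes, dcis$gene)],
    status_INV = inv$direction[match(genes, inv$gene)],
    diffmeth_ADH = adh$diffmeth,
    diffmeth_DCIS = dcis$diffmeth[match(genes, dcis$gene)],
    diffmeth_INV = inv$diffmeth[match(genes, inv$gene)]
  )
  d[, "category" := mapply(classify_gene, d$status_ADH, d$status_DCIS,
                           d$status_INV)]
  d[]
}

#' Per-stage totals, hypo/hyper splits and Venn overlaps
#'
#' Totals count genes significant (non-ns) per stage; each total equals
#' its hypo + hyper split by construction, and the overlap counts obey
#' inclusion-exclusion. The conservation identity is asserted on every
#' call.
#'
#' @param records From [stage_categories()].
#' @return List with `per_stage` (data.table: stage, hypo, hyper, total)
#'   and `overlaps` (named counts: genes significant in each pairwise and
#'   the triple intersection, plus exclusive counts per stage).
#' @export
venn_counts <- function(records) {
  stages <- c(ADH = "status_ADH", DCIS = "status_DCIS", INV = "status_INV")
  per_stage <- data.table::rbindlist(lapply(names(stages), function(s) {
    st <- records[[stages[[s]]]]
    data.table::data.table(stage = s,
                           hypo = sum(st == "hypo"),
                           hyper = sum(st == "hyper"),
                           total = sum(st != "ns"))
  }))
  stopifnot(all(per_stage$hypo + per_stage$hyper == per_stage$total))

  in_adh <- records$status_ADH != "ns"
  in_dcis <- records$status_DCIS != "ns"
  in_inv <- records$status_INV != "ns"
  overlaps <- c(
    ADH_only = sum(in_adh & !in_dcis & !in_inv),
    DCIS_only = sum(!in_adh & in_dcis & !in_inv),
    INV_only = sum(!in_adh & !in_dcis & in_inv),
    ADH_DCIS = sum(in_adh & in_dcis),
    DCIS_INV = sum(in_dcis & in_inv),
    ADH_INV = sum(in_adh & in_inv),
    ADH_DCIS_INV = sum(in_adh & in_dcis & in_inv)
  )
  list(per_stage = per_stage, overlaps = overlaps)
}

#' DiffMeth heat-map matrix with significance mask
#'
#' @param records From [stage_categories()].
#' @param select Optional character vector of categories to keep.
#' @return List with `diffmeth` (genes x 3 numeric matrix), `significant`
#'   (logical mask), `category` (per-row category). Rows are ordered by
#'   category then by invasive-stage DiffMeth, descending, for a
#'   deterministic layout.
#' @export
heatmap_matrix <- function(records, select = NULL) {
  rec <- data.table::as.data.table(records)
  if (!is.null(select)) rec <- rec[rec$category %in% select, ]
  ord <- order(factor(rec$category, levels = STAGE_CATEGORIES),
               -rec$diffmeth_INV, rec$gene)
  rec <- rec[ord, ]
  dm <- as.matrix(rec[, c("diffmeth_ADH", "diffmeth_DCIS", "diffmeth_INV"),
                      with = FALSE])
  sig <- cbind(rec$status_ADH != "ns", rec$status_DCIS != "ns",
               rec$status_INV != "ns")
  dimnames(dm) <- list(rec$gene, c("ADH", "DCIS", "INV"))
  dimnames(sig) <- dimnames(dm)
  list(diffmeth = dm, significant = sig, category = rec$category)
}

#' Serialise a heat-map matrix to TSV
#'
#' @param hm From [heatmap_matrix()].
#' @param path Output path.
#' @export
write_heatmap_tsv <- function(hm, path) {
  dt <- data.table::data.table(
    gene = rownames(hm$diffmeth), category = hm$category,
    diffmeth_ADH = hm$diffmeth[, "ADH"],
    diffmeth_DCIS = hm$diffmeth[, "DCIS"],
    diffmeth_INV = hm$diffmeth[, "INV"],
    sig_ADH = hm$significant[, "ADH"],
    sig_DCIS = hm$significant[, "DCIS"],
    sig_INV = hm$significant[, "INV"]
  )
  write_tsv(dt, path)
}
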