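# Recovery metrics against simulator ground truth: given the per-stage
# promoter results and the generator's true methylation levels, score how
# well the pipeline recovers true effects (significance with the correct
# sign and progression category), how often it fires on null promoters,
# and how accurately DiffMeth estimates track the truth.

#' Evaluate pipeline output against simulation ground truth
#'
#' @param stage_results Named list of [promoter_diff()] tables, one per
#'   stage (names are group labels, e.g. ADH, DCIS, invasive).
#' @param records Stage-category records from [stage_categories()].
#' @param truth `sim_truth` from [assign_methylation()].
#' @param sign_tol True effects are gene/stage pairs with
#'   `|diffmeth_truth| > sign_tol`.
#' @return List of metrics: `pair_recovery` (fraction of true-effect
#'   gene/stage pairs called significant with the correct sign),
#'   `gene_recovery` (fraction of true-effect genes with every affected
#'   stage recovered and the progression category correct),
#'   `false_positive_rate` (fraction of null gene/stage pairs called
#'   significant), `diffmeth_within_0.1` (fraction of true-effect pairs
#'   with estimate within 0.1 of truth), `diffmeth_r` (Pearson r between
#'   estimated and true DiffMeth over all evaluable pairs), plus the
#'   underlying counts.
#' @export
evaluate_recovery <- function(stage_results, records, truth,
                              sign_tol = 1e-9) {
  gl <- truth$gene_levels
  pairs <- data.table::rbindlist(lapply(names(stage_results), function(s) {
    res <- stage_results[[s]]
    tr <- gl[gl$group == s, ]
    data.table::data.table(
      gene = res$gene, stage = s,
      est_diff = res$diffmeth, direction = res$direction,
      true_diff = tr$diffmeth_truth[match(res$gene, tr$gene)])
  }))
  pairs[, "true_status" := ifelse(abs(pairs$true_diff) <= sign_tol, "ns",
                                  ifelse(pairs$true_diff > 0, "hyper", "hypo"))]
  affected <- pairs[pairs$true_status != "ns", ]
  nulls <- pairs[pairs$true_status == "ns", ]

  pair_hits <- affected$direction == affected$true_status
  fp <- nulls$direction != "ns"

  # gene-level: every affected stage recovered and category correct
  truth_wide <- data.table::dcast(
    pairs[, list(gene, stage, true_status)], gene ~ stage,
    value.var = "true_status")
  stage_names <- names(stage_results)
  exp_cat <- mapply(classify_gene,
                    truth_wide[[stage_names[1]]],
                    truth_wide[[stage_names[2]]],
                    truth_wide[[stage_names[3]]])
  truth_wide[, "expected_category" := exp_cat]
  eff_genes <- unique(affected$gene)
  gene_ok <- vapply(eff_genes, function(g) {
    all(pair_hits[affected$gene == g]) &&
      records$category[match(g, records$gene)] ==
        truth_wide$expected_category[match(g, truth_wide$gene)]
  }, logical(1))

  evaluable <- !is.na(pairs$est_diff)
  within <- abs(affected$est_diff - affected$true_diff) <= 0.1
  list(
    n_true_pairs = nrow(affected),
    n_null_pairs = nrow(nulls),
    n_true_genes = length(eff_genes),
    pair_recovery = mean(pair_hits),
    gene_recovery = mean(gene_ok),
    false_positive_rate = mean(fp),
    n_false_positives = sum(fp),
    diffmeth_within_0.1 = mean(within[!is.na(within)]),
    diffmeth_r = if (sum(evaluable) >= 3L) {
      stats::cor(pairs$est_diff[evaluable], pairs$true_diff[evaluable])
    } else NA_real_,
    expected_categories = truth_wide
  )
}
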