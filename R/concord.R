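# Methylation-expression concordance. For genes with significantly
# hyper-/hypomethylated promoters, concordance asks whether an external
# expression table moves the expected way: promoter hypermethylation with
# downregulation (log2 fold-change below -t) or hypomethylation with
# upregulation (log2 fold-change above t). Percentages are computed per
# methylation direction over ALL significant promoters of that direction;
# genes missing from the expression table stay in the denominator and are
# flagged "no data" (the grey slice of a concordance pie). The expression
# table is assumed pre-joined to the methylation gene symbols (any
# cross-species ortholog mapping happens upstream).

#' Score direction-concordance between methylation and expression
#'
#' @param meth Significant promoter rows from [promoter_diff()] (one
#'   comparison; `direction` must be hyper/hypo).
#' @param expr data.table/data.frame with columns `gene` and `log2fc`.
#' @param t Nonnegative fold-change threshold; genes with
#'   `|log2fc| <= t` count as "no change" and are non-concordant.
#' @return List with `records` (gene, meth_direction, log2fc, status in
#'   concordant/discordant/no_change/no_data) and `summary` (per
#'   direction: n tested, n concordant, percent — rounded half away from
#'   zero).
#' @export
score_concordance <- function(meth, expr, t = 0) {
  stopifnot(t >= 0)
  meth <- data.table::as.data.table(meth)
  meth <- meth[meth$direction %in% c("hyper", "hypo"), ]
  if (nrow(meth) == 0L) stop("nothing to score: no significant promoters",
                             call. = FALSE)
  expr <- data.table::as.data.table(expr)
  if (!all(c("gene", "log2fc") %in% names(expr))) {
    stop("expression table needs columns gene and log2fc", call. = FALSE)
  }
  idx <- match(tolower(meth$gene), tolower(expr$gene))
  fc <- expr$log2fc[idx]
  status <- ifelse(is.na(fc), "no_data",
            ifelse(abs(fc) <= t, "no_change",
            ifelse((meth$direction == "hyper" & fc < -t) |
                   (meth$direction == "hypo" & fc > t),
                   "concordant", "discordant")))
  records <- data.table::data.table(
    gene = meth$gene, meth_direction = meth$direction,
    log2fc = fc, status = status)
  summary <- records[, list(
    n = .N,
    n_concordant = sum(status == "concordant"),
    percent = round_half_away(100 * sum(status == "concordant") / .N)
  ), by = "meth_direction"]
  list(records = records, summary = summary)
}

#' Concordance across several expression conditions
#'
#' Scores each condition separately and reports, per methylation
#' direction, how many genes are concordant in the first condition, how
#' many additional genes become concordant only in a later condition, and
#' the any-condition union.
#'
#' @param meth As in [score_concordance()].
#' @param expr_tables Named list of expression tables (first = primary
#'   condition).
#' @param t Fold-change threshold.
#' @return List with `per_condition` (list of [score_concordance()]
#'   summaries), `combined` (data.table per direction: n, first_n,
#'   first_percent, additional_n, any_n, any_percent).
#' @export
multi_line_concordance <- function(meth, expr_tables, t = 0) {
  stopifnot(length(expr_tables) >= 1L)
  if (is.null(names(expr_tables))) {
    names(expr_tables) <- paste0("condition", seq_along(expr_tables))
  }
  scored <- lapply(expr_tables, function(e) score_concordance(meth, e, t = t))
  conc_sets <- lapply(scored, function(s) {
    s$records$gene[s$records$status == "concordant"]
  })
  rec1 <- scored[[1L]]$records
  combined <- rec1[, list(n = .N), by = "meth_direction"]
  genes_by_dir <- split(rec1$gene, rec1$meth_direction)
  first_n <- integer(nrow(combined)); any_n <- integer(nrow(combined))
  for (i in seq_len(nrow(combined))) {
    g <- genes_by_dir[[combined$meth_direction[i]]]
    in_first <- intersect(g, conc_sets[[1L]])
    in_any <- intersect(g, unique(unlist(conc_sets)))
    first_n[i] <- length(in_first)
    any_n[i] <- length(in_any)
  }
  combined[, "first_n" := first_n]
  combined[, "first_percent" := round_half_away(100 * first_n / combined$n)]
  combined[, "additional_n" := any_n - first_n]
  combined[, "any_n" := any_n]
  combined[, "any_percent" := round_half_away(100 * any_n / combined$n)]
  list(per_condition = lapply(scored, `[[`, "summary"), combined = combined[])
}
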