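# Differential methylation between each disease stage and normal tissue.
# Replicates are pooled per group (the study's n = 3 per tissue class) and
# each CpG — or each promoter, after summing counts over its qualifying
# CpGs — is tested with a two-sided Fisher exact test on the 2x2 table
# [C_stage, T_stage; C_normal, T_normal]. DiffMeth is the difference of
# pooled methylation levels (stage minus normal) in [-1, 1]; a promoter is
# called hyper- or hypomethylated by the sign of DiffMeth when p < alpha.
# A Welch t-test on per-sample levels is available as the alternative
# inference path.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value by summing, over the
#' hypergeometric support at fixed margins, the probabilities of all
#' tables no more probable than the observed one (with a 1e-7 relative
#' slack on the comparison, the conventional guard against floating-point
#' ties).
#'
#' @param table 2x2 matrix of nonnegative integer counts
#'   `rbind(c(a, b), c(c, d))`, rows = groups, columns = C/T.
#' @return Two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_2x2(rbind(c(5, 5), c(5, 5)))    # 1
#' fisher_exact_2x2(rbind(c(10, 0), c(0, 10)))  # ~1.08e-5
fisher_exact_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  if (any(c(a, b, cc, d) < 0) || any(c(a, b, cc, d) != round(c(a, b, cc, d)))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  m1 <- a + b; m2 <- cc + d; n1 <- a + cc; n2 <- b + d
  if (m1 == 0 || m2 == 0 || n1 == 0 || n2 == 0) {
    stop("Fisher test undefined: a table margin is zero", call. = FALSE)
  }
  fisher_p(a, m1, m2, n1)
}

# p-value for observed count a with row margins m1, m2 and column-1 margin n1
fisher_p <- function(a, m1, m2, n1) {
  support <- max(0, n1 - m2):min(n1, m1)
  probs <- stats::dhyper(support, m1, m2, n1)
  p_obs <- stats::dhyper(a, m1, m2, n1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# vectorised wrapper
fisher_p_vec <- function(a, b, cc, d) {
  mapply(function(a, b, cc, d) fisher_p(a, a + b, cc + d, a + cc),
         a, b, cc, d)
}

#' Per-CpG differential methylation tests against the reference group
#'
#' For the Fisher path, counts are pooled across replicates within each
#' group and every CpG with pooled depth of at least `min_reads` in both
#' groups is tested on its 2x2 C/T table. For the t-test path, per-sample
#' methylation levels are compared with a two-sided Welch t-test
#' (requires at least two samples per group and non-degenerate levels).
#' CpGs failing the requirements are skipped with a reason, returned in
#' the `skipped` attribute.
#'
#' @param calls Coverage-filtered calls (chrom, pos, sample, count_C,
#'   count_T) across all samples.
#' @param design data.table mapping sample to group.
#' @param stage Stage group to compare.
#' @param reference_group Reference tissue group.
#' @param method `"fisher"` (pooled counts) or `"t_test"` (per-sample
#'   levels).
#' @param min_reads Minimum pooled depth per group (Fisher path).
#' @return data.table: chrom, pos, comparison, C_stage, T_stage,
#'   C_normal, T_normal, level_stage, level_normal, diffmeth, p_value,
#'   method. Attribute `skipped`: data.table of skipped CpGs with
#'   reasons.
#' @export
cpg_tests <- function(calls, design, stage, reference_group = "normal",
                      method = c("fisher", "t_test"), min_reads = 5L) {
  method <- match.arg(method)
  for (g in c(stage, reference_group)) {
    if (!g %in% design$group) {
      stop(sprintf("group '%s' missing from design", g), call. = FALSE)
    }
  }
  calls <- data.table::as.data.table(calls)
  calls[, "group" := design$group[match(calls$sample, design$sample)]]
  if (anyNA(calls$group)) {
    stop("calls contain samples absent from the design", call. = FALSE)
  }
  calls <- calls[calls$group %in% c(stage, reference_group), ]
  comparison <- paste0(stage, "_vs_", reference_group)

  empty <- data.table::data.table(
    chrom = character(), pos = integer(), comparison = character(),
    C_stage = integer(), T_stage = integer(), C_normal = integer(),
    T_normal = integer(), level_stage = numeric(), level_normal = numeric(),
    diffmeth = numeric(), p_value = numeric(), method = character())

  pooled <- calls[, list(C = sum(count_C), T = sum(count_T)),
                  by = c("chrom", "pos", "group")]
  wide <- data.table::dcast(pooled, chrom + pos ~ group,
                            value.var = c("C", "T"), fill = 0L)
  sc <- paste0("C_", stage); st <- paste0("T_", stage)
  rc <- paste0("C_", reference_group); rt <- paste0("T_", reference_group)
  for (col in c(sc, st, rc, rt)) if (!col %in% names(wide)) wide[, (col) := 0L]

  cov_s <- wide[[sc]] + wide[[st]]
  cov_r <- wide[[rc]] + wide[[rt]]
  ok <- cov_s >= min_reads & cov_r >= min_reads
  skipped <- data.table::data.table(
    chrom = wide$chrom[!ok], pos = wide$pos[!ok],
    reason = ifelse(cov_s[!ok] == 0L | cov_r[!ok] == 0L,
                    "missing group coverage", "pooled coverage below minimum"))
  wide <- wide[ok, ]
  if (nrow(wide) == 0L) {
    data.table::setattr(empty, "skipped", skipped)
    return(empty)
  }

  res <- data.table::data.table(
    chrom = wide$chrom, pos = wide$pos, comparison = comparison,
    C_stage = wide[[sc]], T_stage = wide[[st]],
    C_normal = wide[[rc]], T_normal = wide[[rt]])
  res[, "level_stage" := res$C_stage / (res$C_stage + res$T_stage)]
  res[, "level_normal" := res$C_normal / (res$C_normal + res$T_normal)]
  res[, "diffmeth" := res$level_stage - res$level_normal]

  if (method == "fisher") {
    res[, "p_value" := fisher_p_vec(res$C_stage, res$T_stage,
                                    res$C_normal, res$T_normal)]
  } else {
    levels_by <- calls[, list(level = sum(count_C) / (sum(count_C) + sum(count_T))),
                       by = c("chrom", "pos", "group", "sample")]
    key <- paste(res$chrom, res$pos)
    pv <- rep(NA_real_, nrow(res))
    drop <- logical(nrow(res))
    for (i in seq_len(nrow(res))) {
      sub <- levels_by[paste(levels_by$chrom, levels_by$pos) == key[i], ]
      x <- sub$level[sub$group == stage]
      y <- sub$level[sub$group == reference_group]
      if (length(x) < 2L || length(y) < 2L) { drop[i] <- TRUE; next }
      if (stats::sd(c(x, y)) == 0) { pv[i] <- 1; next }
      pv[i] <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
    }
    if (any(drop)) {
      skipped <- rbind(skipped, data.table::data.table(
        chrom = res$chrom[drop], pos = res$pos[drop],
        reason = "fewer than two samples per group"))
      res <- res[!drop, ]; pv <- pv[!drop]
    }
    res[, "p_value" := pv]
  }
  res[, "method" := if (method == "fisher") "fisher" else "t_test"]
  data.table::setattr(res, "skipped", skipped)
  res[]
}

#' Promoter-level differential methylation (DiffMeth)
#'
#' Pools C/T counts over all qualifying CpGs of each promoter within each
#' group, computes group levels and their difference (DiffMeth = stage
#' minus normal), and tests the pooled 2x2 table with the Fisher exact
#' test. Direction is `hyper`/`hypo` by the sign of DiffMeth when
#' `p < alpha` and `|DiffMeth| >= min_effect`, otherwise `ns`. Promoters
#' with no qualifying CpG are emitted with `direction = "ns"`, `p = NA`
#' and note `"no coverage"`.
#'
#' @param calls Coverage-filtered, promoter-annotated calls (needs a
#'   `promoter` column from [annotate_cpgs()]).
#' @param genes Gene annotation (gene column; all genes are reported).
#' @param design Sample-to-group design table.
#' @param stage Stage group to compare.
#' @param reference_group Reference group.
#' @param alpha Significance level on the raw p-value (the analysis uses
#'   unadjusted p < 0.05; see `adjust`).
#' @param min_effect Minimum |DiffMeth| for a directional call.
#' @param min_reads Minimum pooled depth per group per CpG.
#' @param mode `"pooled"` (counts summed over CpGs; default) or
#'   `"mean_of_levels"` (DiffMeth from unweighted mean per-CpG levels;
#'   the Fisher test still uses pooled counts).
#' @param adjust If `TRUE`, direction calls use Benjamini-Hochberg
#'   adjusted p-values (`p_adj` column is always reported).
#' @return data.table: gene, comparison, n_cpgs, level_stage,
#'   level_normal, diffmeth, p_value, p_adj, direction, note.
#' @export
promoter_diff <- function(calls, genes, design, stage,
                          reference_group = "normal", alpha = 0.05,
                          min_effect = 0, min_reads = 5L,
                          mode = c("pooled", "mean_of_levels"),
                          adjust = FALSE) {
  mode <- match.arg(mode)
  tests <- cpg_tests(calls, design, stage, reference_group,
                     method = "fisher", min_reads = min_reads)
  comparison <- paste0(stage, "_vs_", reference_group)

  # map tested CpGs back to their promoter gene(s)
  ann <- data.table::as.data.table(calls)[, c("chrom", "pos", "promoter"),
                                          with = FALSE]
  ann <- unique(ann[!is.na(ann$promoter), ])
  # a CpG may sit in several promoters; expand
  ann <- ann[, list(gene = strsplit(promoter, ",", fixed = TRUE)[[1]]),
             by = c("chrom", "pos")]
  tagged <- merge(tests, ann, by = c("chrom", "pos"),
                  allow.cartesian = TRUE)

  out <- data.table::data.table(
    gene = genes$gene, comparison = comparison, n_cpgs = 0L,
    level_stage = NA_real_, level_normal = NA_real_, diffmeth = NA_real_,
    p_value = NA_real_, p_adj = NA_real_, direction = "ns",
    note = "no coverage")
  if (nrow(tagged)) {
    agg <- tagged[, list(
      n_cpgs = .N,
      Cs = sum(C_stage), Ts = sum(T_stage),
      Cn = sum(C_normal), Tn = sum(T_normal),
      mean_level_stage = mean(level_stage),
      mean_level_normal = mean(level_normal)
    ), by = "gene"]
    agg[, "level_stage" := agg$Cs / (agg$Cs + agg$Ts)]
    agg[, "level_normal" := agg$Cn / (agg$Cn + agg$Tn)]
    if (mode == "mean_of_levels") {
      agg[, "level_stage" := agg$mean_level_stage]
      agg[, "level_normal" := agg$mean_level_normal]
    }
    agg[, "diffmeth" := agg$level_stage - agg$level_normal]
    agg[, "p_value" := fisher_p_vec(agg$Cs, agg$Ts, agg$Cn, agg$Tn)]
    agg[, "p_adj" := stats::p.adjust(agg$p_value, method = "BH")]
    idx <- match(agg$gene, out$gene)
    known <- !is.na(idx)
    for (col in c("n_cpgs", "level_stage", "level_normal", "diffmeth",
                  "p_value", "p_adj")) {
      data.table::set(out, i = idx[known], j = col, value = agg[[col]][known])
    }
    p_dir <- if (adjust) out$p_adj else out$p_value
    sig <- !is.na(p_dir) & p_dir < alpha & abs(out$diffmeth) >= min_effect &
      out$diffmeth != 0
    data.table::set(out, j = "direction",
                    value = ifelse(sig & out$diffmeth > 0, "hyper",
                                   ifelse(sig & out$diffmeth < 0, "hypo", "ns")))
    data.table::set(out, i = which(!is.na(out$p_value)), j = "note", value = "")
  }
  out[]
}

#' Round DiffMeth for reporting
#'
#' Internal precision is kept in full; reports show two decimals.
#' @param x Numeric vector.
#' @export
format_diffmeth <- function(x) round(x, 2)
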