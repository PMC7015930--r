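# Orchestration: simulate (or load) -> digest -> align -> call -> diff ->
# classify -> concordance, as one seeded, logged, resumable run. Every
# output lands under `out_dir`; a JSON manifest records the parameters and
# md5 checksums of inputs and outputs so deterministic stages can be
# skipped on rerun (outputs present + recorded input checksums unchanged)
# and so any divergence between a run and its configuration is auditable.

#' Build and validate a pipeline run configuration
#'
#' Either `sim` (a [sim_config()]; the pipeline generates its own inputs)
#' or all of `genome_fasta`, `genes_tsv`, `design_tsv` (with a `fastq`
#' column per sample) must be provided.
#'
#' @param out_dir Output directory.
#' @param sim Optional [sim_config()] for a simulated run.
#' @param genome_fasta,genes_tsv,design_tsv File-based inputs (ignored
#'   when `sim` is given). `genes_tsv` needs gene, chrom, tss, strand.
#' @param expression Optional expression table (data.frame or TSV path
#'   with gene, log2fc) for concordance scoring against the invasive
#'   comparison.
#' @param islands_bed Optional CpG-island BED overriding detection.
#' @param min_len,max_len,end_len Digestion window and fragment-end
#'   length.
#' @param max_conv_mismatch,max_mismatch,min_uniq_gap,min_anchor Aligner
#'   caps.
#' @param min_reads Per-CpG pooled coverage minimum.
#' @param promoter_up,promoter_down Promoter extent around the TSS.
#' @param alpha Significance level.
#' @param min_effect Minimum |DiffMeth| for a directional call.
#' @param diff_method `"fisher"` or `"t_test"` for the CpG-level tables.
#' @param concordance_t Expression fold-change threshold.
#' @param reference_group Name of the reference tissue group.
#' @param resume Reuse outputs of unchanged stages when present.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir,
                       sim = NULL,
                       genome_fasta = NULL, genes_tsv = NULL,
                       design_tsv = NULL, expression = NULL,
                       islands_bed = NULL,
                       min_len = 40L, max_len = 350L, end_len = 50L,
                       max_conv_mismatch = 3L, max_mismatch = 3L,
                       min_uniq_gap = 2L, min_anchor = 20L,
                       min_reads = 5L,
                       promoter_up = 1000L, promoter_down = 500L,
                       alpha = 0.05, min_effect = 0,
                       diff_method = "fisher",
                       concordance_t = 0,
                       reference_group = "normal",
                       resume = TRUE) {
  cfg <- as.list(environment())
  if (is.null(sim)) {
    for (f in c("genome_fasta", "genes_tsv", "design_tsv")) {
      if (is.null(cfg[[f]])) {
        stop(sprintf("run_config needs either 'sim' or '%s'", f),
             call. = FALSE)
      }
      if (!file.exists(cfg[[f]])) {
        stop(sprintf("%s '%s' does not exist", f, cfg[[f]]), call. = FALSE)
      }
    }
    design <- read_tsv(cfg$design_tsv, required = c("sample", "group", "fastq"))
    if (sum(design$group == reference_group) < 1L) {
      stop(sprintf("design has no sample in reference group '%s'",
                   reference_group), call. = FALSE)
    }
    missing_fq <- design$fastq[!file.exists(design$fastq)]
    if (length(missing_fq)) {
      stop(sprintf("FASTQ file(s) missing: %s",
                   paste(missing_fq, collapse = ", ")), call. = FALSE)
    }
  } else {
    stopifnot(inherits(sim, "sim_config"))
  }
  if (is.character(expression) && length(expression) == 1L &&
      !file.exists(expression)) {
    stop(sprintf("expression table '%s' does not exist", expression),
         call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1, min_reads >= 1L)
  structure(cfg, class = "run_config")
}

config_fingerprint <- function(config) {
  flat <- config
  flat$resume <- NULL
  raw <- jsonlite::toJSON(lapply(flat, function(x) {
    if (inherits(x, "data.table") || is.data.frame(x)) {
      as.list(as.data.frame(x))
    } else x
  }), auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  chars <- utf8ToInt(as.character(raw))
  as.character(sum(chars * seq_along(chars)) %% 2147483647)
}

stage_current <- function(manifest, stage, inputs_hash, outputs) {
  !is.null(manifest$stages[[stage]]) &&
    identical(manifest$stages[[stage]]$inputs_hash, inputs_hash) &&
    all(file.exists(outputs))
}

#' Run the full RRBS differential-methylation pipeline
#'
#' Executes simulate/load -> digest -> align -> methylation calling ->
#' per-stage promoter differential methylation -> stage classification
#' (Venn + heat-map) -> optional expression concordance, writing every
#' artifact under `config$out_dir` along with `manifest.json`.
#'
#' @param config A [run_config()].
#' @return List with design, reference, calls (filtered + annotated),
#'   islands, stage_results (per stage), records, venn, heatmap,
#'   concordance (or NULL), alignment_summary, truth (simulated runs),
#'   and the manifest path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (config$resume && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else list()
  fp <- config_fingerprint(config)
  if (!identical(manifest$config_fingerprint, fp)) manifest <- list()
  manifest$config_fingerprint <- fp
  manifest$package_version <- as.character(utils::packageVersion("rrbstage"))
  if (is.null(manifest$stages)) manifest$stages <- list()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  truth <- NULL
  if (!is.null(config$sim)) {
    say("simulate: seed %d, %d genes over %d bp, %d groups x %d replicates",
        config$sim$seed, config$sim$n_genes, config$sim$genome_length,
        length(config$sim$groups), config$sim$n_replicates_per_group)
    sg <- generate_genome(config$sim)
    truth <- assign_methylation(config$sim, sg)
    sim <- simulate_reads(config$sim, sg, truth)
    genome <- sg$genome
    genes <- sg$genes
    design <- sim$design
    reads_by_sample <- sim$reads
    write_fasta(genome, file.path(out, "genome.fa"))
    write_tsv(genes, file.path(out, "genes.tsv"))
    write_simulation(sim, truth, file.path(out, "sim"))
  } else {
    genome <- read_fasta(config$genome_fasta)
    genes <- read_tsv(config$genes_tsv,
                      required = c("gene", "chrom", "tss", "strand"))
    design <- read_tsv(config$design_tsv,
                       required = c("sample", "group", "fastq"))
    reads_by_sample <- lapply(stats::setNames(design$fastq, design$sample),
                              read_fastq)
  }

  say("digest: MspI+TaqI, size window [%d, %d] bp, %d bp ends",
      config$min_len, config$max_len, config$end_len)
  frags <- predict_fragments(genome, config$min_len, config$max_len)
  reference <- build_reference(frags, genome, config$end_len)
  write_reference(reference, file.path(out, "reference.fa"),
                  file.path(out, "reference.tsv"))
  say("digest: %d in-range fragments -> %d reference entries",
      nrow(frags), nrow(reference))

  say("align: caps conv<=%d bs<=%d, uniqueness gap >= %d",
      config$max_conv_mismatch, config$max_mismatch, config$min_uniq_gap)
  aln_summaries <- list()
  calls_by_sample <- list()
  ref_hash <- unname(tools::md5sum(file.path(out, "reference.tsv")))
  for (s in design$sample) {
    aln_path <- file.path(out, sprintf("alignments_%s.tsv", s))
    inputs_hash <- if (!is.null(config$sim)) {
      paste(ref_hash, "sim", config$sim$seed, length(reads_by_sample[[s]]))
    } else {
      paste(ref_hash, unname(tools::md5sum(design$fastq[design$sample == s])))
    }
    stage_id <- paste0("align:", s)
    if (config$resume && stage_current(manifest, stage_id, inputs_hash,
                                       aln_path)) {
      aln <- read_tsv(aln_path)
      say("align: %s -> reusing %d cached alignments", s, nrow(aln))
    } else {
      aln <- align_reads(reads_by_sample[[s]], reference,
                         max_conv_mismatch = config$max_conv_mismatch,
                         max_mismatch = config$max_mismatch,
                         min_uniq_gap = config$min_uniq_gap,
                         min_anchor = config$min_anchor)
      write_tsv(aln, aln_path)
      manifest$stages[[stage_id]] <- list(inputs_hash = inputs_hash)
      say("align: %s -> %d reads, %d unique, %d ambiguous, %d unmapped",
          s, nrow(aln), sum(aln$status == "unique"),
          sum(aln$status == "ambiguous_discarded"),
          sum(aln$status == "unmapped"))
    }
    aln_summaries[[s]] <- c(n_reads = nrow(aln),
                            unique = sum(aln$status == "unique"),
                            ambiguous_discarded = sum(aln$status == "ambiguous_discarded"),
                            unmapped = sum(aln$status == "unmapped"))
    calls_by_sample[[s]] <- pileup_cpg(aln, reference,
                                       reads_by_sample[[s]], sample_id = s)
  }
  aln_dt <- data.table::data.table(
    sample = names(aln_summaries),
    do.call(rbind, lapply(aln_summaries, as.list)))
  write_tsv(aln_dt, file.path(out, "alignment_summary.tsv"))

  calls <- data.table::rbindlist(calls_by_sample)
  calls <- filter_coverage(calls, config$min_reads)
  islands <- if (!is.null(config$islands_bed)) {
    read_bed(config$islands_bed)
  } else {
    detect_cpg_islands(genome)
  }
  write_bed(islands, file.path(out, "cpg_islands.bed"))
  calls <- annotate_cpgs(calls, genes, islands,
                         promoter_up = config$promoter_up,
                         promoter_down = config$promoter_down)
  write_tsv(calls, file.path(out, "cpg_calls.tsv"))
  say("call: %d CpG-by-sample records pass coverage >= %d",
      nrow(calls), config$min_reads)

  groups <- unique(design$group)
  stages <- setdiff(groups, config$reference_group)
  stage_results <- list()
  for (stg in stages) {
    res <- promoter_diff(calls, genes, design, stage = stg,
                         reference_group = config$reference_group,
                         alpha = config$alpha,
                         min_effect = config$min_effect,
                         min_reads = config$min_reads)
    stage_results[[stg]] <- res
    write_tsv(res, file.path(out, sprintf("promoter_diff_%s.tsv", stg)))
    cpg_res <- cpg_tests(calls, design, stage = stg,
                         reference_group = config$reference_group,
                         method = config$diff_method,
                         min_reads = config$min_reads)
    write_tsv(cpg_res, file.path(out, sprintf("cpg_diff_%s.tsv", stg)))
    say("diff: %s vs %s -> %d/%d promoters significant at alpha=%g",
        stg, config$reference_group, sum(res$direction != "ns"),
        nrow(res), config$alpha)
  }

  records <- venn <- hm <- NULL
  if (length(stages) >= 3L) {
    records <- stage_categories(stage_results[[stages[1]]],
                                stage_results[[stages[2]]],
                                stage_results[[stages[3]]])
    venn <- venn_counts(records)
    hm <- heatmap_matrix(records)
    write_tsv(records, file.path(out, "stage_categories.tsv"))
    write_tsv(venn$per_stage, file.path(out, "venn_per_stage.tsv"))
    write_tsv(data.table::data.table(region = names(venn$overlaps),
                                     count = as.integer(venn$overlaps)),
              file.path(out, "venn_overlaps.tsv"))
    write_heatmap_tsv(hm, file.path(out, "heatmap.tsv"))
    say("classify: categories %s",
        paste(sprintf("%s=%d", names(table(records$category)),
                      table(records$category)), collapse = ", "))
  }

  concordance <- NULL
  if (!is.null(config$expression) && !is.null(records)) {
    expr <- if (is.character(config$expression)) {
      read_tsv(config$expression, required = c("gene", "log2fc"))
    } else data.table::as.data.table(config$expression)
    inv <- stage_results[[stages[length(stages)]]]
    sig <- inv[inv$direction != "ns", ]
    if (nrow(sig)) {
      concordance <- score_concordance(sig, expr, t = config$concordance_t)
      write_tsv(concordance$records, file.path(out, "concordance_records.tsv"))
      write_json_summary(concordance$summary,
                         file.path(out, "concordance_summary.json"))
      say("concord: %s",
          paste(sprintf("%s %d/%d (%g%%)", concordance$summary$meth_direction,
                        concordance$summary$n_concordant,
                        concordance$summary$n, concordance$summary$percent),
                collapse = "; "))
    }
  }

  manifest$parameters <- lapply(unclass(config), function(x) {
    if (inherits(x, "sim_config")) unclass(x) else x
  })
  manifest$outputs <- as.list(tools::md5sum(list.files(out, full.names = TRUE,
                                                       recursive = TRUE,
                                                       pattern = "\\.(tsv|fa|bed|fastq|json)$")))
  writeLines(log_lines, file.path(out, "pipeline.log"))
  write_json_summary(manifest, manifest_path)

  list(design = design, reference = reference, calls = calls,
       islands = islands, stage_results = stage_results, records = records,
       venn = venn, heatmap = hm, concordance = concordance,
       alignment_summary = aln_dt, truth = truth, manifest = manifest_path)
}
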