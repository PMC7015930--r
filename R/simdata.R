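# Synthetic-data generator emulating the study design: a small genome with
# CpG-dense promoters, four tissue groups (normal, ADH, DCIS, invasive) with
# n biological replicates each, and directional RRBS reads from the 5' ends
# of size-selected MspI/TaqI fragments carrying per-CpG binomial methylation
# signal, bisulfite conversion failure and sequencing error. Ground truth
# (per-gene and per-CpG methylation levels per group) is exported separately
# from the FASTQ so downstream recovery tests cannot leak it.

SIM_GROUPS <- c("normal", "ADH", "DCIS", "invasive")

#' Construct and validate a simulation configuration
#'
#' @param seed Master seed; together with the other fields it fully
#'   determines every simulator output.
#' @param genome_length Total genome size in bp, split evenly across
#'   chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param n_genes Number of genes (evenly spread over chromosomes).
#' @param promoter_cpg_density Probability, per emitted token during
#'   promoter sequence synthesis, of inserting a CpG dinucleotide
#'   (controls CpG density inside promoters).
#' @param background_cpg_density Same, outside promoters.
#' @param n_replicates_per_group Biological replicates per tissue group
#'   (the study profiles n = 3 dogs per group).
#' @param groups Ordered group labels; the first is the reference
#'   ("normal") tissue.
#' @param baseline_methylation Either a single promoter methylation level
#'   applied to every gene or a length-2 range from which per-gene
#'   baselines are drawn uniformly.
#' @param background_methylation Methylation level of CpGs outside
#'   promoters (genomic CpGs are typically heavily methylated).
#' @param effect_table `NULL`, or a data.frame with columns gene, group,
#'   delta giving the methylation change (stage minus normal, in [-1, 1])
#'   for specific gene/group pairs; unlisted pairs have delta 0.
#' @param mean_coverage Poisson mean read count per fragment end per
#'   sample.
#' @param read_length Read length in bp (reads are fragment-end prefixes).
#' @param bisulfite_conversion_rate Probability that an unmethylated C is
#'   converted (read as T).
#' @param sequencing_error_rate Per-base substitution error probability.
#' @param replicate_kappa Concentration of the Beta distribution from
#'   which each sample's promoter methylation level is drawn around the
#'   group truth (`Beta(m*kappa, (1-m)*kappa)`); `Inf` disables
#'   between-replicate biological noise.
#' @param size_windows List of length-2 vectors: fragment-length windows
#'   retained by gel size selection.
#' @param read_end_len Fragment-end length used during read generation
#'   (matches the reference `end_len`).
#' @param promoter_up,promoter_down Promoter extent upstream/downstream of
#'   the TSS in bp.
#' @param gene_body_length Gene body length in bp.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       n_chromosomes = 1L,
                       n_genes = 20L,
                       promoter_cpg_density = 0.15,
                       background_cpg_density = 0.01,
                       n_replicates_per_group = 3L,
                       groups = SIM_GROUPS,
                       baseline_methylation = c(0.3, 0.8),
                       background_methylation = 0.75,
                       effect_table = NULL,
                       mean_coverage = 30,
                       read_length = 50L,
                       bisulfite_conversion_rate = 0.99,
                       sequencing_error_rate = 0.001,
                       replicate_kappa = 50,
                       size_windows = list(c(40L, 120L), c(120L, 350L)),
                       read_end_len = 50L,
                       promoter_up = 1000L,
                       promoter_down = 500L,
                       gene_body_length = 2000L) {
  cfg <- list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_chromosomes = as.integer(n_chromosomes), n_genes = as.integer(n_genes),
    promoter_cpg_density = promoter_cpg_density,
    background_cpg_density = background_cpg_density,
    n_replicates_per_group = as.integer(n_replicates_per_group),
    groups = groups, baseline_methylation = baseline_methylation,
    background_methylation = background_methylation,
    effect_table = if (is.null(effect_table)) NULL else data.table::as.data.table(effect_table),
    mean_coverage = mean_coverage, read_length = as.integer(read_length),
    bisulfite_conversion_rate = bisulfite_conversion_rate,
    sequencing_error_rate = sequencing_error_rate,
    replicate_kappa = replicate_kappa,
    size_windows = size_windows, read_end_len = as.integer(read_end_len),
    promoter_up = as.integer(promoter_up),
    promoter_down = as.integer(promoter_down),
    gene_body_length = as.integer(gene_body_length)
  )
  probs <- c(cfg$promoter_cpg_density, cfg$background_cpg_density,
             cfg$baseline_methylation, cfg$background_methylation,
             cfg$bisulfite_conversion_rate, cfg$sequencing_error_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities in a sim_config must lie in [0, 1]", call. = FALSE)
  }
  if (!length(cfg$groups) || cfg$groups[1] != "normal") {
    stop("groups must start with the reference group 'normal'", call. = FALSE)
  }
  if (!is.null(cfg$effect_table)) {
    need <- c("gene", "group", "delta")
    if (!all(need %in% names(cfg$effect_table))) {
      stop("effect_table needs columns gene, group, delta", call. = FALSE)
    }
    if (any(abs(cfg$effect_table$delta) > 1)) {
      stop("effect_table deltas must lie in [-1, 1]", call. = FALSE)
    }
    if (any(!cfg$effect_table$group %in% cfg$groups)) {
      stop("effect_table refers to unknown group(s)", call. = FALSE)
    }
    if (any(cfg$effect_table$group == "normal" & cfg$effect_table$delta != 0)) {
      stop("effect_table cannot assign a nonzero delta to the reference group",
           call. = FALSE)
    }
  }
  span <- cfg$promoter_up + cfg$promoter_down
  if (cfg$n_genes > 0L && cfg$genome_length < 2L * cfg$n_genes * span) {
    stop(sprintf(
      "genome_length %d too short for %d genes with %d bp promoters",
      cfg$genome_length, cfg$n_genes, span), call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Emit n bases of random sequence where, at each step, a CpG dinucleotide is
# inserted with probability `cpg_density` and otherwise a single base drawn
# at a mildly AT-rich composition (GC ~= 0.40, as in mammalian genomes), so
# background sequence is CpG-poor and fails windowed island criteria while
# CpG-enriched promoters pass them.
random_dna <- function(n, cpg_density,
                       base_probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  if (n <= 0L) return(character(0))
  # generate enough tokens: expected length per token = 1 + cpg_density
  n_tok <- ceiling(n / (1 + cpg_density)) + ceiling(4 * sqrt(n)) + 8L
  is_cpg <- stats::runif(n_tok) < cpg_density
  toks <- character(n_tok)
  toks[is_cpg] <- "CG"
  toks[!is_cpg] <- sample(names(base_probs), sum(!is_cpg), replace = TRUE,
                          prob = base_probs)
  out <- strsplit(paste(toks, collapse = ""), "", fixed = TRUE)[[1]]
  while (length(out) < n) {
    out <- c(out, sample(names(base_probs), n - length(out), replace = TRUE,
                         prob = base_probs))
  }
  out[seq_len(n)]
}

#' Generate a synthetic genome and gene annotation
#'
#' Chromosome sequences are random DNA at the background CpG density, with
#' promoter windows re-synthesised at the (much higher) promoter CpG
#' density so that MspI/TaqI sites concentrate there, as in real RRBS.
#' Genes are evenly spaced with alternating strands; promoters span
#' `[TSS - promoter_up, TSS + promoter_down)` (mirrored on minus-strand
#' genes) and gene bodies extend `gene_body_length` downstream of the TSS.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector) and `genes`
#'   (data.table: gene, chrom, tss, strand, promoter_start, promoter_end,
#'   body_start, body_end; all coordinates 0-based half-open).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "genome"))
  chrom_len <- rep(config$genome_length %/% config$n_chromosomes,
                   config$n_chromosomes)
  chrom_len[config$n_chromosomes] <- config$genome_length -
    sum(chrom_len[-config$n_chromosomes])
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))

  chars <- lapply(chrom_len, random_dna, cpg_density = config$background_cpg_density)
  names(chars) <- chrom_names

  genes <- data.table::data.table(
    gene = character(), chrom = character(), tss = integer(),
    strand = character(), promoter_start = integer(),
    promoter_end = integer(), body_start = integer(), body_end = integer()
  )
  if (config$n_genes > 0L) {
    chrom_of <- rep(chrom_names, length.out = config$n_genes)
    idx_in_chrom <- stats::ave(seq_len(config$n_genes),
                               chrom_of, FUN = seq_along)
    n_in_chrom <- table(chrom_of)[chrom_of]
    span <- config$promoter_up + config$promoter_down
    rows <- vector("list", config$n_genes)
    for (i in seq_len(config$n_genes)) {
      chrom <- chrom_of[i]
      L <- chrom_len[match(chrom, chrom_names)]
      slot <- L %/% as.integer(n_in_chrom[i])
      mid <- (idx_in_chrom[i] - 1L) * slot + slot %/% 2L
      strand <- if (i %% 2L == 1L) "+" else "-"
      tss <- mid
      if (strand == "+") {
        p_start <- tss - config$promoter_up
        p_end <- tss + config$promoter_down
        b_start <- tss
        b_end <- min(L, tss + config$gene_body_length)
      } else {
        p_start <- tss - config$promoter_down
        p_end <- tss + config$promoter_up
        b_end <- tss
        b_start <- max(0L, tss - config$gene_body_length)
      }
      p_start <- max(0L, p_start); p_end <- min(L, p_end)
      if (p_end - p_start < span) {
        stop("gene does not fit inside its chromosome; increase genome_length",
             call. = FALSE)
      }
      # CpG-enrich the promoter window
      chars[[chrom]][(p_start + 1L):p_end] <-
        random_dna(p_end - p_start, config$promoter_cpg_density)
      rows[[i]] <- list(gene = sprintf("g%03d", i), chrom = chrom,
                        tss = tss, strand = strand,
                        promoter_start = p_start, promoter_end = p_end,
                        body_start = b_start, body_end = b_end)
    }
    genes <- data.table::rbindlist(rows)
  }
  genome <- vapply(chars, paste, character(1), collapse = "")
  list(genome = genome, genes = genes)
}

#' Assign ground-truth methylation levels per gene, group and CpG
#'
#' Every CpG inside a promoter carries that gene's group-specific level
#' (baseline plus the gene/group delta, clipped to [0, 1]); CpGs outside
#' promoters carry the background level in every group, so they are true
#' nulls for differential testing.
#'
#' @param config A [sim_config()].
#' @param sim_genome Output of [generate_genome()].
#' @return `sim_truth` list with `gene_levels` (gene, group, level,
#'   diffmeth_truth = level - normal level) and `cpg_truth` (chrom, pos,
#'   gene or NA, one level column per group).
#' @export
assign_methylation <- function(config, sim_genome) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sim_genome$genes
  set.seed(substream_seed(config$seed, "methylation"))

  if (!is.null(config$effect_table)) {
    unknown <- setdiff(unique(config$effect_table$gene), genes$gene)
    if (length(unknown)) {
      stop(sprintf("effect_table names unknown gene(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  n_genes <- nrow(genes)
  baseline <- if (length(config$baseline_methylation) == 1L) {
    rep(config$baseline_methylation, n_genes)
  } else {
    stats::runif(n_genes, config$baseline_methylation[1],
                 config$baseline_methylation[2])
  }

  grid <- data.table::CJ(gene = genes$gene, group = config$groups,
                         sorted = FALSE)
  grid[, "baseline" := baseline[match(grid$gene, genes$gene)]]
  grid[, "delta" := 0]
  if (!is.null(config$effect_table) && nrow(config$effect_table)) {
    et <- config$effect_table
    idx <- match(paste(grid$gene, grid$group), paste(et$gene, et$group))
    grid[!is.na(idx), "delta" := et$delta[idx[!is.na(idx)]]]
  }
  grid[, "level" := clip01(grid$baseline + grid$delta)]
  normal_level <- grid[grid$group == "normal", ]
  grid[, "diffmeth_truth" := grid$level -
         normal_level$level[match(grid$gene, normal_level$gene)]]
  gene_levels <- grid[, c("gene", "group", "level", "diffmeth_truth"),
                      with = FALSE]

  # per-CpG truth: locate every CpG, attach promoter gene where applicable
  cpg_rows <- lapply(names(sim_genome$genome), function(chrom) {
    seq <- sim_genome$genome[[chrom]]
    if (nchar(seq) < 2L) return(NULL)
    m <- Biostrings::matchPattern("CG", Biostrings::DNAString(seq), fixed = TRUE)
    pos <- BiocGenerics::start(m) - 1L
    if (!length(pos)) return(NULL)
    data.table::data.table(chrom = chrom, pos = pos)
  })
  cpg <- data.table::rbindlist(cpg_rows)
  if (nrow(cpg)) {
    cpg[, "gene" := NA_character_]
    if (n_genes > 0L) {
      for (i in seq_len(n_genes)) {
        hit <- cpg$chrom == genes$chrom[i] &
          cpg$pos >= genes$promoter_start[i] & cpg$pos < genes$promoter_end[i]
        cpg[hit, "gene" := genes$gene[i]]
      }
    }
    for (g in config$groups) {
      lv <- gene_levels[gene_levels$group == g, ]
      val <- lv$level[match(cpg$gene, lv$gene)]
      val[is.na(val)] <- config$background_methylation
      cpg[, (g) := val]
    }
  }
  structure(list(gene_levels = gene_levels, cpg_truth = cpg),
            class = "sim_truth")
}

#' Simulate directional RRBS bisulfite reads per sample
#'
#' Reads are generated from both 5' ends of every size-selected fragment
#' (directional protocol: only the two bisulfite-converted original
#' strands are read). Per sample, read counts per fragment end are
#' Poisson(`mean_coverage`); each sample's promoter methylation levels are
#' drawn from `Beta(m*kappa, (1-m)*kappa)` around the group truth
#' (biological replicate noise; disabled when `replicate_kappa = Inf`).
#' A CpG-context C is emitted as C with the site's methylation
#' probability; an unmethylated or non-CpG C escapes conversion (stays C)
#' with probability `1 - bisulfite_conversion_rate`; uniform substitution
#' errors are applied last.
#'
#' @param config A [sim_config()].
#' @param sim_genome Output of [generate_genome()].
#' @param truth Output of [assign_methylation()].
#' @return List with `design` (sample, group, replicate), `reads` (named
#'   list: per sample a named character vector of read sequences) and
#'   `origin` (data.table read_id, sample, entry_id, chrom, strand,
#'   start — the truth sidecar, kept apart from the FASTQ).
#' @export
simulate_reads <- function(config, sim_genome, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  win <- range(unlist(config$size_windows))
  frags <- predict_fragments(sim_genome$genome, min_len = win[1], max_len = win[2])
  in_any <- rep(FALSE, nrow(frags))
  for (w in config$size_windows) {
    in_any <- in_any | (frags$length >= w[1] & frags$length <= w[2])
  }
  frags <- frags[in_any]
  if (nrow(frags) == 0L) {
    stop("digestion yields no fragment inside the size windows", call. = FALSE)
  }
  ref <- build_reference(frags, sim_genome$genome,
                         end_len = config$read_end_len)

  design <- data.table::CJ(group = config$groups,
                           replicate = seq_len(config$n_replicates_per_group),
                           sorted = FALSE)
  design[, "sample" := paste0(design$group, "_", design$replicate)]
  data.table::setcolorder(design, c("sample", "group", "replicate"))

  genes <- sim_genome$genes
  cpg_truth <- truth$cpg_truth
  # fast lookup: methylation probability per (chrom,pos) per group
  cpg_key <- paste(cpg_truth$chrom, cpg_truth$pos)

  entry_chars <- strsplit(ref$raw_seq, "", fixed = TRUE)
  entry_len <- pmin(ref$length, config$read_length)
  n_entries <- nrow(ref)

  reads_by_sample <- vector("list", nrow(design))
  origin_by_sample <- vector("list", nrow(design))
  for (s in seq_len(nrow(design))) {
    sample_id <- design$sample[s]
    grp <- design$group[s]
    set.seed(substream_seed(config$seed, paste0("reads:", sample_id)))

    # per-sample promoter levels with biological noise
    gl <- truth$gene_levels[which(truth$gene_levels$group == grp), ]
    level_s <- gl$level
    if (is.finite(config$replicate_kappa) && nrow(gl)) {
      k <- config$replicate_kappa
      jitter <- level_s > 0 & level_s < 1
      level_s[jitter] <- stats::rbeta(sum(jitter),
                                      level_s[jitter] * k,
                                      (1 - level_s[jitter]) * k)
    }
    # per-CpG emission probability for this sample
    if (nrow(cpg_truth)) {
      m_site <- ifelse(is.na(cpg_truth$gene),
                       config$background_methylation,
                       level_s[match(cpg_truth$gene, gl$gene)])
      names(m_site) <- cpg_key
    } else {
      m_site <- numeric(0)
    }

    n_reads <- stats::rpois(n_entries, config$mean_coverage)
    total <- sum(n_reads)
    seqs <- character(total)
    ids <- character(total)
    entry_of <- integer(total)
    pos <- 0L
    conv <- config$bisulfite_conversion_rate
    err <- config$sequencing_error_rate
    bases <- c("A", "C", "G", "T")
    for (e in seq_len(n_entries)) {
      n <- n_reads[e]
      if (n == 0L) next
      L <- entry_len[e]
      tmpl <- entry_chars[[e]][seq_len(L)]
      offs <- ref$cpg_offsets[[e]]
      offs <- offs[offs < L]
      cpos <- ref$cpg_pos[[e]][ref$cpg_offsets[[e]] < L]
      m <- if (length(offs)) {
        unname(m_site[paste(ref$chrom[e], cpos)])
      } else numeric(0)
      m[is.na(m)] <- config$background_methylation
      c_idx <- which(tmpl == "C")
      noncpg_c <- setdiff(c_idx, offs + 1L)

      mat <- matrix(tmpl, nrow = n, ncol = L, byrow = TRUE)
      if (length(offs)) {
        # methylated stays C; unmethylated converted with prob `conv`
        p_c <- m + (1 - m) * (1 - conv)
        show_c <- matrix(stats::runif(n * length(offs)) <
                           rep(p_c, each = n), nrow = n)
        mat[, offs + 1L][!show_c] <- "T"
      }
      if (length(noncpg_c)) {
        stay_c <- matrix(stats::runif(n * length(noncpg_c)) < (1 - conv),
                         nrow = n)
        mat[, noncpg_c][!stay_c] <- "T"
      }
      if (err > 0) {
        hit <- which(matrix(stats::runif(n * L) < err, nrow = n))
        if (length(hit)) {
          cur <- mat[hit]
          sub <- vapply(cur, function(b) sample(setdiff(bases, b), 1L),
                        character(1))
          mat[hit] <- sub
        }
      }
      idx <- pos + seq_len(n)
      seqs[idx] <- apply(mat, 1L, paste, collapse = "")
      entry_of[idx] <- e
      pos <- pos + n
    }
    ids <- sprintf("%s_r%06d", sample_id, seq_len(total))
    names(seqs) <- ids
    reads_by_sample[[s]] <- seqs
    origin_by_sample[[s]] <- data.table::data.table(
      read_id = ids, sample = sample_id,
      entry_id = ref$entry_id[entry_of],
      chrom = ref$chrom[entry_of], strand = ref$strand[entry_of],
      start = ifelse(ref$strand[entry_of] == "top",
                     ref$frag_start[entry_of], ref$frag_end[entry_of])
    )
  }
  names(reads_by_sample) <- design$sample
  list(design = design, reads = reads_by_sample,
       origin = data.table::rbindlist(origin_by_sample), reference = ref)
}

#' Write simulated reads as one FASTQ per sample plus truth sidecars
#'
#' @param sim Output of [simulate_reads()].
#' @param truth Output of [assign_methylation()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the design table with a `fastq` column added.
#' @export
write_simulation <- function(sim, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- data.table::copy(sim$design)
  design[, "fastq" := file.path(dir, paste0(design$sample, ".fastq"))]
  for (i in seq_len(nrow(design))) {
    write_fastq(sim$reads[[design$sample[i]]], design$fastq[i])
  }
  write_tsv(design, file.path(dir, "design.tsv"))
  write_tsv(sim$origin, file.path(dir, "read_origin.tsv"))
  write_tsv(truth$gene_levels, file.path(dir, "truth_gene_levels.tsv"))
  write_tsv(truth$cpg_truth, file.path(dir, "truth_cpg_levels.tsv"))
  invisible(design)
}

#' Demonstration configuration: staged promoter effects at benchmark scale
#'
#' A compact study-shaped configuration used throughout the package's
#' examples and benchmarks: 20 genes over 100 kb, with eight genes given
#' methylation effects of magnitude `effect` in stage-specific patterns —
#' two invasive-only (one hyper, one hypo), two DCIS+invasive same-sign
#' (late stage), two DCIS-only, and two opposite-direction (significant in
#' ADH and invasive with flipped sign) — and twelve null genes. Replicate
#' noise is disabled by default because this configuration backs the
#' calibration and recovery benchmarks, whose exactness guarantees are
#' stated under within-sample binomial sampling (see the methods
#' vignette); set `replicate_kappa` to a finite value for realistic runs.
#'
#' @param seed Master seed.
#' @param effect Absolute methylation difference assigned to true-effect
#'   genes (before clipping to [0, 1]).
#' @param null_effects If `TRUE`, all deltas are zero (null calibration
#'   run).
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
progression_demo_config <- function(seed = 1L, effect = 0.5,
                                    null_effects = FALSE, ...) {
  genes <- sprintf("g%03d", 1:8)
  et <- data.table::rbindlist(list(
    data.table::data.table(gene = genes[1], group = "invasive", delta = +effect),
    data.table::data.table(gene = genes[2], group = "invasive", delta = -effect),
    data.table::data.table(gene = genes[3], group = c("DCIS", "invasive"),
                           delta = +effect),
    data.table::data.table(gene = genes[4], group = c("DCIS", "invasive"),
                           delta = -effect),
    data.table::data.table(gene = genes[5], group = "DCIS", delta = +effect),
    data.table::data.table(gene = genes[6], group = "DCIS", delta = -effect),
    data.table::data.table(gene = genes[7], group = c("ADH", "invasive"),
                           delta = c(+effect, -effect)),
    data.table::data.table(gene = genes[8], group = c("ADH", "invasive"),
                           delta = c(-effect, +effect))
  ))
  if (null_effects) et <- NULL
  sim_config(seed = seed, n_genes = 20L, genome_length = 100000L,
             effect_table = et, mean_coverage = 30,
             n_replicates_per_group = 3L, replicate_kappa = Inf, ...)
}
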