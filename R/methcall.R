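# Per-CpG methylation calling. Each uniquely aligned read reports, at every
# CpG offset of its reference entry that the read covers, either a C
# (methylated: the cytosine resisted bisulfite conversion) or a T
# (unmethylated: it converted). Other bases at that offset are sequencing
# errors and are ignored. Both strands of a CpG are palindromic and report
# the same biological site, so bottom-strand entries contribute to the
# top-strand coordinate of the CpG's C and counts are merged by default.
# The methylation level is #C / (#C + #T).

#' Pile up per-CpG methylated/unmethylated counts for one sample
#'
#' @param alignments data.table from [align_reads()] (all statuses; only
#'   `unique` rows are used).
#' @param reference The `bt_reference` the reads were aligned to.
#' @param reads Named character vector of the read sequences (names must
#'   match `alignments$read_id`), or a FASTQ path.
#' @param sample_id Sample label stored in the output.
#' @param merge_strands Merge top/bottom-strand evidence per CpG site
#'   (default) or keep a `strand` column.
#' @return data.table: chrom, pos (0-based top-strand C of the CpG),
#'   sample, count_C, count_T, level.
#' @export
pileup_cpg <- function(alignments, reference, reads, sample_id = "sample",
                       merge_strands = TRUE) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  aln <- alignments[alignments$status == "unique", ]
  empty <- data.table::data.table(
    chrom = character(), pos = integer(), sample = character(),
    count_C = integer(), count_T = integer(), level = numeric())
  if (!merge_strands) empty[, "strand" := character()]
  if (nrow(aln) == 0L) return(empty)

  bad <- setdiff(unique(aln$entry_id), reference$entry_id)
  if (length(bad)) {
    stop(sprintf("alignment refers to unknown reference entries: %s",
                 paste(utils::head(bad, 3), collapse = ", ")), call. = FALSE)
  }
  seqs <- reads[aln$read_id]
  if (anyNA(seqs)) stop("reads missing for some aligned read ids", call. = FALSE)

  e_idx <- match(aln$entry_id, reference$entry_id)
  # deduplicate identical (sequence, entry) pairs and weight by count
  dt <- data.table::data.table(seq = unname(seqs), e = e_idx)
  agg <- dt[, list(n = .N), by = c("seq", "e")]

  rows <- vector("list", nrow(agg))
  for (i in seq_len(nrow(agg))) {
    e <- agg$e[i]
    offs <- reference$cpg_offsets[[e]]
    if (!length(offs)) next
    L <- min(nchar(agg$seq[i]), reference$length[e])
    keep <- offs < L
    if (!any(keep)) next
    offs <- offs[keep]
    pos <- reference$cpg_pos[[e]][keep]
    base <- substring(agg$seq[i], offs + 1L, offs + 1L)
    counted <- base %in% c("C", "T")
    if (!any(counted)) next
    rows[[i]] <- data.table::data.table(
      chrom = reference$chrom[e], pos = pos[counted],
      strand = reference$strand[e],
      is_c = base[counted] == "C", n = agg$n[i])
  }
  long <- data.table::rbindlist(rows)
  if (nrow(long) == 0L) return(empty)

  by_cols <- if (merge_strands) c("chrom", "pos") else c("chrom", "pos", "strand")
  calls <- long[, list(count_C = sum(n[is_c]), count_T = sum(n[!is_c])),
                by = by_cols]
  calls[, "sample" := sample_id]
  calls[, "level" := calls$count_C / (calls$count_C + calls$count_T)]
  data.table::setcolorder(calls, c("chrom", "pos", "sample"))
  data.table::setorderv(calls, c("chrom", "pos"))
  calls[]
}

#' Coverage-filter CpG calls
#'
#' Keeps CpG-by-sample records whose total read depth (C + T) reaches
#' `min_reads`; the boundary is inclusive, so depth exactly `min_reads`
#' is retained. Idempotent and monotone in `min_reads`.
#'
#' @param calls data.table from [pileup_cpg()] (any extra columns pass
#'   through).
#' @param min_reads Minimum depth.
#' @export
filter_coverage <- function(calls, min_reads = 5L) {
  calls[(calls$count_C + calls$count_T) >= min_reads, ]
}

#' Detect CpG islands by windowed GC and observed/expected CpG content
#'
#' Classic windowed criteria: every `win`-bp window with GC fraction at
#' least `gc_min` and observed/expected CpG ratio at least `oe_min`
#' (obs/exp = n_CG * win / (n_C * n_G); zero denominator scores 0)
#' qualifies, and overlapping qualifying windows are merged into maximal
#' intervals. A user-supplied island BED can be used downstream instead.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param win Window size in bp.
#' @param gc_min Minimum GC fraction.
#' @param oe_min Minimum observed/expected CpG ratio.
#' @return data.table: chrom, start, end (0-based half-open).
#' @export
detect_cpg_islands <- function(genome, win = 200L, gc_min = 0.50,
                               oe_min = 0.60) {
  genome <- as_genome(genome)
  out <- lapply(names(genome), function(chrom) {
    seq <- genome[[chrom]]
    L <- nchar(seq)
    if (L < win) return(NULL)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    is_c <- chars == "C"
    is_g <- chars == "G"
    is_cg <- c(is_c[-L] & is_g[-1L], FALSE)
    cum <- function(x) c(0, cumsum(x))
    cc <- cum(is_c); cg_ <- cum(is_g); ccg <- cum(is_cg)
    starts <- 0:(L - win)                      # 0-based window starts
    nC <- cc[starts + win + 1L] - cc[starts + 1L]
    nG <- cg_[starts + win + 1L] - cg_[starts + 1L]
    # CG dinucleotides fully inside the window [s, s+win)
    nCG <- ccg[starts + win] - ccg[starts + 1L]
    gc <- (nC + nG) / win
    oe <- ifelse(nC * nG > 0, nCG * win / (nC * nG), 0)
    ok <- gc >= gc_min & oe >= oe_min
    if (!any(ok)) return(NULL)
    s <- starts[ok]
    # merge overlapping/adjacent qualifying windows
    brk <- c(TRUE, diff(s) > win)
    grp <- cumsum(brk)
    data.table::data.table(
      chrom = chrom,
      start = as.integer(tapply(s, grp, min)),
      end = as.integer(tapply(s, grp, max)) + win
    )
  })
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  }
  res[]
}

#' Annotate CpG calls with promoter, gene-body and island membership
#'
#' Promoters span `[TSS - promoter_up, TSS + promoter_down)` on plus-strand
#' genes and the mirrored `[TSS - promoter_down, TSS + promoter_up)` on
#' minus-strand genes. A CpG may receive several labels (promoter of one
#' or more genes, gene body, CpG island) simultaneously.
#'
#' @param calls data.table with chrom and pos columns.
#' @param genes data.table with gene, chrom, tss, strand (and optionally
#'   body_start/body_end; if absent, gene bodies are skipped).
#' @param islands Optional island intervals (chrom, start, end) from
#'   [detect_cpg_islands()] or a user BED.
#' @param promoter_up,promoter_down Promoter extent in bp.
#' @return `calls` with added columns `promoter` (comma-joined gene names
#'   or NA), `gene_body` (likewise) and `cpg_island` (logical).
#' @export
annotate_cpgs <- function(calls, genes, islands = NULL,
                          promoter_up = 1000L, promoter_down = 500L) {
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0L) {
    calls[, c("promoter", "gene_body", "cpg_island") :=
            list(character(), character(), logical())]
    return(calls)
  }
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("gene annotation contains unknown strand values", call. = FALSE)
  }
  cpg_gr <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(start = calls$pos + 1L, width = 1L))

  prom_start <- ifelse(genes$strand == "+",
                       genes$tss - promoter_up, genes$tss - promoter_down)
  prom_end <- ifelse(genes$strand == "+",
                     genes$tss + promoter_down, genes$tss + promoter_up)
  prom_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(prom_start, 0L) + 1L, end = prom_end))

  join_hits <- function(hits, labels, n) {
    out <- rep(NA_character_, n)
    if (length(hits)) {
      lab <- tapply(labels[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits),
                    function(x) paste(sort(unique(x)), collapse = ","))
      out[as.integer(names(lab))] <- unname(lab)
    }
    out
  }
  ph <- GenomicRanges::findOverlaps(cpg_gr, prom_gr)
  calls[, "promoter" := join_hits(ph, genes$gene, nrow(calls))]

  if (all(c("body_start", "body_end") %in% names(genes))) {
    has_body <- genes$body_end > genes$body_start
    body_gr <- GenomicRanges::GRanges(
      genes$chrom[has_body],
      IRanges::IRanges(start = genes$body_start[has_body] + 1L,
                       end = genes$body_end[has_body]))
    bh <- GenomicRanges::findOverlaps(cpg_gr, body_gr)
    calls[, "gene_body" := join_hits(bh, genes$gene[has_body], nrow(calls))]
  } else {
    calls[, "gene_body" := NA_character_]
  }

  if (!is.null(islands) && nrow(islands) > 0L) {
    isl_gr <- GenomicRanges::GRanges(
      islands$chrom, IRanges::IRanges(start = islands$start + 1L,
                                      end = islands$end))
    calls[, "cpg_island" := IRanges::overlapsAny(cpg_gr, isl_gr)]
  } else {
    calls[, "cpg_island" := FALSE]
  }
  calls[]
}
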