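# Three-letter bisulfite alignment. Reads have their residual cytosines
# collapsed to thymine and are compared, ungapped and anchored at entry
# position 0, against the C-to-T converted fragment-end reference (reads
# start at restriction cut sites, so no offset search is needed). Candidate
# entries are those within `max_conv_mismatch` in converted space; they are
# then re-scored in unconverted space with bisulfite-aware counting (a T in
# the read over a C in the reference is not a mismatch — that is exactly a
# converted unmethylated cytosine — while a C over a T does count). A read
# is kept as uniquely aligned only when the best candidate beats the
# second-best by at least `min_uniq_gap` mismatches.

BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

#' Collapse a read's cytosines to thymine
#'
#' @param seq ACGTN read sequence.
#' @return List with `converted` (sequence with every C replaced by T) and
#'   `c_positions` (0-based positions of the original cytosines).
#' @export
#' @examples
#' convert_read("ACGT")  # "ATGT", position 1
convert_read <- function(seq) {
  assert_dna(seq, "read")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  list(converted = gsub("C", "T", seq, fixed = TRUE),
       c_positions = which(chars == "C") - 1L)
}

#' Bisulfite-aware mismatch count between unconverted sequences
#'
#' Counts positions where read and reference differ, except that a read T
#' over a reference C is ignored (bisulfite conversion explains it). The
#' reverse — read C over reference T — does count, as do all positions
#' involving N. Sequences are compared over the shorter of the two
#' lengths.
#'
#' @param read_raw,entry_raw Unconverted read and reference-entry
#'   sequences.
#' @return Integer mismatch count.
#' @export
#' @examples
#' bs_mismatch_count("TTGT", "TCGT")  # 0: T over C is conversion
#' bs_mismatch_count("TCGT", "TTGT")  # 1: C over T is a real mismatch
bs_mismatch_count <- function(read_raw, entry_raw) {
  L <- min(nchar(read_raw), nchar(entry_raw))
  r <- strsplit(substr(read_raw, 1L, L), "", fixed = TRUE)[[1]]
  e <- strsplit(substr(entry_raw, 1L, L), "", fixed = TRUE)[[1]]
  sum((r != e & !(r == "T" & e == "C")) | r == "N" | e == "N")
}

default_align_params <- function() {
  list(max_conv_mismatch = 3L, max_mismatch = 3L,
       min_uniq_gap = 2L, min_anchor = 20L)
}

# Encode sequences into an n x width integer matrix (0 = padding).
encode_matrix <- function(seqs, width) {
  n <- length(seqs)
  M <- matrix(0L, n, width)
  sp <- strsplit(seqs, "", fixed = TRUE)
  for (i in seq_len(n)) {
    v <- BASE_CODE[sp[[i]]]
    v[is.na(v)] <- 5L
    L <- min(length(v), width)
    M[i, seq_len(L)] <- v[seq_len(L)]
  }
  M
}

# Indicator matrix (numeric 0/1) for one base code.
indicator <- function(M, code) {
  X <- matrix(0, nrow(M), ncol(M))
  X[M == code] <- 1
  X
}

#' Align a batch of bisulfite reads against the converted reference
#'
#' Implements the full-scan contract: every reference entry whose
#' converted-space anchored Hamming distance to the converted read is at
#' most `max_conv_mismatch` (over an overlap of at least `min_anchor`
#' bases) is a candidate; candidates are ranked by bisulfite-aware
#' mismatches in unconverted space. A read is `unique` when the best
#' candidate has at most `max_mismatch` mismatches and either no rival or
#' a second-best at least `min_uniq_gap` mismatches worse; otherwise it is
#' `ambiguous_discarded` (candidates exist) or `unmapped`. Ties for best
#' give a gap of zero and are therefore discarded.
#'
#' Internally the all-pairs mismatch counts are computed blockwise via
#' one-hot crossproducts, which is exactly equivalent to scanning every
#' entry per read.
#'
#' @param reads Named character vector of read sequences.
#' @param reference A `bt_reference` from [build_reference()].
#' @param max_conv_mismatch Candidate cap on converted-space mismatches.
#' @param max_mismatch Acceptance cap on bisulfite-aware mismatches.
#' @param min_uniq_gap Required advantage of best over second-best.
#' @param min_anchor Minimum read/entry overlap (shorter reads are
#'   unmapped).
#' @param block_size Reads per internal block (memory/speed trade-off;
#'   does not affect results).
#' @return data.table: read_id, status (unique/ambiguous_discarded/
#'   unmapped), entry_id, best_mismatches, second_best_mismatches.
#' @export
align_reads <- function(reads, reference,
                        max_conv_mismatch = 3L, max_mismatch = 3L,
                        min_uniq_gap = 2L, min_anchor = 20L,
                        block_size = 1024L) {
  if (!length(reads)) {
    return(data.table::data.table(
      read_id = character(), status = character(), entry_id = character(),
      best_mismatches = integer(), second_best_mismatches = integer()))
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  if (nrow(reference) == 0L) stop("reference is empty", call. = FALSE)

  useq <- unique(unname(reads))
  width <- max(nchar(useq), reference$length, 1L)

  E_raw <- encode_matrix(reference$raw_seq, width)
  E_conv <- encode_matrix(reference$conv_seq, width)
  len_e <- reference$length
  # one-hot reference indicators (converted space has no C)
  Y_conv <- lapply(c(1L, 3L, 4L), indicator, M = E_conv)
  Y_raw <- lapply(1:4, indicator, M = E_raw)

  n_u <- length(useq)
  res_status <- character(n_u)
  res_entry <- rep(NA_character_, n_u)
  res_best <- rep(NA_integer_, n_u)
  res_second <- rep(NA_integer_, n_u)

  len_r_all <- nchar(useq)
  short <- len_r_all < min_anchor
  res_status[short] <- "unmapped"

  todo <- which(!short)
  conv_useq <- gsub("C", "T", useq, fixed = TRUE)
  blk_starts <- if (length(todo)) seq(1L, length(todo), by = block_size) else integer(0)
  for (blk_start in blk_starts) {
    idx <- todo[blk_start:min(blk_start + block_size - 1L, length(todo))]
    B <- length(idx)
    R_raw <- encode_matrix(useq[idx], width)
    R_conv <- encode_matrix(conv_useq[idx], width)
    len_r <- len_r_all[idx]
    overlap <- outer(len_r, len_e, pmin)

    conv_match <- matrix(0, B, nrow(reference))
    for (k in seq_along(c(1L, 3L, 4L))) {
      code <- c(1L, 3L, 4L)[k]
      conv_match <- conv_match + tcrossprod(indicator(R_conv, code), Y_conv[[k]])
    }
    conv_mm <- overlap - conv_match

    bs_match <- matrix(0, B, nrow(reference))
    for (code in 1:4) {
      bs_match <- bs_match + tcrossprod(indicator(R_raw, code), Y_raw[[code]])
    }
    # read T over entry C is forgiven
    bs_match <- bs_match + tcrossprod(indicator(R_raw, 4L), Y_raw[[2L]])
    bs_mm <- overlap - bs_match

    is_cand <- conv_mm <= max_conv_mismatch & overlap >= min_anchor
    bs_mm[!is_cand] <- Inf

    best <- apply(bs_mm, 1L, min)
    for (b in seq_len(B)) {
      i <- idx[b]
      if (!is.finite(best[b])) { res_status[i] <- "unmapped"; next }
      row <- bs_mm[b, ]
      hits <- which(row == best[b])
      second <- if (length(hits) > 1L) {
        best[b]
      } else {
        r2 <- row[-hits]
        if (all(!is.finite(r2))) NA_real_ else min(r2)
      }
      res_best[i] <- as.integer(best[b])
      res_second[i] <- if (is.na(second) || !is.finite(second)) {
        NA_integer_
      } else as.integer(second)
      ok_cap <- best[b] <= max_mismatch
      ok_gap <- is.na(res_second[i]) || (res_second[i] - res_best[i]) >= min_uniq_gap
      if (ok_cap && ok_gap) {
        res_status[i] <- "unique"
        res_entry[i] <- reference$entry_id[hits[1L]]
      } else {
        res_status[i] <- "ambiguous_discarded"
      }
    }
  }

  map <- match(unname(reads), useq)
  data.table::data.table(
    read_id = names(reads),
    status = res_status[map],
    entry_id = res_entry[map],
    best_mismatches = res_best[map],
    second_best_mismatches = res_second[map]
  )
}

#' Align a single read
#'
#' @inheritParams align_reads
#' @param read One read sequence.
#' @return A one-row list: read_id, status, entry_id (or `NA`),
#'   best_mismatches, second_best_mismatches.
#' @export
align_read <- function(read, reference, max_conv_mismatch = 3L,
                       max_mismatch = 3L, min_uniq_gap = 2L,
                       min_anchor = 20L) {
  res <- align_reads(stats::setNames(read, "read1"), reference,
                     max_conv_mismatch = max_conv_mismatch,
                     max_mismatch = max_mismatch,
                     min_uniq_gap = min_uniq_gap, min_anchor = min_anchor)
  as.list(res[1L, ])
}

#' Align one sample's FASTQ and summarise
#'
#' @param reads Path to a FASTQ file, or a named character vector of read
#'   sequences.
#' @param reference A `bt_reference`.
#' @param ... Passed to [align_reads()].
#' @return List with `alignments` (data.table) and `summary` (named
#'   counts: n_reads, unique, ambiguous_discarded, unmapped).
#' @export
align_sample <- function(reads, reference, ...) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  aln <- align_reads(reads, reference, ...)
  smry <- c(
    n_reads = nrow(aln),
    unique = sum(aln$status == "unique"),
    ambiguous_discarded = sum(aln$status == "ambiguous_discarded"),
    unmapped = sum(aln$status == "unmapped")
  )
  list(alignments = aln, summary = smry)
}
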