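# In-silico MspI + TaqI double digestion and construction of the converted
# fragment-end reference used by the bisulfite aligner. RRBS enriches for
# CpG-dense regions because MspI (C^CGG) and TaqI (T^CGA) sites concentrate
# there; sequencing reads start at the cut sites, so only the first
# `end_len` bases of each strand of each size-selected fragment are ever
# observed, and those ends are what the reference holds.

ENZYME_MOTIFS <- c(MspI = "CCGG", TaqI = "TCGA")

#' Restriction cut positions for MspI or TaqI
#'
#' MspI cuts C^CGG and TaqI cuts T^CGA, i.e. one base into the recognition
#' site. Positions are reported as 0-based boundaries between bases, so a
#' cut at position `p` splits the sequence into `[0, p)` and `[p, len)`.
#' `N` bases never form part of a site.
#'
#' @param seq Uppercase ACGTN sequence (single string).
#' @param enzyme `"MspI"` or `"TaqI"`.
#' @return Sorted integer vector of 0-based cut boundaries.
#' @export
#' @examples
#' cut_sites("AACCGGTT", "MspI")  # 3
#' cut_sites("TTTCGATT", "TaqI")  # 4
cut_sites <- function(seq, enzyme = c("MspI", "TaqI")) {
  enzyme <- match.arg(enzyme)
  assert_dna(seq, "digestion input")
  if (nchar(seq) < 4L) return(integer(0))
  m <- Biostrings::matchPattern(ENZYME_MOTIFS[[enzyme]],
                                Biostrings::DNAString(seq), fixed = TRUE)
  # 1-based motif start == 0-based boundary one base into the site
  sort(BiocGenerics::start(m))
}

#' Predict size-selected MspI-TaqI double-digest fragments
#'
#' The double digest is modelled as the union of both enzymes' cut sites
#' (digestion order does not change the final fragment set). Fragments
#' partition each chromosome; only those whose length falls in
#' `[min_len, max_len]` are returned, mirroring gel size selection.
#' Chromosome-terminal fragments are retained and labelled
#' `"chromosome-end"` on their open side.
#'
#' @param genome Named character vector of chromosome sequences (or a
#'   single unnamed sequence).
#' @param min_len,max_len Inclusive fragment length window in bp.
#' @return data.table with columns chrom, start, end (0-based half-open),
#'   length, left_enzyme, right_enzyme.
#' @export
predict_fragments <- function(genome, min_len = 40L, max_len = 350L) {
  stopifnot(min_len <= max_len, min_len >= 1L)
  genome <- as_genome(genome)
  out <- lapply(names(genome), function(chrom) {
    seq <- genome[[chrom]]
    len <- nchar(seq)
    if (len == 0L) return(NULL)
    cuts_m <- cut_sites(seq, "MspI")
    cuts_t <- cut_sites(seq, "TaqI")
    enz <- c(rep("MspI", length(cuts_m)), rep("TaqI", length(cuts_t)))
    ord <- order(c(cuts_m, cuts_t))
    cuts <- c(cuts_m, cuts_t)[ord]
    enz <- enz[ord]
    keep <- cuts > 0L & cuts < len
    cuts <- cuts[keep]; enz <- enz[keep]
    bounds <- c(0L, cuts, len)
    labels <- c("chromosome-end", enz, "chromosome-end")
    data.table::data.table(
      chrom = chrom,
      start = bounds[-length(bounds)],
      end = bounds[-1L],
      left_enzyme = labels[-length(labels)],
      right_enzyme = labels[-1L]
    )
  })
  dt <- data.table::rbindlist(out)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), length = integer(),
                                  left_enzyme = character(),
                                  right_enzyme = character()))
  }
  dt[, "length" := dt$end - dt$start]
  dt[dt$length >= min_len & dt$length <= max_len,
     c("chrom", "start", "end", "length", "left_enzyme", "right_enzyme"),
     with = FALSE]
}

#' Build the C-to-T converted fragment-end reference
#'
#' For each predicted fragment two entries are created: the first
#' `end_len` bases of the top strand (the 5' end read by a directional
#' protocol) and the reverse complement of the last `end_len` bases (the
#' bottom-strand 5' end). Each entry stores its unconverted sequence, the
#' fully C-to-T converted sequence the aligner matches against, and, for
#' every cytosine in CpG context, the entry-local offset together with the
#' top-strand coordinate of the CpG's C (bottom-strand cytosines report the
#' palindromic top-strand position, so both strands pile up on one site).
#' CpG context is determined from the genome, not just the 50-bp window, so
#' a terminal C followed by a genomic G still counts; any C adjacent to an
#' N is not treated as CpG.
#'
#' @param fragments data.table from [predict_fragments()].
#' @param genome Named character vector of chromosome sequences.
#' @param end_len Length of each fragment end to keep (bp).
#' @return data.table of reference entries with columns entry_id, chrom,
#'   frag_start, frag_end, strand ("top"/"bottom"), raw_seq, conv_seq,
#'   length, cpg_offsets (list, 0-based entry-local), cpg_pos (list,
#'   top-strand C coordinates).
#' @export
build_reference <- function(fragments, genome, end_len = 50L) {
  genome <- as_genome(genome)
  fragments <- data.table::as.data.table(fragments)
  if (nrow(fragments) == 0L) {
    return(empty_reference())
  }
  # 0-based start positions of CpG dinucleotides, per chromosome
  cpg_starts <- lapply(genome, function(seq) {
    if (nchar(seq) < 2L) return(logical(0))
    m <- Biostrings::matchPattern("CG", Biostrings::DNAString(seq), fixed = TRUE)
    flags <- logical(nchar(seq))
    flags[BiocGenerics::start(m)] <- TRUE  # index i <-> 0-based pos i-1
    flags
  })

  n <- nrow(fragments)
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    chrom <- fragments$chrom[i]
    fs <- fragments$start[i]; fe <- fragments$end[i]
    flen <- fe - fs
    k <- min(end_len, flen)
    seq <- genome[[chrom]]
    is_cpg <- cpg_starts[[chrom]]

    # top-strand 5' end: bases at 0-based coords fs .. fs+k-1
    raw_top <- substr(seq, fs + 1L, fs + k)
    coords_top <- fs + 0:(k - 1L)
    c_off <- which(strsplit(raw_top, "", fixed = TRUE)[[1]] == "C") - 1L
    pos_top <- coords_top[c_off + 1L]
    keep <- pos_top + 1L <= length(is_cpg) & is_cpg[pos_top + 1L]
    rows[[2L * i - 1L]] <- list(
      entry_id = sprintf("%s:%d-%d:top", chrom, fs, fe),
      chrom = chrom, frag_start = fs, frag_end = fe, strand = "top",
      raw_seq = raw_top, conv_seq = gsub("C", "T", raw_top, fixed = TRUE),
      length = k,
      cpg_offsets = list(c_off[keep]),
      cpg_pos = list(pos_top[keep])
    )

    # bottom-strand 5' end: revcomp of last k bases (coords fe-1 down to fe-k)
    raw_bot <- revcomp(substr(seq, fe - k + 1L, fe))
    coords_bot <- fe - 1L - 0:(k - 1L)
    c_off_b <- which(strsplit(raw_bot, "", fixed = TRUE)[[1]] == "C") - 1L
    g <- coords_bot[c_off_b + 1L]
    # bottom-strand C at top coord g is CpG iff top strand has CG at (g-1, g)
    keep_b <- g >= 1L
    keep_b[keep_b] <- is_cpg[g[keep_b]]  # is_cpg[g] <-> 0-based pos g-1
    rows[[2L * i]] <- list(
      entry_id = sprintf("%s:%d-%d:bottom", chrom, fs, fe),
      chrom = chrom, frag_start = fs, frag_end = fe, strand = "bottom",
      raw_seq = raw_bot, conv_seq = gsub("C", "T", raw_bot, fixed = TRUE),
      length = k,
      cpg_offsets = list(c_off_b[keep_b]),
      cpg_pos = list(g[keep_b] - 1L)
    )
  }
  ref <- data.table::rbindlist(rows)
  data.table::setattr(ref, "class", c("bt_reference", class(ref)))
  ref[]
}

empty_reference <- function() {
  ref <- data.table::data.table(
    entry_id = character(), chrom = character(), frag_start = integer(),
    frag_end = integer(), strand = character(), raw_seq = character(),
    conv_seq = character(), length = integer(),
    cpg_offsets = list(), cpg_pos = list()
  )
  data.table::setattr(ref, "class", c("bt_reference", class(ref)))
  ref
}

#' Write a fragment-end reference to FASTA plus TSV sidecar
#'
#' The FASTA holds the converted sequences under the entry ids; the sidecar
#' TSV carries the unconverted sequences, fragment coordinates and CpG
#' offsets/positions (comma-separated), enough to reconstruct the
#' reference with [read_reference()].
#'
#' @param reference From [build_reference()].
#' @param fasta_path,tsv_path Output paths.
#' @export
write_reference <- function(reference, fasta_path, tsv_path) {
  seqs <- reference$conv_seq
  names(seqs) <- reference$entry_id
  write_fasta(seqs, fasta_path)
  flat <- data.table::data.table(
    entry_id = reference$entry_id, chrom = reference$chrom,
    frag_start = reference$frag_start, frag_end = reference$frag_end,
    strand = reference$strand, raw_seq = reference$raw_seq,
    conv_seq = reference$conv_seq, length = reference$length,
    cpg_offsets = vapply(reference$cpg_offsets, paste, character(1), collapse = ","),
    cpg_pos = vapply(reference$cpg_pos, paste, character(1), collapse = ",")
  )
  write_tsv(flat, tsv_path)
  invisible(tsv_path)
}

#' Read a fragment-end reference from its TSV sidecar
#' @param tsv_path Path written by [write_reference()].
#' @export
read_reference <- function(tsv_path) {
  flat <- read_tsv(tsv_path, required = c("entry_id", "chrom", "frag_start",
                                          "frag_end", "strand", "raw_seq",
                                          "conv_seq", "length"))
  parse_ints <- function(s) {
    lapply(as.character(s), function(x) {
      if (is.na(x) || !nzchar(x)) integer(0) else as.integer(strsplit(x, ",")[[1]])
    })
  }
  flat[, "cpg_offsets" := parse_ints(flat$cpg_offsets)]
  flat[, "cpg_pos" := parse_ints(flat$cpg_pos)]
  data.table::setattr(flat, "class", c("bt_reference", class(flat)))
  flat[]
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(toupper(as.character(genome)),
                              sub("\\s.*$", "", names(genome)))
  }
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  stopifnot(is.character(genome))
  if (is.null(names(genome))) {
    names(genome) <- paste0("chr", seq_along(genome))
  }
  genome
}
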