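# Shared readers/writers for the plain-text formats the workflow touches:
# FASTA, FASTQ (Phred+33), BED6 (0-based half-open), TSV with header, YAML
# config and JSON summaries. Coordinates are 0-based half-open everywhere in
# memory; BED on disk matches that convention directly.

#' Read a genome FASTA into a named character vector
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return Named uppercase character vector, one element per sequence; names
#'   are the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return Named character vector of read sequences (names = read ids).
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      stop(sprintf("malformed FASTQ '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads to FASTQ with constant Phred+33 qualities
#'
#' @param reads Named character vector (names become read ids).
#' @param path Output path.
#' @param qual_char Single quality character applied to every base.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  x <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(vapply(
    nchar(reads), function(n) strrep(qual_char, n), character(1)
  ))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a BED6 file of intervals
#'
#' @param path Path to a BED file (0-based half-open on disk).
#' @return data.table with columns chrom, start, end, name, score, strand
#'   (0-based half-open starts/ends, matching the in-memory convention).
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("BED file needs at least 3 columns", call. = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, seq_len(min(6L, ncol(dt))), cols[seq_len(min(6L, ncol(dt)))])
  if (!"name" %in% names(dt)) dt[, "name" := "."]
  if (!"score" %in% names(dt)) dt[, "score" := 0]
  if (!"strand" %in% names(dt)) dt[, "strand" := "."]
  dt[, c("chrom", "start", "end", "name", "score", "strand"), with = FALSE]
}

#' Write intervals to BED6
#'
#' @param dt data.table/data.frame with chrom, start, end and optionally
#'   name, score, strand (0-based half-open).
#' @param path Output path.
#' @export
write_bed <- function(dt, path) {
  dt <- data.table::as.data.table(dt)
  out <- data.table::data.table(
    chrom = dt$chrom,
    start = as.integer(dt$start),
    end = as.integer(dt$end),
    name = if ("name" %in% names(dt)) dt$name else ".",
    score = if ("score" %in% names(dt)) dt$score else 0,
    strand = if ("strand" %in% names(dt)) dt$strand else "."
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a TSV with a header row, enforcing required columns
#'
#' @param path Path to the TSV.
#' @param required Character vector of column names that must be present.
#' @return data.table.
#' @export
read_tsv <- function(path, required = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(dt))
    if (length(missing)) {
      stop(sprintf("TSV '%s' is missing required column(s): %s",
                   path, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  dt
}

#' Write a table to TSV with header
#' @param dt Table to write.
#' @param path Output path.
#' @export
write_tsv <- function(dt, path) {
  data.table::fwrite(data.table::as.data.table(dt), path, sep = "\t")
  invisible(path)
}

#' Read a YAML run configuration
#' @param path Path to YAML file.
#' @export
read_yaml_config <- function(path) yaml::read_yaml(path)

#' Write a JSON summary
#' @param x List to serialise.
#' @param path Output path.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
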