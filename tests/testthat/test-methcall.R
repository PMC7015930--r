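# Methylation calling: pileup, coverage filter, islands, annotation.

# genome with one CpG inside a single fragment; both strands observe it
pileup_fixture <- function() {
  g <- c(chr1 = "ATTACGATTAGGATTAGGATTAGGATT")  # CpG at pos 4
  ref <- toy_reference(g)
  list(genome = g, ref = ref)
}

test_that("pileup counts C and T reads and ignores other bases", {
  fx <- pileup_fixture()
  top <- fx$ref[fx$ref$strand == "top", ]
  expect_equal(top$cpg_offsets[[1]], 4L)
  raw <- top$raw_seq
  # 3 methylated (C), 2 converted (T), 1 error (G) at the CpG
  mk <- function(base) {
    s <- strsplit(raw, "")[[1]]; s[5] <- base; paste(s, collapse = "")
  }
  reads <- c(r1 = mk("C"), r2 = mk("C"), r3 = mk("C"),
             r4 = mk("T"), r5 = mk("T"), r6 = mk("G"))
  aln <- data.table::data.table(
    read_id = names(reads), status = "unique", entry_id = top$entry_id,
    best_mismatches = 0L, second_best_mismatches = NA_integer_)
  calls <- pileup_cpg(aln, fx$ref, reads, sample_id = "s1")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 4L)
  expect_equal(calls$count_C, 3L)
  expect_equal(calls$count_T, 2L)
  expect_equal(calls$level, 0.6)
})

test_that("both strands merge onto the top-strand CpG coordinate", {
  fx <- pileup_fixture()
  top <- fx$ref[fx$ref$strand == "top", ]
  bot <- fx$ref[fx$ref$strand == "bottom", ]
  expect_equal(bot$cpg_pos[[1]], top$cpg_pos[[1]])
  reads <- c(r1 = top$raw_seq, r2 = bot$raw_seq)  # both methylated
  aln <- data.table::data.table(
    read_id = names(reads), status = "unique",
    entry_id = c(top$entry_id, bot$entry_id),
    best_mismatches = 0L, second_best_mismatches = NA_integer_)
  merged <- pileup_cpg(aln, fx$ref, reads, sample_id = "s1")
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$count_C, 2L)
  split <- pileup_cpg(aln, fx$ref, reads, sample_id = "s1",
                      merge_strands = FALSE)
  expect_equal(nrow(split), 2L)
  expect_equal(sort(split$strand), c("bottom", "top"))
})

test_that("all-T pileup reports level zero and unknown entries error", {
  fx <- pileup_fixture()
  top <- fx$ref[fx$ref$strand == "top", ]
  raw <- strsplit(top$raw_seq, "")[[1]]; raw[5] <- "T"
  reads <- stats::setNames(rep(paste(raw, collapse = ""), 7),
                           paste0("r", 1:7))
  aln <- data.table::data.table(
    read_id = names(reads), status = "unique", entry_id = top$entry_id,
    best_mismatches = 0L, second_best_mismatches = NA_integer_)
  calls <- pileup_cpg(aln, fx$ref, reads, "s1")
  expect_equal(calls$level, 0)
  expect_equal(calls$count_T, 7L)
  aln$entry_id <- "nonexistent"
  expect_error(pileup_cpg(aln, fx$ref, reads, "s1"), "unknown reference")
})

test_that("coverage filter is inclusive at the boundary, idempotent and monotone", {
  calls <- data.table::data.table(
    chrom = "chr1", pos = 1:4, sample = "s1",
    count_C = c(2L, 3L, 5L, 0L), count_T = c(2L, 2L, 3L, 10L),
    level = c(0.5, 0.6, 0.625, 0))
  f5 <- filter_coverage(calls, 5)
  expect_equal(f5$pos, c(2L, 3L, 4L))   # coverage 4 removed, 5 retained
  expect_equal(filter_coverage(f5, 5), f5)
  f8 <- filter_coverage(calls, 8)
  expect_true(all(f8$pos %in% f5$pos))
  expect_equal(nrow(filter_coverage(calls[0, ], 5)), 0L)
})

test_that("island detection applies GC and observed/expected thresholds and merges", {
  at <- strrep("AT", 300)
  expect_equal(nrow(detect_cpg_islands(c(chr1 = at))), 0L)
  cg <- strrep("CG", 100)  # 200 bp, GC = 1, obs/exp ~ 2
  isl <- detect_cpg_islands(c(chr1 = cg))
  expect_equal(isl$start, 0L)
  expect_equal(isl$end, 200L)
  # two qualifying stretches joined by qualifying overlap merge into one
  joined <- paste0(strrep("CG", 150), strrep("AT", 400), strrep("CG", 150))
  isl2 <- detect_cpg_islands(c(chr1 = joined))
  expect_equal(nrow(isl2), 2L)
  expect_true(all(isl2$end - isl2$start >= 200L))
})

test_that("promoter intervals follow strand orientation", {
  calls <- data.table::data.table(
    chrom = "chr1", pos = c(4200L, 3900L, 4400L, 5800L, 9000L),
    sample = "s1", count_C = 5L, count_T = 5L, level = 0.5)
  genes <- data.table::data.table(
    gene = c("plus", "minus"), chrom = "chr1", tss = c(5000L, 5000L),
    strand = c("+", "-"),
    body_start = c(5000L, 3000L), body_end = c(7000L, 5000L))
  ann <- annotate_cpgs(calls, genes)
  # plus promoter [4000, 5500); minus promoter [4500, 6000)
  expect_equal(ann$promoter[ann$pos == 4200], "plus")
  expect_true(is.na(ann$promoter[ann$pos == 3900]))
  expect_equal(ann$promoter[ann$pos == 4400], "plus")
  expect_equal(ann$promoter[ann$pos == 5800], "minus")
  expect_true(is.na(ann$promoter[ann$pos == 9000]))
  expect_equal(ann$gene_body[ann$pos == 5800], "plus")
  expect_equal(ann$gene_body[ann$pos == 4400], "minus")
  bad <- data.table::copy(genes); bad$strand[1] <- "."
  expect_error(annotate_cpgs(calls, bad), "strand")
})

test_that("island membership and multi-promoter labels are annotated", {
  calls <- data.table::data.table(
    chrom = "chr1", pos = c(100L, 600L), sample = "s1",
    count_C = 5L, count_T = 0L, level = 1)
  genes <- data.table::data.table(
    gene = c("gA", "gB"), chrom = "chr1", tss = c(500L, 900L),
    strand = c("+", "-"))
  islands <- data.table::data.table(chrom = "chr1", start = 0L, end = 200L)
  ann <- annotate_cpgs(calls, genes, islands)
  expect_true(ann$cpg_island[ann$pos == 100])
  expect_false(ann$cpg_island[ann$pos == 600])
  # pos 600: inside gA promoter [-500,+1000) = [0,1500)? no: [tss-1000, tss+500)
  # gA plus: [-500, 1000); gB minus: [400, 1900) -> pos 600 in both
  expect_equal(ann$promoter[ann$pos == 600], "gA,gB")
})

test_that("methylation estimates converge to simulated truth with depth", {
  b <- tiny_sim(seed = 55, n_genes = 2, genome_length = 10000,
                n_replicates = 1, coverage = 50,
                sequencing_error_rate = 0, bisulfite_conversion_rate = 1,
                replicate_kappa = Inf, baseline_methylation = 0.35)
  ref <- b$sim$reference
  reads <- b$sim$reads[[1]]
  aln <- align_reads(reads, ref)
  calls <- filter_coverage(pileup_cpg(aln, ref, reads, "s1"), 30)
  m <- merge(calls, b$tr$cpg_truth, by = c("chrom", "pos"))
  expect_gt(nrow(m), 50)
  # average absolute deviation shrinks with depth ~ sqrt(p(1-p)/n)
  expect_lt(mean(abs(m$level - m$normal)), 0.08)
  expect_lt(abs(mean(m$level - m$normal)), 0.02)
})
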