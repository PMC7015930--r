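# Synthetic genome, methylation truth and read generator.

test_that("config validation rejects bad probabilities, groups and sizing", {
  expect_error(sim_config(bisulfite_conversion_rate = 1.2), "probabilities")
  expect_error(sim_config(groups = c("ADH", "normal")), "reference group")
  expect_error(sim_config(n_genes = 50, genome_length = 20000), "too short")
  expect_error(sim_config(effect_table = data.frame(
    gene = "g001", group = "normal", delta = 0.3)), "reference group")
  expect_error(sim_config(effect_table = data.frame(
    gene = "g001", group = "invasive", delta = 1.5)), "-1, 1")
})

test_that("a zero-gene config yields a genome with empty annotation", {
  cfg <- sim_config(seed = 1, n_genes = 0, genome_length = 5000)
  sg <- generate_genome(cfg)
  expect_equal(nrow(sg$genes), 0L)
  expect_equal(sum(nchar(sg$genome)), 5000L)
})

test_that("the same seed reproduces genome, annotation and FASTQ bytes", {
  run <- function() {
    b <- tiny_sim(seed = 77, n_genes = 2, genome_length = 8000,
                  n_replicates = 1, coverage = 4)
    d <- tempfile(); write_simulation(b$sim, b$tr, d)
    list(genome = b$sg$genome, genes = b$sg$genes,
         fq = lapply(list.files(d, pattern = "fastq$", full.names = TRUE),
                     readLines))
  }
  a <- run(); b <- run()
  expect_identical(a$genome, b$genome)
  expect_identical(a$genes, b$genes)
  expect_identical(a$fq, b$fq)
})

test_that("methylation truth follows baseline + delta with clipping", {
  cfg <- sim_config(seed = 2, n_genes = 3, genome_length = 10000,
                    baseline_methylation = 0.8,
                    effect_table = data.frame(
                      gene = c("g001", "g002", "g003"),
                      group = c("invasive", "invasive", "DCIS"),
                      delta = c(-0.65, +0.5, 0)))
  sg <- generate_genome(cfg)
  tr <- assign_methylation(cfg, sg)
  gl <- tr$gene_levels
  lvl <- function(g, grp) gl$level[gl$gene == g & gl$group == grp]
  expect_equal(lvl("g001", "normal"), 0.8)
  expect_equal(lvl("g001", "invasive"), 0.15)
  expect_equal(lvl("g002", "invasive"), 1.0)  # 0.8 + 0.5 clipped
  # zero delta everywhere else: truth equals baseline
  expect_true(all(gl$level[gl$group == "ADH"] == 0.8))
  expect_equal(gl$diffmeth_truth[gl$gene == "g001" & gl$group == "invasive"],
               -0.65)
  expect_error(assign_methylation(
    sim_config(seed = 2, n_genes = 3, genome_length = 10000,
               effect_table = data.frame(gene = "g999", group = "DCIS",
                                         delta = 0.1)), sg),
    "unknown gene")
})

test_that("per-CpG truth is promoter level inside promoters, background outside", {
  cfg <- sim_config(seed = 3, n_genes = 2, genome_length = 8000,
                    baseline_methylation = 0.4, background_methylation = 0.9)
  sg <- generate_genome(cfg)
  tr <- assign_methylation(cfg, sg)
  ct <- tr$cpg_truth
  expect_true(all(ct$normal[!is.na(ct$gene)] == 0.4))
  expect_true(all(ct$normal[is.na(ct$gene)] == 0.9))
})

test_that("forced methylation states produce deterministic read bases", {
  base_cfg <- function(m) sim_config(
    seed = 4, n_genes = 1, genome_length = 4000,
    baseline_methylation = m, background_methylation = m,
    n_replicates_per_group = 1, groups = c("normal"),
    mean_coverage = 8, sequencing_error_rate = 0,
    bisulfite_conversion_rate = 1, replicate_kappa = Inf)
  check_cpg_bases <- function(m, expected) {
    cfg <- base_cfg(m)
    sg <- generate_genome(cfg)
    tr <- assign_methylation(cfg, sg)
    sim <- simulate_reads(cfg, sg, tr)
    ref <- sim$reference
    reads <- sim$reads[[1]]
    org <- sim$origin
    seen <- character(0)
    for (i in seq_len(min(nrow(org), 500))) {
      e <- match(org$entry_id[i], ref$entry_id)
      offs <- ref$cpg_offsets[[e]]
      offs <- offs[offs < nchar(reads[org$read_id[i]])]
      if (length(offs)) {
        seen <- c(seen, substring(reads[org$read_id[i]], offs + 1, offs + 1))
      }
    }
    expect_true(length(seen) > 50)
    expect_true(all(seen == expected))
  }
  check_cpg_bases(1, "C")  # fully methylated: every CpG read reports C
  check_cpg_bases(0, "T")  # unmethylated, full conversion: always T
})

test_that("non-CpG cytosines are fully converted when conversion rate is 1", {
  cfg <- sim_config(seed = 5, n_genes = 1, genome_length = 4000,
                    baseline_methylation = 1, background_methylation = 1,
                    n_replicates_per_group = 1, groups = c("normal"),
                    mean_coverage = 6, sequencing_error_rate = 0,
                    bisulfite_conversion_rate = 1, replicate_kappa = Inf)
  sg <- generate_genome(cfg)
  tr <- assign_methylation(cfg, sg)
  sim <- simulate_reads(cfg, sg, tr)
  ref <- sim$reference
  reads <- sim$reads[[1]]
  org <- sim$origin
  for (i in seq_len(min(nrow(org), 200))) {
    e <- match(org$entry_id[i], ref$entry_id)
    rd <- reads[org$read_id[i]]
    L <- nchar(rd)
    tmpl <- strsplit(substr(ref$raw_seq[e], 1, L), "")[[1]]
    got <- strsplit(rd, "")[[1]]
    noncpg_c <- setdiff(which(tmpl == "C") - 1L, ref$cpg_offsets[[e]])
    noncpg_c <- noncpg_c[noncpg_c < L]
    if (length(noncpg_c)) expect_true(all(got[noncpg_c + 1L] == "T"))
    # and non-C template bases are untouched at error rate 0
    expect_equal(got[tmpl != "C"], tmpl[tmpl != "C"])
  }
})

test_that("observed C fraction at a CpG converges to its truth (marginal calibration)", {
  cfg <- sim_config(seed = 6, n_genes = 1, genome_length = 4000,
                    baseline_methylation = 0.6, background_methylation = 0.6,
                    n_replicates_per_group = 1, groups = c("normal"),
                    mean_coverage = 60, sequencing_error_rate = 0,
                    bisulfite_conversion_rate = 1, replicate_kappa = Inf)
  sg <- generate_genome(cfg)
  tr <- assign_methylation(cfg, sg)
  sim <- simulate_reads(cfg, sg, tr)
  ref <- sim$reference
  reads <- sim$reads[[1]]
  org <- sim$origin
  # pool >= 1000 CpG observations across entries
  obs <- character(0)
  for (i in seq_len(nrow(org))) {
    e <- match(org$entry_id[i], ref$entry_id)
    offs <- ref$cpg_offsets[[e]]
    offs <- offs[offs < nchar(reads[org$read_id[i]])]
    if (length(offs)) {
      obs <- c(obs, substring(reads[org$read_id[i]], offs + 1, offs + 1))
    }
    if (length(obs) >= 1000) break
  }
  expect_gte(length(obs), 1000)
  expect_lt(abs(mean(obs == "C") - 0.6), 0.05)
})

test_that("most promoters are covered by in-range digest fragments", {
  cfg <- sim_config(seed = 7, n_genes = 20, genome_length = 100000)
  sg <- generate_genome(cfg)
  frags <- predict_fragments(sg$genome, 40, 350)
  covered <- vapply(seq_len(nrow(sg$genes)), function(i) {
    any(frags$chrom == sg$genes$chrom[i] &
          frags$end > sg$genes$promoter_start[i] &
          frags$start < sg$genes$promoter_end[i])
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})
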