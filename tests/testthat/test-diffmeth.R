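# Fisher exact test and differential methylation.

test_that("fisher_exact_2x2 reproduces known values and input checks", {
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5))), 1.0)
  # frozen from the enumeration oracle (and stats::fisher.test)
  expect_equal(fisher_exact_2x2(rbind(c(10, 0), c(0, 10))),
               1.082509e-05, tolerance = 1e-6)
  expect_equal(fisher_exact_2x2(rbind(c(9, 1), c(1, 9))),
               oracle_fisher(9, 1, 1, 9), tolerance = 1e-12)
  expect_error(fisher_exact_2x2(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(fisher_exact_2x2(rbind(c(1.5, 2), c(1, 2))), "integers")
})

test_that("fisher_exact_2x2 agrees with stats::fisher.test on random tables", {
  set.seed(99)
  for (rep in 1:50) {
    tab <- matrix(rpois(4, 8) + c(1, 0, 0, 1), 2)
    expect_equal(fisher_exact_2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
})

make_calls <- function(counts) {
  # counts: list(sample = list(group, C = vector, T = vector)) over shared positions
  data.table::rbindlist(lapply(names(counts), function(s) {
    x <- counts[[s]]
    data.table::data.table(chrom = "chr1", pos = seq_along(x$C) * 10L,
                           sample = s, count_C = x$C, count_T = x$T,
                           level = x$C / (x$C + x$T))
  }))
}

test_that("identical pooled count profiles give p = 1 at every CpG", {
  calls <- make_calls(list(
    n1 = list(C = c(5L, 8L), T = c(5L, 2L)),
    t1 = list(C = c(5L, 8L), T = c(5L, 2L))))
  design <- data.table::data.table(sample = c("n1", "t1"),
                                   group = c("normal", "DCIS"))
  res <- cpg_tests(calls, design, stage = "DCIS")
  expect_equal(res$p_value, c(1, 1))
  expect_equal(res$diffmeth, c(0, 0))
})

test_that("group pooling, skip reasons and design validation behave", {
  calls <- make_calls(list(
    n1 = list(C = c(2L, 10L), T = c(1L, 0L)),
    n2 = list(C = c(2L, 10L), T = c(1L, 0L)),
    t1 = list(C = c(0L, 1L), T = c(3L, 9L)),
    t2 = list(C = c(1L, 1L), T = c(2L, 9L))))
  design <- data.table::data.table(sample = c("n1", "n2", "t1", "t2"),
                                   group = c("normal", "normal",
                                             "invasive", "invasive"))
  res <- cpg_tests(calls, design, stage = "invasive")
  # pooled tables: pos10 [1,5;4,2] -> tested; counts pooled across replicates
  expect_equal(res$C_normal, c(4L, 20L))
  expect_equal(res$C_stage, c(1L, 2L))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  # a CpG covered in only one group is skipped with a reason
  calls2 <- rbind(calls, data.table::data.table(
    chrom = "chr1", pos = 99L, sample = c("n1", "n2"),
    count_C = 5L, count_T = 5L, level = 0.5))
  res2 <- cpg_tests(calls2, design, stage = "invasive")
  sk <- attr(res2, "skipped")
  expect_equal(sk$pos, 99L)
  expect_equal(sk$reason, "missing group coverage")
  expect_error(cpg_tests(calls, design, stage = "ADH"), "missing from design")
})

test_that("swapping group labels negates diffmeth and preserves p", {
  set.seed(7)
  calls <- make_calls(list(
    n1 = list(C = rpois(6, 10) + 1L, T = rpois(6, 10) + 1L),
    t1 = list(C = rpois(6, 4) + 1L, T = rpois(6, 14) + 1L)))
  design <- data.table::data.table(sample = c("n1", "t1"),
                                   group = c("normal", "DCIS"))
  fwd <- cpg_tests(calls, design, stage = "DCIS")
  design_swapped <- data.table::data.table(sample = c("n1", "t1"),
                                           group = c("DCIS", "normal"))
  rev <- cpg_tests(calls, design_swapped, stage = "DCIS")
  expect_equal(fwd$diffmeth, -rev$diffmeth)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
})

test_that("the Fisher path detects large shifts at pooled depth 30 per group", {
  set.seed(123)
  n_cpg <- 500
  calls <- data.table::rbindlist(lapply(c(normal = 0.2, DCIS = 0.8), function(p) {
    C <- rbinom(n_cpg, 30, p)
    data.table::data.table(chrom = "chr1", pos = seq_len(n_cpg) * 10L,
                           sample = paste0("s", p), count_C = C,
                           count_T = 30L - C, level = C / 30)
  }))
  design <- data.table::data.table(sample = unique(calls$sample),
                                   group = c("normal", "DCIS"))
  res <- cpg_tests(calls, design, stage = "DCIS")
  expect_equal(nrow(res), n_cpg)
  expect_gte(mean(res$p_value < 0.05), 0.95)
})

test_that("the Welch t-test path works on per-sample levels", {
  calls <- make_calls(list(
    n1 = list(C = c(2L, 3L), T = c(8L, 7L)),
    n2 = list(C = c(3L, 2L), T = c(7L, 8L)),
    t1 = list(C = c(8L, 9L), T = c(2L, 1L)),
    t2 = list(C = c(9L, 8L), T = c(1L, 2L))))
  design <- data.table::data.table(sample = c("n1", "n2", "t1", "t2"),
                                   group = c("normal", "normal",
                                             "invasive", "invasive"))
  res <- cpg_tests(calls, design, stage = "invasive", method = "t_test")
  expect_equal(res$method, rep("t_test", 2))
  expect_true(all(res$p_value < 0.05))
  # single replicate per group: all skipped
  res1 <- cpg_tests(calls[calls$sample %in% c("n1", "t1"), ],
                    design[design$sample %in% c("n1", "t1"), ],
                    stage = "invasive", method = "t_test")
  expect_equal(nrow(res1), 0L)
  expect_true(all(attr(res1, "skipped")$reason ==
                    "fewer than two samples per group"))
})

promoter_fixture <- function() {
  # one promoter with two CpGs, strongly hypomethylated in the stage
  calls <- data.table::rbindlist(lapply(
    list(n1 = c(40L, 10L), t1 = c(9L, 51L)), function(ct) {
      data.table::data.table(chrom = "chr1", pos = c(4100L, 4300L),
                             count_C = ct[1], count_T = ct[2],
                             level = ct[1] / sum(ct))
    }))
  calls$sample <- rep(c("n1", "t1"), each = 2)
  genes <- data.table::data.table(gene = c("gX", "gEmpty"), chrom = "chr1",
                                  tss = c(5000L, 50000L), strand = "+")
  calls <- annotate_cpgs(calls, genes)
  design <- data.table::data.table(sample = c("n1", "t1"),
                                   group = c("normal", "invasive"))
  list(calls = calls, genes = genes, design = design)
}

test_that("promoter DiffMeth is the pooled-level difference with Fisher significance", {
  fx <- promoter_fixture()
  res <- promoter_diff(fx$calls, fx$genes, fx$design, stage = "invasive")
  gx <- res[res$gene == "gX", ]
  expect_equal(gx$n_cpgs, 2L)
  expect_equal(gx$level_normal, 0.8)
  expect_equal(gx$level_stage, 0.15)
  expect_equal(format_diffmeth(gx$diffmeth), -0.65)
  expect_equal(gx$direction, "hypo")
  # uncovered promoter is reported, not dropped
  ge <- res[res$gene == "gEmpty", ]
  expect_equal(ge$direction, "ns")
  expect_true(is.na(ge$p_value))
  expect_equal(ge$note, "no coverage")
})

test_that("identical pooled promoter counts are not significant", {
  fx <- promoter_fixture()
  calls <- data.table::copy(fx$calls)
  calls[calls$sample == "t1", c("count_C", "count_T") := list(c(40L, 10L), c(10L, 40L))]
  calls[calls$sample == "n1", c("count_C", "count_T") := list(c(40L, 10L), c(10L, 40L))]
  res <- promoter_diff(calls, fx$genes, fx$design, stage = "invasive")
  gx <- res[res$gene == "gX", ]
  expect_equal(gx$diffmeth, 0)
  expect_equal(gx$p_value, 1)
  expect_equal(gx$direction, "ns")
})

test_that("mean-of-levels mode and minimum effect threshold are honoured", {
  fx <- promoter_fixture()
  res <- promoter_diff(fx$calls, fx$genes, fx$design, stage = "invasive",
                       mode = "mean_of_levels")
  gx <- res[res$gene == "gX", ]
  expect_equal(gx$level_normal, mean(c(0.8, 0.8)))
  res2 <- promoter_diff(fx$calls, fx$genes, fx$design, stage = "invasive",
                        min_effect = 0.9)
  expect_equal(res2$direction[res2$gene == "gX"], "ns")
})
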