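# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package: plain window scans,
# factorial enumeration and full reference scans.

# 0-based cut boundaries by sliding-window motif scan (cut one base into
# the recognition site).
oracle_cut_sites <- function(seq, motif) {
  n <- nchar(seq)
  w <- nchar(motif)
  hits <- integer(0)
  if (n >= w) {
    for (i in 1:(n - w + 1)) {
      if (substr(seq, i, i + w - 1) == motif) hits <- c(hits, i)
    }
  }
  hits  # 1-based motif start == 0-based boundary after the first base
}

oracle_fragments <- function(seq, min_len, max_len) {
  n <- nchar(seq)
  cuts <- sort(unique(c(oracle_cut_sites(seq, "CCGG"),
                        oracle_cut_sites(seq, "TCGA"))))
  cuts <- cuts[cuts > 0 & cuts < n]
  bounds <- c(0L, cuts, n)
  st <- bounds[-length(bounds)]
  en <- bounds[-1]
  keep <- (en - st) >= min_len & (en - st) <= max_len
  data.frame(start = st[keep], end = en[keep])
}

# Exact two-sided Fisher p by full enumeration with log-factorials.
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  lp <- function(x) {
    lchoose(m1, x) + lchoose(m2, n1 - x) - lchoose(m1 + m2, n1)
  }
  support <- max(0, n1 - m2):min(n1, m1)
  probs <- exp(sapply(support, lp))
  p_obs <- exp(lp(a))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Plain full-scan aligner: anchored comparison against every entry.
oracle_align <- function(read, reference, max_conv_mismatch = 3,
                         max_mismatch = 3, min_uniq_gap = 2,
                         min_anchor = 20) {
  split1 <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
  rlen <- nchar(read)
  if (rlen < min_anchor) {
    return(list(status = "unmapped", entry_id = NA_character_,
                best = NA_integer_, second = NA_integer_))
  }
  conv_read <- gsub("C", "T", read, fixed = TRUE)
  cand <- list()
  for (i in seq_len(nrow(reference))) {
    L <- min(rlen, reference$length[i])
    if (L < min_anchor) next
    cr <- split1(substr(conv_read, 1, L))
    ce <- split1(substr(reference$conv_seq[i], 1, L))
    conv_mm <- sum(cr != ce | cr == "N" | ce == "N")
    if (conv_mm > max_conv_mismatch) next
    rr <- split1(substr(read, 1, L))
    re <- split1(substr(reference$raw_seq[i], 1, L))
    bs <- sum((rr != re & !(rr == "T" & re == "C")) | rr == "N" | re == "N")
    cand[[length(cand) + 1]] <- list(i = i, bs = bs)
  }
  if (!length(cand)) {
    return(list(status = "unmapped", entry_id = NA_character_,
                best = NA_integer_, second = NA_integer_))
  }
  bs_all <- vapply(cand, `[[`, numeric(1), "bs")
  ord <- order(bs_all)
  best <- bs_all[ord[1]]
  second <- if (length(bs_all) > 1) bs_all[ord[2]] else NA
  unique_ok <- best <= max_mismatch &&
    (is.na(second) || (second - best) >= min_uniq_gap)
  list(
    status = if (unique_ok) "unique" else "ambiguous_discarded",
    entry_id = if (unique_ok) reference$entry_id[cand[[ord[1]]]$i] else NA_character_,
    best = as.integer(best),
    second = if (is.na(second)) NA_integer_ else as.integer(second)
  )
}

random_seq <- function(n, probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# A small complete simulation bundle for integration tests.
tiny_sim <- function(seed = 11, n_genes = 4, genome_length = 20000,
                     n_replicates = 2, coverage = 12, ...) {
  cfg <- sim_config(seed = seed, n_genes = n_genes,
                    genome_length = genome_length,
                    n_replicates_per_group = n_replicates,
                    mean_coverage = coverage, ...)
  sg <- generate_genome(cfg)
  tr <- assign_methylation(cfg, sg)
  sim <- simulate_reads(cfg, sg, tr)
  list(cfg = cfg, sg = sg, tr = tr, sim = sim)
}

# Construct a bt_reference-shaped table by digesting a hand-built genome.
toy_reference <- function(genome, min_len = 1, max_len = 10^9, end_len = 50) {
  build_reference(predict_fragments(genome, min_len, max_len), genome,
                  end_len)
}
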