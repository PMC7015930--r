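---
title: "Methods: RRBS differential methylation across tumor progression stages"
author: "rrbstage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RRBS differential methylation across tumor progression stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ductal breast carcinoma develops through recognisable stages: hyperplastic
lesions (ADH), pre-invasive carcinoma in situ (DCIS), and invasive
carcinoma. Promoter DNA methylation changes accumulate along this
progression and can distinguish the stages. `rrbstage` implements, end to
end, a reduced representation bisulfite sequencing (RRBS) analysis for
this setting: it predicts which genomic fragments an MspI+TaqI double
digest makes visible, aligns bisulfite-converted reads to those fragment
ends, estimates per-CpG methylation, tests promoters for differential
methylation between each disease stage and normal tissue, classifies
genes by their cross-stage pattern, and scores whether an external
expression table moves in the direction methylation predicts. A seeded
simulator generates study-shaped data with exported ground truth, so the
whole chain is testable without any sequencing archive.

## RRBS and the fragment-end reference

RRBS concentrates sequencing on CpG-dense regions by digesting genomic
DNA with CpG-containing restriction enzymes and size-selecting the
fragments. Here the digest is TaqI (T^CGA) followed by MspI (C^CGG);
because the final fragment set of a complete double digest does not
depend on digestion order, the package models it as a single partition of
each chromosome at the union of both enzymes' cut sites (each cut one
base into its palindromic site). Fragments of 40–350 bp are retained for
analysis; the simulator's gel windows (40–120 and 120–350 bp) are a
separate knob, and chromosome-terminal fragments are kept with a
`chromosome-end` label.

Sequencing reads start at cut sites, so only fragment ends are ever
observed. The aligner's reference therefore holds, for each in-range
fragment, the first 50 bp of the top strand and the first 50 bp of the
bottom strand (the reverse complement of the fragment's last 50 bp) —
the two 5' ends a directional library produces — together with each
entry's fully C→T-converted sequence and the genomic coordinates of its
CpG-context cytosines. CpG context is determined from the genome, not the
50 bp window, so a terminal C followed by a genomic G still counts; any C
adjacent to an N is not treated as a CpG. Bottom-strand cytosines are
mapped to the top-strand coordinate of the palindromic CpG so that both
strands accumulate evidence for one biological site.

## Three-letter alignment and the uniqueness rule

Bisulfite conversion turns unmethylated C into T, so a read and its
reference locus differ wherever conversion happened. The classical
three-letter strategy removes this: residual cytosines in the read are
collapsed to T (positions noted), the reference entries are likewise
fully converted, and candidate hits are entries whose converted sequence
is within `max_conv_mismatch` (default 3) anchored mismatches of the
converted read. Alignment is ungapped and anchored at entry position 0
because RRBS reads begin exactly at cut sites; reads shorter than 20 bp
are not aligned, longer reads are truncated to the entry length.

Candidates are then re-scored in *unconverted* space with bisulfite-aware
counting: a read T over a reference C is ignored (that is precisely a
converted cytosine), a read C over a reference T counts, and N on either
side counts. A read is kept only if its best candidate has at most
`max_mismatch` (default 3) such mismatches and beats the second-best
candidate by at least 2; ties and near-ties are discarded as non-unique.
"Two more mismatches" is read as `second_best − best ≥ 2`, so an exact
tie (gap 0) and a gap of 1 are both discarded. The caps and the tie
policy are configuration, not inference: the analysis convention they
encode is stated here once and used everywhere. Internally the aligner
computes all-pairs mismatch counts blockwise with one-hot cross-products,
which is arithmetically identical to scanning every entry per read; the
test suite holds it to a brute-force full-scan oracle.

## Methylation calling

Each uniquely aligned read reports, at every CpG offset of its entry that
it covers, either C (the cytosine resisted conversion: methylated) or T
(converted: unmethylated); any other base there is a sequencing error and
is ignored. Counts from the two strands are merged per CpG site by
default (`merge_strands = FALSE` keeps them apart). The methylation level
is `#C / (#C + #T)`, and only CpG×sample records with depth ≥ 5 enter
inference — the boundary is inclusive, and the filter is applied per
sample before group pooling. Each CpG is annotated with promoter
(−1000/+500 bp around the TSS, mirrored for minus-strand genes — a
common proximal-promoter convention; the window is configurable),
gene-body, and CpG-island membership. Islands are called with classic
windowed criteria (200 bp windows, GC ≥ 0.5, observed/expected CpG ≥ 0.6,
overlapping qualifying windows merged); a user-supplied island BED can
replace detection.

## Differential methylation

For each stage versus normal, replicate counts are pooled within groups —
matching a design with few biological replicates per tissue class — and
each CpG with pooled depth ≥ 5 in both groups is tested on its 2×2 C/T
table with a two-sided Fisher exact test (implemented from the
hypergeometric density, summing the probabilities of all tables at fixed
margins no more probable than the observed one). A Welch t-test on
per-sample levels is the alternative path when at least two replicates
per group are available.

Promoter-level inference sums C/T counts over all qualifying CpGs of a
promoter into one 2×2 table per comparison; `DiffMeth` is the difference
of pooled levels (stage − normal, in [−1, 1], reported to two decimals
but kept at full precision internally), and direction (hyper/hypo) is
assigned by sign when raw p < 0.05. The pooled-count definition was
chosen over the mean-of-CpG-levels alternative because it weights CpGs by
evidence and feeds the same table to the test; `mode = "mean_of_levels"`
is available, as are a minimum-effect threshold (default 0) and
Benjamini–Hochberg adjustment (reported always, used for calls only on
request — the default mirrors the raw p < 0.05 convention of the
analysis this package implements; with hundreds of promoters the BH flag
is the recommended setting for new studies). CpG-level tables are emitted
alongside so users can apply, e.g., min-one-significant-CpG rules
instead.

## Stage categories, Venn counts, heat map

Each gene's three direction calls (ADH, DCIS, invasive) collapse into one
progression category: `adh_only` / `dcis_only` / `invasive_only` (one
significant stage), `late_stage` (DCIS and invasive, same sign, ADH
quiet), `all_stages_consistent` (all three, one sign),
`opposite_direction` (two or more significant stages with conflicting
signs — including DCIS/invasive disagreement, which is deliberately not
`late_stage`), `mixed` (ADH plus one later stage, same sign), or `none`.
The mapping is total over the 27 status triples and exhaustively tested.
Venn totals per stage always satisfy hypo + hyper = total (asserted at
run time), and the heat-map matrix orders rows by category and then by
invasive-stage DiffMeth so layouts are reproducible.

## Expression concordance

For significant promoters of one comparison, concordance asks whether an
external `gene → log2 fold-change` table moves oppositely to promoter
methylation: hypermethylated → downregulated, hypomethylated →
upregulated. Percentages divide by *all* significant promoters of that
direction; genes absent from the expression table stay in the denominator
as "no data". The fold-change threshold defaults to 0 (pure direction
agreement). Percentages are rounded half away from zero — one convention,
applied uniformly. Ortholog mapping between species is upstream of this
module: the expression table is assumed already joined by gene symbol
(case-insensitively).

## The simulator and what the benchmarks show

`sim_config()` describes a study: genome size, number of genes, CpG
densities, group labels with replicate counts, per-gene baseline
methylation (default drawn uniformly from [0.3, 0.8]), a gene×group
effect table, coverage, read length, bisulfite conversion rate (0.99) and
sequencing error rate (0.001). Background sequence is mildly AT-rich
(GC ≈ 0.40) and CpG-poor, as in mammalian genomes, while promoter windows
are CpG-enriched, so restriction sites and islands concentrate in
promoters exactly as RRBS assumes; CpGs outside promoters sit at a high
background methylation level (0.75) in every group and act as true nulls.
Read counts per fragment end are Poisson — the natural count model for
the Fisher tests downstream — and only the two original-strand 5' ends
are sequenced (directional protocol). Biological replicate noise draws
each sample's promoter level from `Beta(m·κ, (1−m)·κ)` with κ = 50 by
default, giving a per-sample standard deviation of about 0.07 at m = 0.5.
Truth tables are TSV sidecars, never FASTQ comments, so the pipeline
cannot see them.

The bundled benchmark configuration (`progression_demo_config()`) uses 20
genes over 100 kb, ±0.5 effects on eight genes in four stage patterns,
30× coverage and n = 3 per group — scaled to run in about two minutes on
one CPU; these sizes are stated here as the package's chosen benchmark
conditions. One design point deserves emphasis: the benchmark disables
replicate noise (κ = ∞). Pooling replicates and applying Fisher's exact
test is *exact only under within-sample binomial sampling*; with real
between-replicate variance the pooled test is anticonservative, and at
the pooled depths this design reaches (promoter tables of 10³–10⁴
reads) κ = 50 noise drives the null rejection rate far above the nominal
0.05 — a well-known property of pooled exact tests, not a defect of this
implementation. The calibration and recovery benchmarks therefore test
the machinery under its own sampling model, where exactness is a
meaningful claim; runs with κ finite demonstrate the t-test path, which
is the appropriate inference under biological dispersion. Consequently,
passing benchmarks show correctness of the pipeline's computations — they
do not show that pooled Fisher p-values are calibrated on real replicated
tissue data, and for such data the t-test path or an adjusted threshold
should be preferred.

A second caveat the simulator makes visible: with promoter tables that
large, the exact test flags differences of ~0.01 in methylation as
significant, so a truly null stage of an affected gene occasionally turns
"significant" with a negligible DiffMeth, which changes the gene's
progression *category* even though every true effect is recovered with
the correct sign. Per-stage false-positive rates stay at the nominal
level; category labels inherit them multiplicatively. A minimum-effect
threshold (`min_effect`) suppresses this if category stability matters
more than strict fidelity to the raw p < 0.05 convention; the default
keeps the convention.

What the simulator does not emulate: adapter read-through, PCR
duplicates, quality-score structure, indels, copy-number or purity
effects, non-CpG methylation, and spatial correlation of methylation
beyond promoter blocks. Recovery results should be read with those
limits in mind.

## Numerical conventions

Coordinates are 0-based half-open in memory and in BED files, 1-based
only in human-readable text. The Fisher implementation compares table
probabilities with a `1e-7` relative slack (the standard guard against
floating-point ties) and matches an independent factorial-enumeration
oracle to 1e-12 over all tables with margins ≤ 15. All randomness flows
from one master seed through named substreams
(`substream_seed(seed, "reads:ADH_2")` etc.), so any stage can be
reproduced in isolation; byte-identical outputs under a repeated seed are
part of the test suite. Degenerate inputs follow explicit rules: zero
margins are an error for the Fisher test, promoters without covered CpGs
are reported with `direction = "ns"` and a `"no coverage"` note rather
than dropped, empty FASTQs yield empty alignment tables, and methylation
levels at m ∈ {0, 1} bypass the Beta noise (which is undefined there).

## Running the workflow

The `analysis/` scripts run the demonstration study end to end
(`01_simulate.R` → `06_concordance.R`), writing tables under
`results/demo/`. The same computation is available as one call:

```{r, eval = FALSE}
library(rrbstage)
cfg <- run_config(out_dir = "results/demo-run",
                  sim = progression_demo_config(seed = 42))
res <- run_pipeline(cfg)
res$venn$per_stage
```

`scripts/acceptance.R` re-runs the recovery and calibration benchmarks
and the concordance worked example from scratch and writes the resulting
metrics as JSON.
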