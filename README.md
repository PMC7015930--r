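# rrbstage

Reduced representation bisulfite sequencing (RRBS) analysis of promoter
DNA methylation across breast tumor progression stages — normal tissue,
atypical ductal hyperplasia (ADH), ductal carcinoma in situ (DCIS), and
invasive carcinoma — with a fully seeded synthetic-data generator so the
entire pipeline is testable without any sequencing archive.

The package is for epigenomics analysts who want a transparent,
end-to-end reimplementation of the classic RRBS promoter-methylation
workflow: in-silico restriction digestion, three-letter bisulfite
alignment, CpG methylation calling, Fisher-exact differential testing,
progression-category classification, and methylation–expression
concordance — every stage a tested R function.

## The method

1. **Digest** — chromosomes are partitioned at the union of TaqI (T^CGA)
   and MspI (C^CGG) cut sites; fragments of 40–350 bp are retained, and
   the aligner's reference is built from the 50 bp 5' ends of both
   strands of each fragment, fully C→T converted.
2. **Align** — reads have residual cytosines collapsed to T and are
   matched, ungapped and anchored at the cut site, against the converted
   reference (≤ 3 mismatches). Candidates are re-scored in unconverted
   space where a read **T over reference C is not a mismatch** (that is
   bisulfite conversion) but **C over T is**. A read is kept only if its
   best hit beats the second best by ≥ 2 mismatches; otherwise it is
   discarded as non-unique.
3. **Call** — at each covered CpG, a read contributes C (methylated) or
   T (unmethylated); both strands merge onto one site, and the level is
   `#C / (#C + #T)` for sites with ≥ 5 reads. CpGs are annotated with
   promoter (−1000/+500 bp of the TSS), gene body, and CpG island
   (200 bp windows, GC ≥ 0.5, obs/exp CpG ≥ 0.6).
4. **Test** — per stage vs normal, replicate counts are pooled, each
   promoter's CpG counts are summed into one 2×2 table, and
   `DiffMeth = level_stage − level_normal` is called hyper-/hypomethylated
   by sign when the two-sided Fisher exact p < 0.05 (a Welch t-test on
   per-sample levels is the alternative path).
5. **Classify** — each gene's (ADH, DCIS, invasive) direction triple maps
   to a progression category: single-stage, late-stage (DCIS+invasive,
   same sign), all-stages-consistent, opposite-direction, or mixed;
   per-stage Venn counts and a DiffMeth heat-map matrix follow.
6. **Concordance** — significant promoters are scored against an external
   `gene, log2fc` expression table: hypermethylated→down and
   hypomethylated→up count as concordant, with all significant promoters
   of a direction in the denominator.

## Worked example

The `analysis/` scripts run a demonstration study: a simulated 100 kb
genome with 20 CpG-dense promoters, eight of which carry ±0.5
methylation effects in stage-specific patterns (invasive-only,
DCIS+invasive, DCIS-only, opposite-direction), sequenced at 30× per
fragment end for 3 replicates × 4 groups.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_digest_reference.R
Rscript analysis/03_align_call.R
Rscript analysis/04_differential_methylation.R
Rscript analysis/05_stage_classification.R
Rscript analysis/06_concordance.R
```

Output at seed 42:

```
digestion: 596 in-range fragments (median 101 bp) -> 1192 reference entries
20/20 promoters overlap at least one in-range fragment; 3070 CpGs on top-strand fragment ends
normal_1: 35693 reads, 100.0% unique, 0.0% discarded as non-unique
56448 CpG-by-sample calls pass the coverage filter; 33 CpG islands (37160 bp total)
ADH vs normal: 2/20 promoters significant (1 hypo, 1 hyper); strongest DiffMeth g008 -0.50
DCIS vs normal: 5/20 promoters significant (3 hypo, 2 hyper); strongest DiffMeth g006 -0.50
invasive vs normal: 6/20 promoters significant (3 hypo, 3 hyper); strongest DiffMeth g002 -0.50
invasive DiffMeth vs truth: max |error| 0.013 over 20 promoters
```

The classification stage then reports the recovered categories
(`dcis_only = 2`, `late_stage = 3`, `invasive_only = 1`,
`opposite_direction = 2`, `none = 12`; one true invasive-only gene drew a
borderline DCIS call at raw p < 0.05 — see the vignette on category
stability) with the per-stage conservation identity hypo + hyper = total
(2, 5, 6). Exact numbers for any run are in
`results/demo/*.tsv`; the same computation is available in one call via
`run_pipeline(run_config(out_dir, sim = progression_demo_config(seed = 42)))`.

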