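---
title: "Gene-centric transcriptome coverage: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centric transcriptome coverage: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genecov)
```

## The question the package answers

Different RNA quantification platforms disagree not only about *how much*
of a transcript is present but about *whether it is present at all*.
genecov takes the gene-centric view: a chromosome's (or the genome's)
coverage is the fraction of its protein-coding genes for which at least
one transcript is detected, where "detected" means passing a platform
cut-off rule. Everything else in the package — set similarity, Venn
decompositions, donor variability, calibration — is built on those
detection sets.

The denominator of every statistic is a **gene catalog**: the unique
protein-coding genes of a GTF annotation, restricted to the 24 nuclear
chromosomes (1–22, X, Y). Mitochondrial genes and alt/random scaffolds are
excluded so that denominators are stable across annotation dialects. Gene
identity is the Ensembl-style `gene_id` with the `.version` suffix
stripped; symbols are kept for reporting but never used as keys, because
symbols are not unique.

## Detection rules and the cut-off sweep

The canonical minimum cut-offs are strict `FPKM > 0` (short-read RNA-Seq),
strict `TPM > 0` (nanopore direct RNA), and inclusive `Ct ≤ 40` (qPCR; Ct
is the amplification cycle at which probe fluorescence exceeds background,
so *lower* Ct means *more* template, and 40 cycles is the usual trust
limit). Strictness matters at the boundary: an abundance of exactly 0
never counts as detected, while a Ct of exactly 40.0 does. A gene counts
once no matter how many of its isoforms pass the cut-off; gene-level
abundance from transcript-level quantifications is the *sum* of member
transcript values (the usual convention downstream of transcript
quantifiers), which leaves detection unchanged whenever any isoform is
non-zero.

`cutoff_sweep()` recomputes the detected count along an ascending
threshold ladder. For strict `greater_than` rules the counts are
non-increasing — raising a cut-off can only remove genes — and the suite
checks this against brute-force filtering on random tables.

## Coverage tables, inclusion–exclusion, and truncation

`coverage_table()` tabulates, per chromosome, the catalog size, the two
platforms' detected counts, their intersection, and three proportions:
each platform's coverage and the two-platform union obtained by
inclusion–exclusion, |A ∪ B| = |A| + |B| − |A ∩ B|.

Two formatting conventions deserve a note, because they are deliberately
*not* rounding:

* **Proportions truncate.** Displayed proportions are
  `floor(x·10^d)/10^d`. The choice is forced by consistency with the
  published tables this layout mirrors: 453/812 = 0.5578 must print as
  0.55 and 186/275 = 0.6763 as 0.67, both of which rounding would break.
  Figure-style percentages truncate at one decimal (224/275 → 81.4%).
  Integer percentages are the one exception: they round
  (63/275 = 22.9% → 23%), which is how whole-percent figures are
  conventionally printed. Raw proportions are always carried alongside
  (in the `raw_proportions` attribute), so truncation never destroys
  information.
* **The summary row averages, it does not pool.** Its counts are column
  sums, but its proportions are the unweighted mean of the per-chromosome
  raw proportions, rounded — a "typical chromosome" summary rather than a
  genome-wide pooled ratio. Published tables of this kind report the
  column average (which a pooled ratio-of-totals does not reproduce), and
  the mean-of-chromosomes reading is the one consistent with them. Users
  who want the pooled ratio can compute it from the count columns.

A related known inconsistency: published per-chromosome tables of this
design print a chrY second-platform cell of 0.03 where the printed counts
give 12/40 = 0.30. genecov reports 0.30; the desk-check tests exclude that
single cell.

## Set similarity and its interpretation bands

`tanimoto()` computes T(a,b) = |a∩b| / (|a| + |b| − |a∩b|) and classifies
it: T ≥ 0.70 — the sets are effectively identical; 0.55 ≤ T < 0.70 —
similarity is much weaker; T < 0.55 — the sets differ considerably. The
literature ranges for these bands overlap at their edges; the package
resolves them as the half-open intervals above, which reproduces the
published verdicts at T = 0.75 (identical) and T = 0.67, 0.63 (weaker).
Whether T = 0.55 itself is "weaker" or "different" is not decidable from
the published wording; here it is "weaker", a documented convention rather
than a claim about the original authors' intent. Two empty sets get
T = 1.0 — with no members there is no evidence of difference — another
convention that real data never exercises.

`donor_variability()` measures inter-donor reproducibility: for each donor
the genes detected *only* in that donor, divided by the union of all
donors' detections for that technology, averaged over donors. The
denominator is deliberately the cross-donor union (the "total detected by
the technology"), not each donor's own set size, which keeps the statistic
a fraction of a common universe.

## Calibration: from relative abundance to copies per cell

`fit_calibration()` is ordinary least squares of log10(copies per cell) on
log10(abundance), the classic modelling interface: it returns a classed
fit with `print`, `summary`, `coef`, `predict`, `plot`, `residuals` and
`simulate` methods. Pairs are restricted to genes detected by *both*
platforms (abundance > 0, copies > 0, Ct within the limit) — log of zero
is undefined and an undetected gene carries no calibration information.
Log base 10 on both axes is the only transform under which one linear fit
is meaningful across the four-to-five-decade dynamic range of a
transcriptome.

Conversion through the model is gated on R² > 0.5: below that the
regression equation is too loose to convert relative units into absolute
copy numbers, and `convert_abundance()` refuses with a classed error
rather than returning a number. Degenerate inputs (zero variance on
either axis, fewer than 3 pairs) are errors, not silently perfect or
silently zero R².

## What the synthetic study emulates — and what it does not

`preset("liver")` and `preset("hepg2")` generate a 3-donor, 3-platform
study over a 24-chromosome catalog whose per-chromosome gene counts follow
a census of human protein-coding genes (19,593 genes at scale 1).

True expression is drawn per gene on the log10 copies-per-cell scale:
unimodal Normal(0.5, 1) for liver-like tissue, and for the proliferating
cell-line preset a two-component mixture (means 0.5 and 2.5, sd 0.6,
equal weights) — a low-expressed and an elevated component. Donor copies
are the truth times a lognormal jitter (sd 0.1 on the log10 scale).
Transcript lengths are lognormal with median 2 kb; chrY genes are drawn
short (median 400 nt) to exercise the nanopore length floor.

Platform observation models are minimal mechanisms with the right
qualitative behaviour, not read-level simulators:

| platform | sampling | detection | default parameters |
|---|---|---|---|
| short-read | reads ~ Poisson(depth·copies·kb) | ≥ 3 reads | depth 17 |
| nanopore | same, length-penalized | ≥ 8 reads | depth 2.5; < 500 nt gets ×0.05 |
| qPCR | Ct = 38.7 − 3.32·log10(copies) + N(0, 0.3) | Ct ≤ 40 | slope 3.32 ≈ log2(10), i.e. 100% PCR efficiency |

Reported abundances are copies times lognormal measurement noise — FPKM
as-is, nanopore renormalized to TPM (summing to 10^6), qPCR as copies per
cell with the Ct carried — and 0 for undetected genes. Detection
probability is non-decreasing in true copies on every platform (tested).
One RNG stream per (donor, platform) is derived from the master seed, so
adding a platform never perturbs another's draws, and a seed fully
determines the output.

The defaults were chosen once, by calibrating the three detection margins
to the study conditions the liver preset is meant to emulate: pooled
coverage ordering short-read > qPCR > nanopore at roughly 0.96 / 0.84 /
0.67 of the catalog, inter-donor variability at most 5% on every platform
(measured 0.8% / 1.1% / 2.8% over 20 seeds), and strongly depressed
nanopore detection of sub-500-nt transcripts. The nanopore depth is small
because a single direct-RNA flow cell yields on the order of 1–1.5 Gb,
far from saturating transcript detection.

What the generator does **not** emulate: read-level artifacts (no FASTQ,
no alignment, no splicing), fragment GC and positional bias, between-gene
expression correlation, batch effects, and biological donor structure
beyond a lognormal jitter. Passing the end-to-end tests therefore shows
that the *pipeline* recovers the statistical structure it assumes — it is
not evidence about any particular real dataset.

```{r end-to-end}
cfg <- preset("liver", seed = 17)
truth <- simulate_truth(cfg)
catalog <- truth_catalog(truth)
tables <- simulate_platform_tables(truth, cfg)
det <- lapply(tables, function(donors)
  lapply(donors, function(q) detect(q, platform_rule(q$platform), catalog)))
pooled <- lapply(det, function(d) unique(unlist(lapply(d, `[[`, "genes"))))
round(vapply(pooled, length, integer(1)) / nrow(catalog), 3)
```

## Problem sizes and tolerances

The test suite runs the full generator at scale 1 (19,593 genes, 3 donors,
3 platforms) over 20 seeds for the end-to-end checks — about half a second
per seed — and uses 1,000 random set pairs for the similarity properties
and 100 random instances for the OLS-versus-normal-equations oracle.
Calibration recovery is asserted at n = 200 pairs, noise sd 0.1, within
±0.05 of the generating slope and intercept, consistent with the OLS
standard error at that design. Desk arithmetic (truncation, unions, bands)
is asserted exactly.

## Known limitations

* Venn decomposition is limited to 2 or 3 sets; k-set coverage beyond that
  is out of scope (the union machinery itself is pairwise).
* The calibration model is a single straight line in log–log space; real
  FPKM-to-copies relations can flatten at the detection floor, which a
  one-piece line ignores. The R² gate is the guard against over-reading
  such fits.
* Overlap significance (e.g. hypergeometric tests on detection sets) is
  deliberately not computed; the statistics here are descriptive.
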