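# genecov

Gene-centric transcriptome coverage analysis across quantification
platforms.

Bulk RNA quantification platforms disagree about which genes are expressed
at all: short-read RNA-Seq (abundances in FPKM), nanopore direct RNA
sequencing (TPM), and qPCR (absolute copies per cell, with a threshold
cycle Ct) each have their own detection floor. genecov is for
transcriptomics researchers who want to quantify that disagreement the
gene-centric way: per chromosome, what fraction of protein-coding genes
has at least one detectable transcript on each platform, how much a second
platform adds, and how stable the answer is across donors.

The core quantities:

* **Detection sets** under cut-off rules — strict `FPKM > 0`, strict
  `TPM > 0`, inclusive `Ct ≤ 40` — restricted to a protein-coding gene
  catalog built from a GTF annotation (24 nuclear chromosomes), and
  cut-off sensitivity sweeps.
* **Coverage tables** per chromosome with the two-platform union by
  inclusion–exclusion, |A ∪ B| = |A| + |B| − |A ∩ B|, and proportions
  displayed by truncation (not rounding) with raw values carried
  alongside.
* **Tanimoto similarity** T(a,b) = |a ∩ b| / (|a| + |b| − |a ∩ b|) with
  interpretation bands (≥ 0.70 identical, 0.55–0.70 weaker, < 0.55
  different), 2–3-set Venn decompositions, and an inter-donor
  variability statistic (mean fraction of technology-total detections
  specific to a single donor).
* **Calibration models**: ordinary least squares of log10(copies per
  cell) on log10(abundance) over genes detected by both platforms,
  returned as a classed fit with the usual methods; conversion into
  copies per cell is refused unless R² > 0.5.
* A **synthetic study generator** (`preset("liver")`, `preset("hepg2")`)
  producing multi-donor, multi-platform tables with per-platform
  detection models (Poisson sampling with a length floor for nanopore, a
  linear Ct model for qPCR), so the whole pipeline runs and is testable
  without any downloads.

## Worked example

Simulate the liver-style study (3 donors, 3 platforms, 19,593 genes),
derive pooled detection sets, and tabulate coverage:

```r
library(genecov)

cfg     <- preset("liver", seed = 17)
truth   <- simulate_truth(cfg)
catalog <- truth_catalog(truth)
tables  <- simulate_platform_tables(truth, cfg)

det <- lapply(tables, function(donors)
  lapply(donors, function(q) detect(q, platform_rule(q$platform), catalog)))
pooled <- lapply(det, function(d) unique(unlist(lapply(d, `[[`, "genes"))))
round(vapply(pooled, length, integer(1)) / nrow(catalog), 3)
#> illumina      ont     qpcr
#>    0.963    0.673    0.842
```

Short-read sequencing detects 96.3% of the catalog, qPCR 84.2%, shallow
nanopore sequencing 67.3% — the characteristic ordering of detection
floors. The per-chromosome coverage table (here short-read vs nanopore):

```r
mk <- function(p) structure(list(platform = p, donor = "pooled",
  rule = platform_rule(p), genes = sort(pooled[[p]])),
  class = "detection_set")
tab <- coverage_table(list(a = mk("illumina"), b = mk("ont")), catalog)
head(as.data.frame(tab), 3)
#>   chromosome n_genes  n_a  n_b n_both prop_a prop_b prop_union
#> 1          1    2022 1954 1338   1338   0.96   0.66       0.96
#> 2          2    1247 1206  835    835   0.96   0.66       0.96
#> 3          3    1059 1025  728    728   0.96   0.68       0.96
```

`prop_union` barely exceeds `prop_a`: adding nanopore to short-read
sequencing contributes almost no extra genes in the unimodal liver-like
regime. Similarity and donor variability:

```r
tanimoto(pooled$illumina, pooled$qpcr)
#> Tanimoto similarity: |a| = 18868, |b| = 16503, |a ∩ b| = 16500, T = 0.874 (identical)
donor_variability(lapply(det$ont, `[[`, "genes"))
#> Inter-donor variability: 2.80% (specific counts: donor1=364, donor2=370, donor3=372; union = 13190)
```

And the calibration of FPKM against qPCR copies for one donor:

```r
fit <- fit_calibration(
  pair_for_calibration(tables$illumina$donor1, tables$qpcr$donor1))
fit
#> Calibration (illumina): log10(copies/cell) = 0.964 * log10(FPKM) + 0.027
#>   R² = 0.948 on n = 15904 gene pairs; conversion acceptable (R² > 0.5)
convert_abundance(fit, 10)   # copies per cell at FPKM = 10
```

The generator creates FPKM proportional to copies, so the recovered
log–log slope is near 1; on real data R² is often well below the 0.5
acceptability gate, in which case `convert_abundance()` refuses.

A thin command-line wrapper around the same functions ships at
`inst/cli/genecov` (subcommands `simulate`, `coverage`, `sweep`,
`compare`, `calibrate`, `report`), and `run_full_analysis()` writes the
whole report bundle (coverage TSV, similarity/Venn/variability JSON,
sweep TSV, calibration JSON, manifest) in one call.

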