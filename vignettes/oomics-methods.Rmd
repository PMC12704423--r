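---
title: "Methods: multi-omic analysis of GV-oocyte knockout models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic analysis of GV-oocyte knockout models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oomics)
```

`oomics` implements the analysis stages used to characterize epigenetic and
proteomic consequences of subcortical maternal complex (SCMC) gene knockouts
in mouse germinal-vesicle (GV) oocytes: differential protein abundance from
raw label-free intensity tables, single-cell bisulfite (scPBAT) methylome QC
and differential methylation, marker-based NSN/SN staging of oocyte
transcriptomes, and cross-omic integration. Every stage can be exercised on
seeded synthetic data with planted ground truth, so the statistical
behaviour of the pipeline (calibration, power, recovery) is testable without
any external download.

## Differential protein abundance

The proteomics stage consumes a raw intensity matrix (proteins × samples,
strictly positive where present) with a sample-to-group design. Analysis is
deliberately minimal, mirroring the standard desktop workflow for this kind
of matrix:

1. `log2_transform()` — per-value log2; no width, median or quantile
   normalization and no imputation are applied by default. The bundled
   GV-oocyte tables reproduce their published headline fold changes exactly
   under plain log2 means, which is the behaviour a user comparing against
   such tables needs.
2. `group_log2fc()` — fold change is the **difference of per-group means of
   log2 intensities** (test − reference), not the log2 ratio of mean raw
   intensities. Unequal group sizes are handled by plain means. Proteins
   with fewer than two present values in either group are untestable (`NA`)
   and are excluded from the multiple-testing family.
3. `differential_test()` — two-sample Student t-test (pooled variance, the
   convention of the Perseus-style pipeline this stage mirrors; Welch via
   `var_equal = FALSE`), Benjamini–Hochberg adjustment, and a significance
   flag requiring `q < 0.1` **and** `|log2FC| > 0.5` (both strict). The
   fold-change cut-off corresponds to a ±30% abundance change.
4. `percent_of_reference()` returns `2^log2FC × 100` at full precision;
   `format_percent()` applies the reporting convention (one decimal below
   10%, integer above).

`standardize_for_heatmap()` supports two display standardizations: plain row
centring, and a cross-dataset mode that first subtracts each dataset's
global mean and divides by its global **variance** (not the standard
deviation — this matches the convention of the comparative heatmaps this
mode reproduces) before row-centring within dataset.

```{r proteomics}
scmc <- log2_transform(oocyte_proteome_example("scmc"))
fc <- group_log2fc(scmc, reference_group = "WT", test_group = "Hom")
round(fc[["NALP5"]], 2)
format_percent(percent_of_reference(fc[["NALP5"]]))
```

## Single-cell methylome QC and differential methylation

The methylome stage consumes Bismark-style per-CpG coverage files (1-based;
the percentage column is ignored and recomputed from counts) plus BED region
annotations (0-based half-open, converted at the boundary). Strand is
assumed already merged.

**Contamination screen.** GV oocytes have an idiosyncratic methylome —
bimodal 100-CpG tile methylation peaking at 0% and 100%, unusually high
non-CpG methylation, and unmethylated X-chromosome CpG islands — while
contaminating somatic (granulosa) DNA is unimodal and intermediate
genome-wide, methylated at X CGIs, and nearly devoid of CHH methylation.
`screen_cells()` therefore retains a cell only if it passes:

1. read count: ≥ 600,000 CpGs covered (boundary passes);
2. X-CGI methylation ≤ 10% (pooled over X CGIs; strictly above 10% flags
   contamination);
3. context ratios from the aligner QC summary: mCpG < 40%, mCHG > 3%,
   mCHH > 4% (all strict);
4. tile bimodality: over informative tiles (≥ 5 calls), the mid-range
   fraction (25–75%) must be ≤ 0.20 with ≥ 5% of tiles in each tail.

The bimodality rule is a quantitative operationalization of a criterion that
is usually judged visually from the tile histogram; its thresholds are
exposed (`max_mid`, `min_tail`) and were fixed before any testing at values
that cleanly separate the generator's pure-oocyte and 50:50-mixture
profiles. Criteria with no informative data return `"untestable"` and the
cell is excluded conservatively. When a cell already fails the read filter
the contamination criteria are reported `NA` by default.

**Tiling and statistics.** `build_tiles()` groups each chromosome's
reference CpG map into consecutive windows of exactly 100 CpGs; a trailing
partial window is dropped so tile statistics stay homogeneous.
`quantify_tiles()` pools calls per tile and reports percent methylation only
at ≥ 30 calls (pseudo-bulk) or ≥ 5 calls (individual cells) — both exposed.
`segment_domains()` merges runs of consecutive informative tiles at 0–25%
into hypomethylated domains and 75–100% into hypermethylated domains
(closed intervals, runs broken by missing or mid-range tiles).

Differential methylation (`call_dmrs()`, `test_gdmrs()`) uses a Pearson
chi-square test (df 1, **no** continuity correction) on pooled pseudo-bulk
counts, BH adjustment ("adjusted P" is not otherwise specified in the
workflows this mirrors; BH is the natural reading), and calls requiring
`q < 0.05` and `|Δ| > 25` percentage points (strict). Tiles are restricted
to hypo/hypermethylated domains when a domain annotation is supplied.
Germline DMRs (gDMRs) are quantified over whole regions at ≥ 20 calls, and a
gDMR is only *called* when also highly covered — strictly more than 100 CpG
calls per kilobase. The source workflow does not say whether that filter
applies to one or both groups; the default here is **both** (the
conservative reading), with `density_mode = "either"` available.

`global_methylation()` computes each cell's unweighted mean over informative
tiles (default ≥ 5 calls, the individual-oocyte setting; the alternative
30-call reading is one argument away) and compares groups by Welch t-test
plus a difference of group medians.

## Transcriptome QC, staging, differential expression

`qc_cells()` applies the stated per-cell bounds: ≥ 4 million reads,
mito < 2%, rRNA < 10%, genes measured within the closed interval
[37%, 50%], uniquely mapped > 70%; every violated bound is listed.

`stage_cells()` assigns NSN/SN maturity from marker genes. The score is the
mean z-scored log1p-CPM of SN markers minus the same for NSN markers, with a
symmetric margin (default 0.5): above the margin → SN, below the negative
margin → NSN, otherwise ambiguous (ambiguous cells are what a user should
exclude, mirroring the practice of excluding unclear samples rather than
forcing a call). The statistic and margin are exposed because the underlying
practice is defined only as "marker-based with exclusion of unclear
samples"; a mean-difference of z-scores is robust to library size and to a
single aberrant marker.

`surrogate_de_test()` is a plain per-gene Welch t-test on log2(CPM + 1). It
is **not** a negative-binomial model and is documented as a surrogate:
externally computed per-gene tables (e.g. from a dedicated DE package) in
the same `gene`/`log2fc`/`p` schema plug into `threshold_degs()`, which
applies BH and the inclusive cut-offs `q ≤ 0.05`, `|log2FC| ≥ 0.5`. (A
stricter |log2FC| > 2 / FDR < 10% display convention exists in some volcano
plots; the analysis thresholds are the default here and both are reachable
through the arguments.) `combine_stage_degs()` forms the union and shared
set of stage-wise DEG lists.

## Cross-omic integration

`hypergeometric_overlap()` computes the upper-tail probability
`P(X ≥ k)` for the overlap of two feature sets in a universe. The universe
is the caller's choice; the recommended (and default in the worked
examples) universe is the features detected in **both** omics layers, since
an overlap statistic computed on asymmetric universes is not interpretable.
Depletion is available behind a flag. `paired_fc_scatter()` joins per-gene
and per-protein fold changes through a one-to-one feature map and reports
the Pearson correlation with the paired table.

## The synthetic-data generators

`simulate_methylomes()` emulates the data structure the screen and the
methylation statistics assume:

* genome: 5 autosomes + X, 20,000 CpGs each at exact 100 bp spacing
  (10 CpGs/kb) — 1,200 full tiles, small enough for desk-scale tests and
  large enough for stable tile statistics;
* bimodal oocyte profile: alternating hyper (0.90) / hypo (0.05) blocks of
  5 tiles; CpG islands inherit their domain's level except on the X, where
  oocyte CGIs sit at 0.02 and somatic at 0.40;
* somatic contaminant: unimodal 0.70 genome-wide (its true global level is
  not documented for the screen this emulates; 0.70 is a conventional
  somatic value and makes mixtures fail the screen the way real
  contamination does), mCpG/mCHG/mCHH 75/1/0.5% versus oocyte 38/5/6%;
* contamination acts **per read**: each read is drawn from the somatic
  profile with probability *f*, so site-level methylation, context
  summaries and X-CGI levels shift jointly — exactly the coupling the three
  screening criteria rely on;
* coverage: each CpG covered independently with probability
  `coverage_rate / total CpGs` (default 36,000 expected CpGs ≈ 30%), read
  depth 1 + zero-truncated Poisson(1);
* planted effects: a 0.10 deficit on hyper domains in KO cells (half the
  tiles are hypermethylated, so the planted **global** deficit is
  5 percentage points, matching the magnitude of deficit this assay is
  meant to detect) and three single-tile gDMRs at 0.85 with a −30 pp KO
  effect; default cell numbers are 19 WT / 10 KO;
* truth: every planted quantity — per-cell group and contamination, per-gDMR
  delta, the expected per-group global level — is returned once in `truth`.

Context summaries are binomial draws (200,000 cytosines per context) around
the mixed expected fractions, independent of the site-level draws; this
mirrors the fact that real context summaries come from the aligner's QC
report, not from the CpG coverage file.

What the generator does **not** emulate: read-level bisulfite conversion
error, CpG density variation (CGIs are not CpG-denser than their
surroundings), replication- or transcription-coupled methylation structure,
and correlated coverage along the genome. Tests passing on this generator
therefore demonstrate the statistics' behaviour under the assumed model,
not robustness to real-data artefacts beyond those modelled.

Note one scale consequence: the synthetic genome has 120,000 CpGs, so the
real-data read-count threshold (600,000 covered CpGs) is unreachable by
construction; simulation-based tests pass a genome-appropriate `min_cpgs`
(e.g. 30,000) to `screen_cells()` while the default stays at the real-data
value.

`simulate_proteome()` draws log-normal intensities
(`2^Normal(baseline + shift, sd)`, default sd 0.3 on ~20 log2 units of
baseline) with per-group planted shifts and MCAR missingness.
`simulate_counts()` draws negative-binomial counts with stage-specific
marker multipliers (default 10× across 20-gene NSN/SN modules) and planted
KO shifts; default cell numbers are 4/6 WT and 4/2 KO over NSN/SN, the
configuration of a small staged single-oocyte experiment.

All generators are pure functions of their spec (which includes the seed):
identical spec ⇒ byte-identical output.

## Numerical and design notes

* Boundary semantics follow the printed inequalities everywhere: screening
  thresholds (>10%, <40%, >3%, >4%), DM cut-offs (|Δ| > 25, q < 0.05,
  hyper-CGI > 75%, > 100 calls/kb) are strict; domain bands 0–25% / 75–100%
  and the DEG cut-offs (q ≤ 0.05, |log2FC| ≥ 0.5) are inclusive; the
  600,000-CpG and 4-million-read floors pass at the boundary.
* Degenerate 2×2 margins (e.g. both groups fully methylated): the exported
  `chi_square_2x2()` refuses them; inside the DMR machinery such tiles get
  chi2 = 0, p = 1, since no methylation difference is expressible.
* Identical constant groups in the t-test and in `global_methylation()`
  return p = 1 rather than erroring.
* BH is `stats::p.adjust(method = "BH")` throughout; untestable features
  never enter the family.
* Problem sizes used by the test-suite simulations (desk scale, chosen as
  the package's own test conditions): 1,200-tile genomes, 8–29 cells,
  2,000-protein/2,000-gene matrices, 20-replicate Monte-Carlo loops.

## Known limitations

* The surrogate DE test is not a negative-binomial model; with few cells
  and strong zero-inflation its p-values are approximate. Use a dedicated
  DE package and feed its results to `threshold_degs()` for real analyses.
* The contamination screen's bimodality thresholds are an
  operationalization; cells near the boundary of the histogram criteria
  deserve visual inspection.
* Region overlap uses point-in-interval containment on sorted CpG maps;
  regions are assumed non-pathological (valid, within chromosome bounds).
* `standardize_for_heatmap()`'s dataset mode divides by the variance by
  convention of the displays it reproduces; it is not a z-score.
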