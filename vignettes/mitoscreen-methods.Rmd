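---
title: "Methods: the overexpression screen and its validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the overexpression screen and its validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscreen)
```

# The problem

Spindle-assembly checkpoint (SAC) genes are candidate therapeutic targets
in hepatocellular carcinoma because chromosomally unstable tumors depend
on them. Nominating targets from public expression compendia poses two
statistical problems this package addresses: (i) overexpression in HCC is
*heterogeneous across patients*, so a gene can matter clinically while its
mean fold change over normal livers stays modest; and (ii) candidate
validation relies on small-replicate bench assays (qPCR, viability,
apoptosis, clonogenicity, xenografts) whose summary statistics and
threshold rules must be applied consistently.

# The screen

## Preprocessing

Input matrices are probe-level log2 intensities (linear input is
log2-transformed at read time; non-positive background-corrected
intensities become missing rather than being clamped, because fabricating
−∞ or a floor would distort downstream means). The pipeline order is
fixed: per-sample **median centering at probe level**, then **collapsing
to Entrez genes** by the arithmetic mean of each gene's probe values on
the log2 scale (the geometric mean of intensities). Median centering
before collapsing removes array-loading offsets before probes are
averaged; centering is a pure shift (no rescaling of spread), and it is
idempotent and invariant to per-sample constant offsets — both properties
are tested. Missing values are carried as explicit `NA` and excluded
pairwise from every mean, median and test, since genes are routinely
absent from individual platforms.

## The dual gate

For gene $g$ in one dataset, with reference level $r(g)$ the mean log2
expression over normal livers (median optional), each tumor sample $s$
receives a linear fold $2^{x_{gs} - r(g)}$ and an overexpression call when
that fold is at least $F = 2$. The *overexpression frequency* is the
fraction of evaluable tumors (non-missing values only) carrying the call,
and the gene passes in the dataset when the frequency is at least
$\Phi = 0.30$. Both thresholds are **inclusive**; boundary behavior is
pinned by tests.

A deliberate design choice: the fold threshold acts *per patient*, inside
the frequency, and marking gates on the frequency alone. The per-dataset
mean fold $2^{\bar{x}_{tumor} - \bar{x}_{ref}}$ is computed and reported
(it is the natural heat-map summary, and equals 1 exactly when the group
means agree), but it does not gate by default: with an overexpressed
subpopulation of 60% of tumors at $+1.5$ log2, the population mean fold is
$2^{0.9} \approx 1.87$ — below $F$ even though more than half the patients
individually exceed 2-fold. Gating on the mean would make the screen miss
precisely the heterogeneous targets it exists to find. Users who want the
stricter conjunction can set `gate = "fold_and_frequency"` in
`screenConfig()`.

## Aggregation across datasets

Genes missing from a platform must not veto a consensus, so the default
rule is `majority_present`: a gene is *markedly overexpressed* when it
passes in more than half of the datasets where it is measured.
`all_present` (pass everywhere measured) and `pooled` (per-sample calls
pooled over all tumors, each against its own dataset's reference, with the
pooled fold the tumor-count-weighted geometric mean) are available; the
choice is recorded inside the `ScreenResult` so flags are always
recomputable from the stored records.

Differential expression accompanying the gate uses the two-tailed
**pooled-variance Student's t** (not Welch) on log2 values, tumor versus
reference, unpaired by default with a paired variant where tumor/adjacent
pairing metadata exists. Raw p-values are reported; a Benjamini–Hochberg
adjusted matrix is exported alongside as a clearly separate convenience.

## Degenerate comparisons

Zero-variance and identical-group comparisons arise constantly in
noiseless synthetic data and would otherwise crash `t.test()`. The
pipeline-wide convention: when the pooled standard deviation is zero the
p-value is 1 if the group means agree and 0 otherwise; identical groups
give p = 1; both set a `zero_variance` flag that is carried into results
and never silently dropped.

# qPCR quantification

Relative levels assume perfect doubling per cycle (efficiency fixed at
2.0; no standard-curve correction): $\Delta C_t$ = mean target Ct − mean
β-actin Ct per observation, relative level $2^{-\Delta C_t}$, and the
fold between conditions $2^{-\Delta\Delta C_t}$ computed as the ratio of
mean relative levels. The standard deviation attached to a fold is that of
the per-observation condition-A ratios against the fixed mean of B,
matching the single "fold ± s.d." cell format of resistant-versus-parental
tables; the t test runs on $-\Delta C_t$ values, which are far closer to
normal than the ratios. Replicate spreads above 1.5 cycles trigger a QC
warning (not an error). Relative levels are invariant to plate-wide Ct
offsets, and fold(A,B)·fold(B,A) = 1 to near machine precision — both
tested.

The paired specimen survey calls a tumor/adjacent pair up-regulated at a
configurable fold threshold, default 2. Survey calls of this kind are
traditionally made by gel inspection, with no numeric rule a threshold
could be validated against; what the package pins down is the reporting
arithmetic (counts, and percentages rounded *half-up* to one decimal, so
46/53 prints 86.8) and the box statistics (median, quartiles, extremes of
$-\Delta C_t$ per group). Knockdown QC passes only *strictly below* 60%
remaining mRNA, and the proliferation-hit rule is strictly below 75%
viability — both strict readings are boundary-tested.

# Phenotype assays

Relative viability is the percent ratio of mean OD450 absorbances with a
t test on the raw absorbances. Apoptosis summaries are means ± sd of
annexin-positive percentages over independent experiments. Colony counts
are compared directly; the ≥50-cells-per-colony size rule is upstream
metadata recorded in the output. Xenograft volumes use the caliper
ellipsoid $\pi/6 \times \text{major} \times \text{minor}^2$ (mm³, days as
integers from inoculation), compared per aligned measurement day with an
endpoint summary and optional tumor-weight comparison. No IC50 curves are
fit anywhere: dose–response data are summarized per concentration.

# What the generators emulate

The expression generator draws gene baselines $\mu_g \sim N(8, 1)$ log2,
adds per-sample loading offsets $N(0, 0.5)$ and measurement noise
$N(0, 0.5)$ (normal on the log2 scale, i.e. multiplicative intensity
noise, the standard microarray convention), assigns 1–3 probes per gene,
spikes 10 of 500 genes by $+1.5$ log2 in each tumor independently with
probability 0.6 (heterogeneity across patients is what makes the frequency
gate meaningful, and carriers are drawn independently per dataset), and
omits 5% of genes per dataset. The default collection is 3 datasets of 60
tumors and 20 normal livers. These defaults are the regime the screen is
validated under: across 10 replicate collections the default gate recovers
on average at least 9 of 10 spiked genes with at most 5 false positives
(observed: 10/10 and 0 across seeds 0–9), and a brute-force per-sample
double loop reproduces fold, frequency and flags exactly on small
instances.

The qPCR generator places the reference at Ct 16 and the target 8 cycles
above it, shifting condition A by $-\log_2(\text{fold})$; with triplicate
Ct noise sd 0.1 and 3 observations per condition, folds of 0.36, 1.0,
4.40 and 7.12 (down-, no- and up-regulation regimes) are re-estimated with
absolute log2 bias below 0.3 over 20 replicate experiments. The cohort
generator draws up-regulated pairs with folds uniform in [2.5, 16] and
background pairs in [0.7, 1.4] at Ct noise sd 0.05 — margins chosen once
so that the generated call counts are sharp at the 2-fold threshold and a
53-pair cohort with 46 up-regulated pairs surveys to exactly 86.8%. The
assay generator draws OD450, fractions, counts and two-arm caliper series
(volume noise lognormal, converted to axes at a fixed 1.5 aspect ratio so
the ellipsoid formula recovers the intended volumes exactly).

All generators are deterministic: identical configuration including the
seed yields byte-identical written output. What they do **not** emulate:
platform-specific probe affinities, batch structure, correlated gene
modules, copy-number-driven expression, amplification-efficiency drift, or
gel-based semi-quantitative readouts. Passing tests therefore demonstrate
the pipeline's arithmetic and decision rules under a realistic noise
regime, not performance on any particular public dataset; the GEO loader
exists for users to bring real series-matrix files, and leaves group
annotation to them because sample roles are not encoded uniformly in those
files.

# Problem sizes and runtime choices

Validation runs use 3 datasets × 500 genes × 80 samples per collection
(10 replicate collections), 20 replicate qPCR experiments per fold regime,
and 10 replicate assay tables — sizes at which every documented property
is measurable with comfortable margins while the full suite runs in well
under a minute of compute.

# Known limitations

- The screen's cross-dataset consensus treats datasets symmetrically;
  there is no weighting by cohort size under `all_present`/
  `majority_present` (only `pooled` weights by tumor counts).
- Frequency denominators are tumors with non-missing values; a gene
  measured in very few tumors of a dataset can pass on thin evidence
  (the per-dataset `n_tumor` is reported so users can filter).
- Single-reference-gene qPCR normalization only; no multi-gene reference
  or efficiency calibration.
- The specimen-survey call threshold is a numeric stand-in for an
  inherently qualitative gel-inspection readout.
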