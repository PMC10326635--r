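---
title: "Screening for metastasis-associated lncRNAs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for metastasis-associated lncRNAs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical models behind `lncscreen`, the
parameters that matter, what the synthetic cohort generator does and does
not emulate, and the design decisions taken where the screening procedure
admits more than one reading.

## The differential expression engine

All two-group comparisons share one engine. Counts for gene *i* in sample
*j* are modeled as negative binomial,

$$K_{ij} \sim \mathrm{NB}\!\left(\mu_{ij} = s_j\, q_{i,g(j)},\ \alpha_i\right),
\qquad \mathrm{Var}(K_{ij}) = \mu_{ij} + \alpha_i \mu_{ij}^2,$$

with median-of-ratios size factors $s_j$ (the median over genes with a
positive geometric mean of $K_{ij}$ divided by that geometric mean) and a
group mean $q$ per comparison arm, fitted by Newton iteration on the
score equation of the log-link GLM. The Wald statistic is
$\log_2(q_B/q_A)$ divided by its standard error from the observed Fisher
information, with a two-sided normal reference; BH adjustment runs over
all tested genes, excluding genes with zero counts in every sample of the
comparison (reported `NA`).

Numerical choices worth knowing:

* **Dispersion** is per-gene method of moments on normalized counts:
  pooled within-group variance $v_i$ gives
  $\hat\alpha_i = (v_i - \bar q_i\,\overline{1/s})/\bar q_i^2$, floored at
  $10^{-8}$ (a constant gene therefore gets the floor). At the cohort
  sizes the screen works with (7–20 samples per arm) this estimator is
  noisy, so `estimate_dispersion(shrink = TRUE)` optionally moderates
  $\log\hat\alpha$ toward a lowess trend on $\log$ mean, weighting the
  per-gene estimate by its residual degrees of freedom against
  `prior_df = 10` pseudo-observations. The exported default is the raw
  estimator; the screen's internal DE calls use the moderated one, which
  is what every mature NB engine does, and which removes the heavy upper
  tail of $\hat\alpha$ that otherwise costs sensitivity on individual
  genes.
* **Calibration.** With estimated dispersion and a normal reference, the
  Wald test at 10 vs 10 runs slightly hot (the effective reference is
  close to a t with ~18 df), around 0.055–0.065 observed size at nominal
  0.05 on null NB data. This is the familiar behavior of plug-in NB Wald
  tests and is asserted as such in the tests (band 0.03–0.07).
* **Zero groups.** A group with zero total counts would have an infinite
  fold change; the fitted mean is replaced by half a read over the
  group's total depth, keeping statistics finite while remaining strongly
  significant when the other arm is expressed.
* **Equivariance.** Multiplying one sample's counts by *c* multiplies its
  size factor by *c* exactly. Test results are invariant only up to that
  sample's shot noise — scaled counts genuinely carry more information —
  which is why the tests assert approximate, not exact, invariance.
* **VST** is $\log_2(K_{ij}/s_j + c)$ with pseudocount $c = 4$, which
  meets the variance-decoupling contract (|slope| of per-gene SD on mean
  below 0.1 for means above 20) on NB data with realistic dispersion. It
  feeds PCA and clustering only, so a closed-form transform is preferred
  over a fitted one.

## The four-stage screen

Stage 1 tests metastases against primaries over lncRNA genes only
(positive fold change = up in metastasis) and keeps genes with
padj strictly below 0.15 — a deliberately permissive net whose errors the
later stages absorb. Size factors are computed once from all genes of the
compared samples, then the lncRNA subset is tested.

Stage 2 runs three control comparisons, each oriented
control-minus-reference: (a) each non-prostate normal tissue vs all
primaries, (b) all non-prostate normals vs all primaries, (c) all
non-prostate normals vs BPH. The keep/drop rule is stated in prose in the
screening design this package implements, and two readings are possible;
we formalize it as: *drop a survivor with metastasis direction $d$ iff
some control comparison has padj < 0.01 and a fold change of sign $d$.*
The rationale: a control tissue elevated (or depressed) in the same
direction as the metastasis signal could explain that signal by tissue of
origin; a control deviating in the opposite direction cannot. The
inverted reading is available via
`screen_config(stage2_rule = "opposite-sign-drop")`. Control comparisons
are computed over the full lncRNA universe (the same BH denominator as
stage 1) and the rule is then applied to survivors; each drop records the
filter, tissue, fold change and padj. Filters are skipped with a warning
when their control samples are absent.

Stage 3 computes, per patient with paired samples, the sign of mean
normalized metastasis expression minus (mean) primary expression —
normalized counts, not VST, so direction semantics match stage 1 — and
removes genes opposite to their discovery direction in more than two
patients. Exact zero differences count as consistent, since only
"opposite" directions are disqualifying. For a patient with two primaries
the primary mean is used.

Stage 4 never silently drops anything: candidates with a same-strand
overlap of at least one base pair (half-open semantics throughout) with a
protein-coding gene or pseudogene are flagged `needs_curation` and kept on
a worklist, because the judgment of whether a lncRNA's signal is really
read-through from its neighbor needs a genome browser and a human. A
decision file (`gene_id`, `decision` ∈ keep/drop) can be applied to make
a curated run reproducible.

Every stage returns the surviving set plus one machine-readable reason per
dropped gene; `run_screen()` asserts the funnel is monotone and the audit
partitions the input.

## Regulatory windows and TF enrichment

Windows span 5 kb upstream to 2 kb downstream of the TSS *in
transcription direction*: $[\mathrm{tss}-5000, \mathrm{tss}+2000)$ on the
plus strand and the mirrored $[\mathrm{tss}-2000+1, \mathrm{tss}+5000+1)$
on the minus strand, clipped at zero. The unstranded reading
(`stranded = FALSE`) exists for comparison with naive implementations.
Overlap counting (≥ 1 bp, half-open) delegates to
GenomicRanges/IRanges; the test suite holds it to a quadratic all-pairs
oracle, including single-base and abutment cases.

Enrichment per TF is the one-tailed (greater) hypergeometric tail on the
2×2 table of *has ≥ 1 site* against *candidate vs background-minus-
candidate*, where the background is **all lncRNAs in the annotation**, not
all genes — lncRNA promoters are not a random sample of promoters, and
the question is whether candidates differ from their own class. Multiple
peaks in one window collapse to a binary indicator for the table (the
per-window counts remain available in the binding matrix). BH is applied
across the tested TFs with an enrichment call at padj < 0.15. Depletion
is deliberately not tested. Because the exact test is discrete, its null
p-values are sub-uniform; under no planted enrichment the fraction of TFs
below $\alpha$ is *at most* about $\alpha$, which is how the calibration
test is phrased.

## Survival analysis

Expression is dichotomized at the third quartile (type-7 linear
interpolation), with "high" meaning *strictly above* Q3 so that the high
group is the extreme quartile; ties with Q3 fall to "low". Covariates are
categorized at the published boundaries: age ≤ 62 vs > 62 (62 itself is
low), PSA ≤ 10 / [10, 20) / ≥ 20 ng/mL (20.0 exactly is high), Gleason
< 7 / = 7 / > 7, and pT coded as an opaque ordinal with a configurable
split (default: 5 and above is high). Kaplan–Meier, log-rank, Cox and the
proportional-hazards test delegate to the `survival` package; the Cox
model uses Breslow tie handling (the simplest defensible default, stated
so results are reproducible) and stratum-specific baseline hazards per
Gleason category — Gleason violates proportional hazards in cohorts of
this kind, so it enters as a stratum, never as a covariate. Constant
covariates are dropped with a warning rather than producing a singular
fit. The PH check uses scaled Schoenfeld residuals (Grambsch–Therneau,
KM time transform) and refuses to report with fewer than five events.

## The synthetic cohort generator

`simulation_config()` defaults describe the study conditions the screen
is validated under, emulating a multi-site autopsy cohort: 25 patients of
whom six contributed primaries (one of them two primaries), three
metastases per patient with sites drawn at realistic frequencies (lymph
node most common, then bone, liver, adrenal, subdural), twelve normal
samples per non-prostate site, twelve BPH samples, and 2,500 genes of
which 80% are lncRNAs. Counts follow
$K \sim \mathrm{NB}(\exp(\beta_0 + (\beta_\mathrm{pat} + \beta_\mathrm{status} + \beta_\mathrm{site})\ln 2),\ \alpha = 0.15)$
with baseline $\beta_0 \sim U(2.3, 6.9)$ (mean counts roughly 10–1,000)
— all configured effect sizes are in log2 units:

* **Patient effects** are N(0, `patient_effect_sd` = 1) draws shared by
  all of a patient's samples *per block of genes* (50 blocks). A single
  per-patient scalar across all genes would be absorbed by size factors;
  the block structure is the simplest mechanism that makes expression
  cluster by patient, as multi-site tumor cohorts do, while staying
  invisible to normalization.
* **Planted metastasis genes** (20, of which 80% up) shift by ±3 log2 in
  every metastasis sample — the signal the screen must recover.
* **Tissue-specific confounders** (6 per site) shift by +7 log2 in *both*
  a site's normal tissue and the metastases seeded there. This is
  deliberately the confound that stage 1 cannot remove and stage 2 must:
  contamination by surrounding normal tissue elevates the gene in that
  site's metastases. The magnitude reflects that tissue-restricted
  lncRNAs are near-binary across tissues (orders of magnitude, not
  two-fold).
* **Site markers** (40 per site) shift by +7 log2 in a site's normal
  samples only. They carry no metastasis signal but give the stage-2
  control comparisons the hundreds of genuinely tissue-specific genes
  real tissues differ by, which sets a realistic BH ranking in those
  comparisons.
* **Gene models** are laid along one synthetic chromosome with random
  strands; a configurable 10% of lncRNAs get a masking coding/pseudogene
  relocated inside them on the same strand. The overlap truth is computed
  from the final geometry, so it is exact even where relocation creates
  incidental overlaps.
* **Peaks**: for each TF, a 150–400 bp peak falls into each lncRNA's
  regulatory window with probability 0.15, raised to 0.8 at planted genes
  for the designated enriched TFs (defaults: two enriched among twenty).
* **Survival cohorts** use exponential event times with the hazard
  multiplied by `hr_expression` in the high-expression group and
  per-subject exponential censoring calibrated so each subject is
  censored with probability `censor_rate`; clinical covariates are drawn
  from fixed distributions (mean age 62, log-normal PSA, Gleason 6–9, pT
  2–6) and deliberately carry no hazard effect, so planted-HR recovery is
  unconfounded.

Every generator restores the caller's RNG state and is bit-reproducible
from `seed`; the generators derive independent streams from fixed offsets
of it.

**What this does not emulate** — and therefore what passing tests do not
show about real data: isoform structure (one transcript length per gene),
read-level artifacts (mapping, GC, batch), correlated gene–gene networks
beyond the shared patient blocks, partial contamination gradients (site
effects are all-or-nothing), non-exponential hazards, and covariate–
expression correlation in the survival cohort. The screen's behavior on
those axes must be judged on real cohorts.

## Problem sizes in the tests

The acceptance suite validates at the cohort scale above (2,000 lncRNAs,
~150 samples, one full screen in a few seconds), runs the exhaustive
Fisher oracle over all 2×2 tables with N ≤ 60, a thousand random overlap
fixtures, a hundred Cox replicates at n = 1,000, and twenty randomized
screen configurations at reduced size (300–500 genes, 8 patients); unit
tests use smaller fixtures chosen so each check isolates one property.

## Known limitations

* The stage-2 rule is an interpretation of a prose description; both
  readings are implemented, but only the default is validated against
  planted truth.
* The Wald test treats samples as independent; with strong patient
  effects its stage-1 error control is approximate (the pairwise stage
  exists precisely to absorb this).
* Dispersion moderation uses a lowess trend, not a parametric
  mean-dispersion curve; at fewer than ~50 genes the trend falls back to
  the median.
* TPM percentile summaries rank mean TPM across samples; they do not
  model within-cohort expression heterogeneity of the TFs.
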