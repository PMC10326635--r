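# lncscreen

Multi-stage screening for long noncoding RNAs (lncRNAs) aberrantly
expressed in prostate cancer metastases, with transcription-factor
regulatory-region enrichment and prognostic survival analysis.

## The problem

Metastatic castration-resistant prostate cancer (mCRPC) is the lethal
stage of the disease, and lncRNAs — highly tissue- and cancer-specific
transcripts — are candidate drivers and biomarkers of progression. Bulk
RNA-seq of autopsy cohorts (multiple metastases plus the corresponding
primary tumor per patient) can reveal metastasis-specific lncRNAs, but the
analysis is dominated by two confounds:

1. **Patient-to-patient variability.** Expression clusters by patient, not
   by primary/metastasis status, so naive differential expression mixes
   genomic background with metastasis biology.
2. **Tissue of origin.** A lncRNA "upregulated in liver metastases" may
   simply be a liver-specific transcript picked up from the surrounding
   normal tissue.

`lncscreen` implements a four-stage screen that addresses both, plus the
downstream analyses that characterize the resulting candidates, and a
synthetic cohort generator with planted ground truth for validating the
whole pipeline. It is intended for computational biologists analyzing
multi-site tumor cohorts, and as a tested reference implementation of this
screening design.

## The method

**Differential expression engine.** Two-group comparisons use a per-gene
negative-binomial model with log link and median-of-ratios size factors
s_j: counts K_ij ~ NB(mean = s_j q_ig, dispersion alpha_i) with
Var = mu + alpha mu^2. Dispersion is estimated per gene by method of
moments on normalized counts (optionally moderated toward a mean-dispersion
trend), the group log-fold-change log2(q_iB / q_iA) is tested with a Wald
statistic, and Benjamini–Hochberg adjustment is applied over tested genes
(all-zero genes are reported NA and excluded from m).

**The screen** (`run_screen()`):

1. *Discovery*: metastases vs primaries over lncRNA genes, keep padj < 0.15
   (a deliberately relaxed first net).
2. *Tissue-specific control filters* at padj < 0.01: (a) each non-prostate
   normal tissue vs all primaries; (b) all non-prostate normals vs all
   primaries; (c) all non-prostate normals vs BPH (benign prostatic
   hyperplasia, the normal-prostate control). A candidate with metastasis
   direction d is dropped when a control comparison deviates significantly
   in the same direction d — i.e. when tissue of origin could explain its
   signal.
3. *Pairwise patient consistency*: per patient with paired samples, the
   sign of (mean metastasis expression − primary expression); genes
   opposite to their discovery direction in more than two patients are
   removed.
4. *Overlap flagging*: candidates overlapping a protein-coding gene or
   pseudogene on the same strand (≥ 1 bp, half-open intervals) are flagged
   `needs_curation` for review in a genome browser; an optional decision
   file resolves the worklist.

Every stage emits an audit report (survivors plus a machine-readable drop
reason per gene), and the funnel is monotone by construction.

**TF regulation** (`fisher_enrichment()` and friends): regulatory windows
of −5 kb/+2 kb around each TSS (strand-aware), per-TF peak overlap counts,
and a one-tailed Fisher/hypergeometric enrichment of binding in candidate
windows against the all-lncRNA background (BH over TFs, enriched at
padj < 0.15), plus tumor/normal AR-binding-site summaries and TPM-based TF
expression percentiles.

**Survival** (`cox_stratified()` and friends): expression dichotomized at
the third quartile (strictly above Q3 = "high"), Kaplan–Meier with
log-rank, and a Cox model for the expression group adjusted for PSA, age
and pT categories with Gleason-stratified baseline hazards (Breslow ties),
plus a Grambsch–Therneau proportional-hazards check.

## Worked example

```r
library(lncscreen)

cfg <- simulation_config(seed = 7L)   # paper-scale synthetic cohort
coh <- simulate_cohort_counts(cfg)    # counts, samples, models, truth
res <- run_screen(coh$counts, coh$samples, coh$models)
print(res)
#> Metastasis lncRNA screen
#>   lncRNAs tested : 2000
#>   stage 1 (DE)   : 37
#>   stage 2 (tissue): 22
#>   stage 3 (pairwise): 22
#>   stage 4 (overlap): 22
#>   final candidates: 22 (18 up, 4 down; 2 need curation)

planted <- coh$truth$planted_met_genes$gene_id
mean(planted %in% res$candidates$gene_id)
#> [1] 1
```

The cohort plants 20 metastasis-specific lncRNAs (|log2 FC| = 3) and 30
tissue-specific confounders among 2,000 lncRNAs; here the screen recovers
all 20 planted genes, and the funnel shows stage 2 removing the
tissue-driven discoveries (37 → 22).

TF enrichment against the all-lncRNA background recovers the two planted
TFs and nothing else among 20:

```r
peaks <- simulate_peaks(cfg, coh$models, coh$truth)
lnc   <- coh$models[coh$models$biotype == "lncRNA", ]
bm    <- binding_matrix(regulatory_regions(lnc), peaks)
head(fisher_enrichment(bm, res$candidates$gene_id), 2)
#>   tf_name  a b   c    d odds_ratio p_adjusted enriched
#> 1   FOXA1 18 4 287 1691      26.51   1.04e-10     TRUE
#> 2  HOXB13 16 6 282 1696      16.04   1.31e-08     TRUE
```

Prognostic evaluation on a simulated prostatectomy cohort (n = 81, true
hazard ratio 2 for the high-expression group):

```r
surv <- simulate_survival_cohort(n = 81, hr_expression = 2,
                                 censor_rate = 0.3, seed = 7L)
km_logrank(surv$time, surv$event, surv$expr_group)$p
#> [1] 0.0124
cox_stratified(surv, surv$expr_group)$table[2, ]
#>     variable level    hr ci_low ci_high      p reference
#> 2 expression  high 2.179  1.127    4.21 0.0206     FALSE
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/lncscreen-cli.R` with `simulate`, `screen`, `tfea` and
`survival` subcommands.

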