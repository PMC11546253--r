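# umivar

Benchmarking somatic SNV detection in cell-free DNA (cfDNA) from deep
targeted sequencing with unique molecular identifiers (UMIs).

## The problem

Circulating tumor DNA carries tumor mutations at allele fractions that are
often far below the raw sequencing error rate (errors run as high as ~1% per
base; clinically relevant variant allele frequencies reach down to 1e-5).
Detecting them requires the whole chain to work together: UMI consensus
collapsing to suppress replicate-level errors, a calling statistic that
separates real variants from the residual error floor, matched-normal (PBMC)
filtering to remove germline SNPs and clonal hematopoiesis (CHIP), and a
panel of normals (PON) to mask recurrent position-specific artifacts.
Evaluating choices along this chain on clinical data is hard because such
data cannot be shared. `umivar` provides the full evaluation framework over
a seeded synthetic cohort generator with the statistical structure of a
UMI-based liquid-biopsy study, so every processing choice can be exercised,
measured, and reproduced.

It is aimed at bioinformaticians building or tuning cfDNA variant-calling
pipelines, and at methodologists who want a controlled testbed for
low-frequency calling statistics.

## What is inside

* **Cohort simulator** (`simulate_cohort()`): case plasma, matched PBMC at
  WES-like (~78X) and deep collapsed (Thousands X) depths, control plasma,
  and a PON; tumor variants over a VAF grid, CHIP variants shared between
  plasma and PBMC, germline SNPs from a population pool, single-strand
  damage that survives consensus, UMI-tag errors, PCR family-size
  variation, and 1%-level error hotspots. Output either as collapsed
  consensus pileups (evaluation scale) or as full read-family tables
  (UMI-processing studies).
* **UMI processing** (`group_umis()`, `call_consensus()`,
  `umi_collapse()`): the five grouping strategies (unique, percentile,
  cluster, adjacency, directional) over Hamming-distance-1 tag networks,
  quality-sum consensus with a minimum family-size filter, and retained-data
  accounting.
* **Calling statistics** (`call_variants()`): a strand-aware beta-binomial
  Bayes factor against pooled PON counts with two strand models
  (`shearwater_and`/`shearwater_or`; posterior = BF/(1+BF)), a one-sided
  Fisher exact tumor-normal test (`fisher`), a TLOD-style likelihood ratio
  (`tlod`), and a read-feature error-model likelihood-ratio p-value
  (`dreams`).
* **Filtering** (`filter_by_pbmc()`, `filter_by_pon_recurrence()`): the
  WES-PBMC rule (coverage < 10 or VAF > 10% removed), the deep-PBMC rule
  (coverage < 1000 or VAF > 0.1% removed), and the PON recurrent-mismatch
  mask (VAF > 1% in more than one PON sample).
* **Evaluation** (`pr_curve()`, `stratify_by_vaf()`, `roc_curve()`,
  `classify_cohort()`, `bin_by_depth()`, `downsample_to_mean_depth()`):
  mutation-level precision-recall with VAF strata, tumor-informed and
  tumor-agnostic sample classification (combined statistics, highest-ranking
  variant, FPR-calibrated call counts and mean VAF), and depth-confounder
  diagnostics.

The core per-variant quantity is the beta-binomial marginal likelihood

    P(k | n, alpha, beta) = C(n,k) B(k + alpha, n - k + beta) / B(alpha, beta)

with strand-s pseudo-counts `alpha = K_s + 1`, `beta = N_s - K_s + 1` taken
from pooled PON counts; the Bayes factor compares this error-only null
against a flat-prior variant model, jointly over strands (AND) or per strand
(OR). Smaller Bayes factors favour the variant.

## Worked example

```r
library(umivar)

cohort <- simulate_cohort(cohort_config(), seed = 101)
cohort
#> umivar synthetic cohort: 90 samples, 2000 panel sites, level = counts
#>   truth variants: 370 ( 200 tumor / 50 CHIP / 120 germline )

bm <- benchmark_mutations(cohort, regime = "deep")
round(sapply(bm, function(x) x$pr$auc), 3)
#> shearwater_and  shearwater_or         fisher           tlod         dreams
#>          0.883          0.884          0.884          0.881          0.885

cls <- classify_cohort(cohort, "shearwater_and", pairing_seed = 11)
cls$informed$roc$combined$auc
#> [1] 1

lab <- bm$shearwater_and$labeled
truth <- cohort$truth[origin == "tumor",
                      .(sample = paste0(patient, "_plasma"), site, alt, vaf)]
st <- stratify_by_vaf(lab, lab$quality, stratum_by = "target",
                      truth = truth, positives = "all")
round(sapply(st, function(s) if (is.null(s)) NA else s$auc), 3)
#>     (0,0.0001] (0.0001,0.001]   (0.001,0.01]       (0.01,1]
#>          0.000          0.185          0.920          1.000
```

Reading the numbers: pooled over 20 case plasma samples, all five statistics
reach a PR-AUC near 0.88 after deep-PBMC filtering and PON masking; the
tumor-informed combined statistic separates cases from donor-paired controls
perfectly at this tumor load; and retrieval is a step function of allele
frequency — variants below VAF 1e-4 are unrecoverable at 2,000X collapsed
depth, variants above 1% are retrieved essentially perfectly.

## Vignette

`vignettes/umivar-methods.Rmd` documents the generative model, the four
calling statistics and their strand models, the filtering rules, the
numerical conventions (tie handling, quantile estimator, quality caps), and
the known limitations of the synthetic cohort as a stand-in for clinical
data.
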