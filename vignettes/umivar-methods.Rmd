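---
title: "umivar: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{umivar: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`umivar` is an evaluation framework for low-frequency somatic SNV detection
in UMI-tagged deep targeted cfDNA sequencing. This vignette is the package's
account of its science: the generative model behind the synthetic cohorts,
the four calling statistics, the filtering and benchmarking conventions, the
numerical choices, and what the framework can and cannot say about real
clinical data.

## 1. The generative model

### Panel and samples

A *panel* is an ordered list of sites, each with a contig, a 0-based
position and an assigned reference base. The working default
(`panel_preset("desk")`) is 2,000 bp on one contig; a
`panel_preset("paper")` geometry (15,396 bp over 12 gene contigs) mirrors
the scale of a clinical colorectal-cancer capture design. Reference bases
are arbitrary but deterministic: the panel is a coordinate system, not a
genome; sequence context beyond the assigned bases is a non-goal.

A cohort (`cohort_config()`, `simulate_cohort()`) contains, per case
patient, a plasma sample, a WES-like PBMC sample (~78X, no UMIs) and a deep
UMI-collapsed PBMC sample; per control donor, plasma and deep PBMC; plus a
panel of normals (PON). Defaults: 20 cases, 10 controls, 10 PON donors,
2,000X collapsed plasma depth, 3,000X deep PBMC, 2,000X PON.

### Variant composition

* **Tumor mutations** (default 10 per case) are private to a case's plasma,
  with plasma VAFs drawn log-uniformly on `[1e-5, 0.1]` so that each decade
  of the benchmark's VAF stratification receives comparable truth mass.
* **CHIP variants** (2 per case, 1 per control; VAF uniform on
  `[0.005, 0.03]`) are clonal-hematopoiesis stand-ins: present in both the
  patient's plasma and PBMC compartments at the same fraction. The VAF range
  is chosen to sit above the deep-PBMC filter threshold (0.1%) but below the
  WES filter threshold (10%), which is exactly the regime where deep normal
  sequencing pays off.
* **Germline SNPs** (3 per person from a shared pool of 8 population sites;
  VAF 0.5 or 1 with heterozygous:homozygous odds of 3:1) are carried by
  cases, controls and PON donors alike.
* **Error hotspots**: the default profile places two positions with a 1%
  per-molecule mismatch rate toward a fixed alternative — the recurrent
  position-specific artifact class that position-blind callers cannot see.
  Hotspot positions are excluded from variant placement so artifacts and
  true variants stay distinguishable by construction.

### Error processes

Three error processes are separated because UMI consensus treats them
differently:

* `seq_error` (default 1e-3, a Q30-like raw read error) applies
  independently per sequenced read and base; consensus voting suppresses it.
* `pre_umi_damage` (default 1e-5 per molecule-site) models single-strand
  chemical damage acquired *before* UMI ligation; every replicate of the
  molecule inherits it, so no amount of consensus removes it. This is the
  post-collapsing error floor.
* `umi_error` (default 1e-3 per tag base) substitutes bases inside the
  observed UMI tag of each read, fragmenting read families under
  exact-match grouping.

### Two output levels

`simulate_cohort(level = "reads")` emits full read-family tables: fragments
placed uniformly (clipped at panel edges so expected coverage is flat),
negative-binomial replicate counts truncated at 1 (mean 4, dispersion 2 by
default; no distribution is prescribed by the underlying study design, and
the truncated negative binomial is the standard overdispersed choice for PCR
family sizes), per-read sequencing and tag errors.

`simulate_cohort(level = "counts")` draws collapsed consensus pileup counts
directly: per site and strand, depth is Poisson around the role mean and
each molecule carries a given alternative with probability equal to the
applicable truth VAF plus the per-molecule error rate. For consensus
samples that rate is `pre_umi_damage` plus an analytic residual,
`consensus_error_rate()`, obtained by exact enumeration of quality-sum
voting outcomes under the family-size distribution conditioned on the
minimum-family filter. The two levels are therefore the same model at two
resolutions, and the enumeration is cross-checked against Monte-Carlo
voting in the test suite. Count-level generation is what makes
2 kb x 2,000X x 90-sample studies run in seconds; read-level generation is
used where the UMI machinery itself is under study.

A parity effect is worth knowing: at even family sizes a split vote is a
tie, which yields an `N` (dropped) rather than a miscall, so even sizes are
uniformly safer than neighbouring odd sizes; the consensus error decreases
monotonically within each parity class.

Every sample consumes an RNG stream derived from `(master seed, sample id)`
(`derive_seed()`), so cohorts are reproducible under any generation order.

## 2. UMI grouping and consensus

Grouping operates per (fragment start, strand) locus on observed tag counts,
with five strategies: `unique` (exact tags), `percentile` (exact tags,
discarding tags below 1% of the mean tag count — the conventional threshold;
none is prescribed elsewhere), `cluster` (connected components of the
Hamming-distance-1 graph), `adjacency` (greedy claiming of distance-1
neighbours by descending count), and `directional` (edges `A -> B` when
`count(A) >= 2 count(B) - 1`, followed transitively). Hamming distance is
the appropriate metric for fixed-length tags. Seeding ties break on the
lexicographically smallest tag, making partitions deterministic; `unique`,
`adjacency` and `directional` all refine the `cluster` components.

Consensus calling (`call_consensus()`) is a per-site quality-sum vote: the
winning base's quality is the winner-minus-runner-up quality margin, capped
at 93; exact ties give `N` with quality 0, and `N` is excluded from pileups.
This is a deliberate simplification of full per-base posterior consensus
models: the evaluation depends on family-size filtering and error
suppression, not on the exact consensus quality calculus. Groups below
`min_reads` (default 3) are dropped; `retained_fraction()` accounts for the
discarded reads.

## 3. Calling statistics

All statistics are computed for every (site, alternative) with at least one
supporting consensus read; informed variant lists are evaluated even at zero
support, taking the caller's null value (p = 1, the k = 0 Bayes factor,
TLOD 0).

**Beta-binomial Bayes factor** (`shearwater_and` / `shearwater_or`). The
error-only null models the strand-s alt count as beta-binomial with
pseudo-counts `K_s + 1`, `N_s - K_s + 1` from pooled PON counts (the tested
sample is never in its own pool; `pon_pool(exclude=)` provides
leave-one-out). Conjugate pooling replaces maximum-likelihood dispersion
estimation — a documented simplification that keeps the model closed-form.
The variant model places a flat Beta(1,1) prior on the variant fraction:
*AND* shares one fraction across strands (closed form
`C(nf,kf) C(nr,kr) B(kf+kr+1, nf+nr-kf-kr+1)`), *OR* multiplies independent
per-strand Bayes factors. Smaller BF favours the variant;
`bf_to_posterior()` maps BF to the null posterior under a 0.5 prior. At low
counts the OR mode is uniformly more conservative than AND — the
higher-precision / lower-sensitivity strand-requiring mode — while the
shared-fraction AND marginal rewards strand-balanced signals. (A fully
strand-biased split can receive a slightly smaller OR factor than a balanced
one at high counts against a pristine PON, a direct consequence of the
log-convexity of the null marginal in k; the test suite pins the
oracle-verified behaviour.)

**Fisher exact** (`fisher`). One-sided hypergeometric tail for alt
enrichment in tumor over the matched normal, strands pooled; candidates
without a usable table get p = 1, the convention for calls missing from a
caller's output. In the mutation benchmark the matched normal is the PBMC
sample of the active regime (WES PBMC in the `wes` arm, deep PBMC in the
`deep` arm): the regime defines which normal data the analysis owns.

**TLOD-style score** (`tlod`). `log10 L(f_hat)/L(0)` with per-read alt
probability `f(1-e) + (1-f)e/3` and `f_hat` the closed-form ML fraction on
`[0, 1]`. The default `e` is the pooled PON mismatch rate (excluding
likely-variant cells, see below). This is a deliberately simplified
stand-in for haplotype-caller log-odds scores; assembly, orientation and
contamination models are out of scope.

**Read-feature error-model p-value** (`dreams`). A logistic error model
(`fit_error_model()`) is trained on control observations — mismatch
indicator against whatever feature columns are supplied, with count
weights — and each candidate is tested by a likelihood-ratio for a shared
variant fraction against per-observation error probabilities, with the
chi-square reference halved for the boundary null. At collapsed-count
resolution only coarse features are statistically identifiable (the default
is the alternative base; trinucleotide context and strand can be requested),
so the model is a linear, count-level stand-in for richer read-level error
learners. Its defining property is preserved: it cannot represent
*position-specific* error rates, so 1%-hotspots are flagged as variants
until the PON recurrence mask removes them.

PON error training (`pon_error_observations()`, and the TLOD error rate)
excludes cells whose pooled VAF exceeds 1%: those are germline polymorphisms
carried by the normal donors (or gross artifacts), not sequencing errors.
Without this exclusion a handful of 50%-VAF SNP sites would dominate the
estimated error rate.

## 4. Filtering

`filter_by_pbmc()` implements both depth regimes with strict inequalities,
exactly as worded: WES-PBMC removes candidates with PBMC coverage below 10
or PBMC VAF above 10%; deep-PBMC removes coverage below 1,000 or VAF above
0.1%. A site absent from the PBMC pileup counts as coverage 0 and is
removed, with the fired rule logged. `filter_by_pon_recurrence()` masks a
(site, alternative) observed above 1% VAF in more than one PON sample;
masking per allele (rather than per site) avoids erasing true variants that
happen to sit at error-prone positions, and per-site masking is available
via `per_allele = FALSE`. Filters are order-independent by construction.

## 5. Benchmarking conventions

**Labelling**: a candidate is a true positive when its (sample, site, alt)
triple matches the sample's tumor truth; CHIP, germline leak-through, error
calls and every control-sample call are false positives.

**PR curves** (`pr_curve()`) sweep distinct quality values (ties enter
together, so curves are deterministic) and integrate step-wise,
`sum(precision * delta recall)` — the average-precision convention, which
the brute-force enumeration oracle in the tests reproduces exactly. The
recall denominator defaults to truth variants with at least one alt read in
their own plasma (detectable in principle), counted before filtering;
passing `positives` overrides this with the full truth count.

**VAF strata** use the four canonical half-open intervals `(0,1e-4]`,
`(1e-4,1e-3]`, `(1e-3,1e-2]`, `(1e-2,1]`. True positives occupy exactly one
stratum; false positives are shared across strata by default (an error call
competes with true variants of every frequency), with per-stratum matching
available. At 2,000X collapsed depth one alt read already means a measured
VAF of 5e-4, so the lowest measured-VAF stratum is structurally empty; the
stratifier therefore also supports strata on the *target* (injected) VAF
with all-truth denominators, which is what the package's own acceptance
checks use for the sub-1e-4 statement.

**Sample classification** (`classify_cohort()`): tumor-informed scores are
the combined statistic of the informed list (mean TLOD; product of Bayes
factors accumulated in log space; Fisher's method for p-values, reported as
`-log10` of the combined p) and the highest-ranking informed variant
(`-log10` of the minimum p or posterior, maximum TLOD). Controls borrow
donor truth lists — each control is paired with `multiplicity` distinct
random case donors (37 controls at multiplicity 3 give the canonical 111
control points). Tumor-agnostic scores are the number of calls above a
pooled FPR cutoff, their mean VAF, and the highest-ranking candidate. The
FPR cutoff ranks pooled false positives by quality and takes rank
`max(1, round(FP_total * rate))` (round half up — no rounding rule is
prescribed anywhere, and half-up with a floor of one is the conservative
reading); ranking within false positives is the default, within all pooled
candidates available via flag. All scores are oriented so that higher is
more cancer-like before ROC construction; `roc_curve()`'s trapezoidal area
equals concordance-pair counting with half-credit ties.

**Depth diagnostics**: `variant_quality()` is `-log10` of p-values and
posteriors (exact zeros capped at 100, the cap logged) and TLOD as-is;
`bin_by_depth()` uses equal-count depth bins (20 by default) and type-7
empirical quantiles at 99% and 99.5% — both fixed for reproducibility;
`downsample_to_mean_depth()` is binomial thinning with retention
`target/current`, the exact analogue of subsampling collapsed molecules.
Downsampling operates on collapsed (consensus) units, matching how depths
are book-kept throughout.

## 6. Study scales and what the tests show

The packaged studies run at the desk scale: 2 kb panel, 2,000X collapsed
plasma, 20/10/10 cohort (mutation benchmark and classification); a 30+30
null cohort with 3x or 0.5x PBMC depth imbalance (confounder study); and a
150-site, 150X read-level cohort with 1%-per-base tag errors (UMI study).
These sizes were chosen so the full evaluation re-runs from scratch in
minutes while keeping every direction statistically resolvable; the
acceptance script reports each quantity with the problem size it used.

On these cohorts the framework reproduces the qualitative findings the
design targets: deep-PBMC filtering beats WES filtering for every caller on
CHIP-containing cohorts; the PON mask removes hotspot false positives for
the position-blind callers at zero recall cost; retrieval is a step function
of VAF with nothing recoverable below 1e-4 at 2,000X; PBMC depth imbalance
alone moves the Fisher caller's sample-classification AUC far from 0.5 in
either direction and binomial downsampling restores the null; and
network-based UMI grouping beats exact matching when all reads are kept,
with the gap closing at a minimum family size of 3.

## 7. Limitations

The synthetic cohort is a structural stand-in, not a clinical simulacrum:
no indels or CNVs, no fragmentomics, no GC or capture bias, no real genome
context (trinucleotide contexts exist but carry no elevated error rates by
default), no duplex (double-strand) consensus, no mate-pair overlap (each
molecule is observed once per site, so overlap masking is unnecessary by
construction), and hotspot damage is strand-symmetric. Passing the packaged
checks therefore demonstrates that the *pipeline mechanics and statistics*
behave as designed under a faithful error structure — it does not certify
performance numbers on any real dataset, and the headline AUCs of clinical
studies are not reproducible at desk scale. The published clinical values
are deliberately echoed only as directions and orderings, never as numeric
targets.
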