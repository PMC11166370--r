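---
title: "Spectral-count differential abundance and EV biomarker panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count differential abundance and EV biomarker panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evpanel)
```

`evpanel` chains five analysis stages: spectral-count quantification,
cross-proteome comparison, directional pathway activation, human biomarker
classing, and SVM panel selection. This vignette explains the statistical
model behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design choices
made where the procedure left genuine latitude.

## Spectral-count quantification

The quantification input is a matrix of peptide-spectrum-match (PSM) counts
per protein per sample, with each sample tagged by tissue (hippocampus,
cortex, plasma EV), age (3 or 6 months), genotype (WT, 5xFAD) and technical
replicate. Within a tissue-by-age stratum, replicates of a genotype are
pooled by summation into a cumulative count $c$ — a deliberate choice that
mirrors semi-quantitative spectral counting practice and means **biological
variance is not modeled**: the test below addresses counting error, not
animal-to-animal variation. The normalized PSM index is

$$ i = s \cdot c / T, $$

with $T$ the group's total PSM count and scale $s = 10^4$ (counts per ten
thousand PSMs; the scale cancels from ratios and is exposed as `scale`).

Fold changes are computed on indices with a pseudocount,
$\log_2((i_B + q)/(i_A + q))$, default $q = 0.5$ index units. The
pseudocount exists solely so that proteins detected in a single genotype
(common in EV proteomes) receive a finite, rankable fold change; it is
**never** applied to the test statistic. Significance uses the G-test on the
raw cumulative counts against expectations proportional to the group totals,

$$ G = 2\sum_{j \in \{A,B\}} c_j \ln(c_j/e_j), \qquad
   e_j = (c_A + c_B)\,\frac{T_j}{T_A + T_B}, $$

with $0\ln 0 = 0$ and p-values from the upper tail of $\chi^2_1$. No
Williams or continuity correction is applied by default (`correct =
"williams"` is available); with the pooled totals seen in practice
(hundreds of thousands of PSMs) the asymptotics are comfortable, and the
null calibration test in the suite confirms a 3–7% empirical rate at
nominal 5% on 2000 null proteins. Proteins with zero counts in both groups
are reported as `ND` (not determined) and excluded from testing rather than
imputed.

Filtering conventions: `p < p_max` is strict, `|log2 fold| >= lfc_min` is
inclusive (so the headline "log2 fold ≥ 5" retains exactly 5), and output
ordering is p ascending, then |fold| descending, then protein id — fully
deterministic. These conventions matter at boundaries and are tested.

## Cross-proteome comparison

Altered-protein sets per stratum are the quantified records passing
`p < 0.05` and `|log2 fold| ≥ 5` in either direction. Recapitulation between
two strata is plain set intersection annotated with both strata's signed
folds; a protein `ND` in a stratum is absent from that stratum's set, not
zero-fold. Age contrasts join the 3- and 6-month tables of a tissue and flag
concordance (same sign / opposite / single-age). The packaged worked
examples assert the published recapitulation sets (four proteins between
3-month hippocampus and cortex; two at 6 months; five in the age contrast)
on transcription fixtures, because the underlying raw spectra are not
available to rederive them.

## Directional pathway activation

Pathway definitions are user data: a member list plus an expected direction
(+1/−1) per member, read and written as GMT with the direction string in the
description field. For a differential table, members significant at
`p < 0.05` contribute $s_k = \mathrm{sign}(\log_2\mathrm{fold}_k) \cdot
d_k$, and

$$ z = \frac{\sum_k s_k}{\sqrt{N}}, \qquad |z| \le \sqrt{N}, $$

the unweighted directional-consistency z-score. Enrichment is the one-sided
hypergeometric (Fisher) upper tail of the overlap between the pathway and
the significant set, with the universe restricted to quantified proteins. A
call requires both $|z| \ge 0.5$ and $-\log_{10} p > 1.3$ (base 10; 1.3
corresponds to p ≈ 0.05) — the thresholds are exposed as `z_cut` and
`logp_cut`. The commercial pathway tools' curated knowledge bases, edge
weights and literature-bias corrections are out of scope; this module scores
whatever gene sets it is given.

The cross-proteome summary labels a pathway activated if every directional
call across strata is activated, deactivated symmetrically, and mixed when
both directions occur; pathways with no directional call anywhere are
excluded from the denominator. Percentages are reported to one decimal and
sum to 100 within rounding.

## Human panels: staging, statistics, classes

Subjects are staged from MMSE scores: late < 16, 16 ≤ early ≤ 23,
healthy ≥ 24 — a total partition of [0, 30] tested at both boundaries. Band
intensities are assumed Ponceau-normalized (`ponceau_normalize()` is the
ratio helper). Each protein is tested by one-way ANOVA across the three
groups followed by the three pairwise comparisons at Bonferroni-adjusted
level α/3. The pairwise tests use the ANOVA pooled mean squared error with
N − 3 degrees of freedom — the convention of the standard "Bonferroni's
multiple comparisons" post-hoc as implemented by the common GraphPad-style
workflow — rather than independent two-sample tests; a per-pair Welch
variant is available via `welch = TRUE`. Bonferroni is applied within each
protein's family of three comparisons, not across proteins, matching
per-panel testing practice.

Class assignment maps the (healthy-vs-early, healthy-vs-late, early-vs-late)
flags through a rule table (`default_class_rules()`), matched top to bottom
with wildcards:

| he  | hl  | el  | class |
|-----|-----|-----|-------|
| ns  | *   | *   | unclassified |
| up  | up  | *   | class3 |
| up  | ns  | ≠ns | class1 |
| up  | ns  | ns  | class2 |
| up  | down| *   | class1 |
| down| *   | *   | class2 |

The class-1 / class-2 boundary was genuinely open: both are "significant in
early disease", and they differ only in late-stage behavior. We use the
early-vs-late comparison to decide — class 1 requires the late level to
*detectably return* from the early elevation, class 2 leaves late behavior
indeterminate. Down-going early changes route to class 2 (changed early,
late indeterminate), and the undescribed up-early/below-healthy-late
combination routes to class 1. Because the table is plain data, any of these
choices can be overridden without touching code.

## Panel selection and cross-validation

Classifier features must come from the common intersection of per-group
marker availability (`common_intersection()`, which errors on an empty
intersection). `accumulate_cv()` runs `repeats` (default 10) seeded
repetitions of stratified `folds`-fold (default 10) cross-validation; every
fold's class proportions differ from the global ones by at most one subject.
**Inside each training fold** features are ranked by two-sample
pooled-variance t-tests (ties: |t|, then id; zero-variance features rank
first only under exact separation) and accumulated one at a time into a
linear soft-margin SVM (cost 1, features standardized with training-fold
statistics). Ranking inside the fold is a deliberate strengthening over
ranking once on all data: it keeps held-out subjects out of the feature
choice, which a leakage metamorphic test enforces. The SVM kernel,
regularization and standardization were unspecified in the emulated
procedure; linear with C = 1 is the minimal reproducible choice and is
config-exposed.

Accuracy, sensitivity and specificity are averaged over all 100 held-out
folds per panel size k; `best_k` is the smallest k attaining the maximal
mean accuracy. Held-out decision scores at `best_k` are pooled within each
repeat to form one ROC per repeat (mirroring a single reported AUC-ROC per
contrast); the reported AUC is the mean across repeats, and the ROC points
pool all repeats. `roc_auc()` builds the curve by a threshold sweep and
integrates by trapezoid, which equals the Mann–Whitney pair-counting
statistic with ties counted one half — verified exhaustively for small n.
The three diagnostic contrasts are always one-vs-one binary models, never
multiclass.

The human densitometry data behind the published accuracies (78.5%, 79.6%,
70.5%) and AUCs (0.84, 0.85, 0.75) are not deposited; those numbers are
documentation context only, and the classifier is validated on synthetic
panels with known truth instead.

## The synthetic-data generator

The generator exists to make every downstream stage testable with planted
truth; its distributions are stand-ins, not instrument models.

* **PSM counts**: protein relative abundances are log-uniform over
  `abundance_decades` (default 2) decades — a long-tailed stand-in for
  protein dynamic range; each sample draws a lognormal depth factor
  (σ = 0.1); counts are Poisson. Planted proteins multiply their 5xFAD rate
  by `2^effect_log2`, so the generating group-mean count ratio equals the
  planted fold exactly. Under this model the G-test's conditional-binomial
  assumptions hold, enabling the calibration suite.
* **Compositional caveat**: planting changes the 5xFAD total, so
  index-normalized folds are `effect_log2 − log2(1 + (2^effect −
  1)Σw_planted)`. At the default study conditions (20 planted of 2000,
  ≈1% of PSM mass) this is a ≈0.1 log2-unit shrinkage and abundant null
  proteins stay null; tests that need exact fold recovery use equal
  abundances to keep the planted mass fraction small. Real spectral-count
  data have the same property — a strongly regulated abundant protein
  depresses everyone else's index.
* **Human panels**: the 14 candidate proteins carry their reported class
  patterns; log-intensities are normal (σ = 0.4) around class-specific
  means, i.e. lognormal noise on the natural scale, with the planted shift
  `human_effect_d` in units of σ. Class 2's late mean is set midway between
  the healthy and early means — an "intermediate" pattern distinct from
  classes 1 and 3. Consequence: in a *well-powered* design (d = 3, n = 40)
  the midway mean is itself detectable and the rule table assigns class 3;
  the truth record therefore carries `expected_class`, the label the rule
  table implies for each protein's generating means under full power, and
  the round-trip test asserts recovery of that label (classes 1 and 3
  recover their planted labels exactly; class 2 recovers up to this
  boundary decision). At moderate effect sizes class-2 late behavior is
  genuinely indeterminate, which is the phenomenon the class models.
* **MMSE** scores are uniform over each group's admissible integer interval
  (no distribution was reported); every generated subject's score maps back
  to its group under the staging rule.
* **Pathway sets**: half coherent (members from the planted set, expected
  directions matching planted signs — activated by construction), half
  random members with random directions. Random streams are split per table
  (seed offsets) so adding pathways never perturbs count generation.

What the generator does **not** emulate: peptide-level identification and
FDR, MS1 intensities, retention times, batch effects, biological replicate
variance, correlated proteins, missing-band censoring in western blots, or
any relationship between mouse folds and human intensities. Passing tests
therefore demonstrate correctness of the statistics under their stated
assumptions, not performance on real cohorts.

## Numerical and determinism choices

* `0 · ln 0 = 0` in the G statistic; tiny negative rounding at `c = e` is
  clamped to 0, so `G = 0, p = 1` exactly for perfectly proportional counts.
* Strict `p <` thresholds everywhere; inclusive fold thresholds.
* Deterministic orderings: differential tables (p, |fold|, id),
  recapitulation (id), feature rankings (p, |t|, id), `best_k` ties to the
  smaller panel.
* All stochastic procedures take explicit seeds; repeat r of the
  cross-validation uses `seed + r − 1`, and the pipeline derives stage seeds
  from the global seed by fixed small offsets. Rerunning a pipeline
  configuration gives a byte-identical manifest (the manifest carries
  parameters, seeds and output MD5 hashes, and deliberately no timestamps).
* Degenerate inputs: zero-variance groups with equal means give `ns` flags /
  p = 1 rankings; exact separation ranks first with p = 0; empty selections,
  missing genotypes, inconsistent counts and out-of-range MMSE scores raise
  errors naming the offending input.

## Problem sizes in the test and acceptance runs

The packaged suites run at 2000 proteins, 3 technical replicates per
genotype and a mean depth of 10^5 PSMs per sample for calibration and
recovery; 40 subjects per diagnostic group for the human panel; and
10×10-fold cross-validation over 9 features for the classifier benchmarks —
the same orders of magnitude as the emulated study (750–4100 detected
proteins, 39–47 subjects per group, 9-feature universe), chosen so the whole
suite completes in well under a minute per module.

## Known limitations

* Pooling technical replicates discards replicate-level dispersion; with
  biological replicates a count model with overdispersion (e.g.
  negative-binomial) would be preferable to the G-test.
* The pseudocount makes single-group detections rankable but shrinks fold
  changes of low-abundance proteins; the `|log2 fold| ≥ 5` filter is
  therefore conservative near the detection floor.
* Class assignment inherits the multiplicity convention (per-protein
  Bonferroni over three comparisons); no across-protein FDR is applied, by
  design, to match the emulated per-panel testing.
* The activation score treats members independently and unweighted;
  curated-network effects are out of scope.
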