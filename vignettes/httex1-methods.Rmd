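---
title: "Models and methods in httex1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in httex1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(httex1)
```

This vignette is the package's own account of its science: the repeat
grammar, the mosaicism estimator, the regression/survival suite, the
synthetic-data generator that stands in for access-restricted clinical
cohorts, and the numerical and design choices that were genuinely open.

## The repeat grammar and its ambiguities

The *HTT* exon-1 repeat region is modelled as the regular grammar

```
(CAG)+  (CAA)?  (CAACAG)*  (CCGCCA)*  (CCG)*  (CCT)*
```

with Q1 = pure CAG count, Q2 = lone CAA + 2 × CAACAG, QT = Q1 + Q2,
P1 = 2 × CCGCCA, PT = P1 + P2 + P3. Parsing is exact at codon granularity:
no mismatch tolerance inside the tract, reads that fail the grammar are
rejected and counted, and sequencing error is handled upstream by a
mean-quality filter (default Phred ≥ 30). Exactness makes genotypes
deterministic functions of the read; with ultra-deep amplicon coverage,
discarding imperfect reads costs depth, not accuracy.

Two boundary ambiguities need a rule. A CAACAG cassette begins with codons
that could extend the upstream blocks, so the parser munches the pure CAG
tract maximally first; a following `CAA` is taken as the lone interruption
only when the next six bases are not themselves a `CAACAG` cassette. This
reproduces the catalogued decomposition of the interrupted
41-3-2-7-2 allele (`CAG[41] CAA[1] CAACAG[1] …`) while still parsing
`CAGCAACAG` as one CAG plus one cassette. Downstream, `CCGCCA` is consumed
before pure `CCG`, which is unambiguous because `CCA` never occurs on its
own. Anchor flanks, when supplied, must occur exactly once; without them
the read is assumed pre-trimmed (primer sequences are run-specific
configuration, not constants of the method).

The fragment-length emulator maps Q2 to a sizing offset relative to Q1:
−2 for cassette deletions (Q2 = 0), 0 for typical alleles, +1 for
duplications (Q2 = 4) — duplications size only one repeat long, not two,
because the sizing primer mis-primes across the polymorphic region. For
the rare Q2 = 3 interrupted allele no fragment-length behaviour has been
observed; the package uses +1 (3 bp ≈ one codon under naive sizing) and
documents it as a convention.

## The mosaicism estimator

For one individual's disease allele, reads are binned by pure CAG length.
The progenitor (inherited) length is the modal length, with ties broken
upward because PCR slippage is strongly downward-biased, making the upper
of two equally supported lengths the more plausible template. The ratio of
somatic expansions is

$$ R = \frac{\#\{\text{reads} > \text{progenitor}\}}
            {\#\{\text{reads} = \text{progenitor}\}} . $$

Design choices, each surfaced as an argument rather than hard-coded:

* **No slippage subtraction by default.** Single-molecule evidence shows
  upward slippage is rare, so reads above the progenitor are treated as
  genuine somatic expansions. An optional `subtract_slippage` rate
  (e.g. estimated from the short, stable non-disease allele) subtracts the
  expected artefactual counts and floors the numerator at zero.
* **Denominator = progenitor peak only** (`progenitor_window = 0`); a
  window flag widens it for sensitivity analyses.
* **Contractions are counted and reported but never enter the ratio**;
  quantifying contractions reliably would require an assay that separates
  them from slippage, which this measure does not attempt.

Allele splitting partitions the read histogram at the minimum-count valley
between the two largest modes at least 3 CAG apart; unimodal histograms
yield a single allele with a warning rather than an arbitrary split.

## Regression and survival suite

**SE models.** `fit_se_model()` regresses the raw ratio (no transform —
its age trend is linear on the natural scale) on centred age, the centred
CAG measure (Q1 or QT), their interaction, sex and cohort; `SEQ1Q2` adds
Q2 as a categorical factor (treatment coding, reference Q2 = 2) with
Q2 × age interactions. All continuous covariates are centred internally,
so fits are invariant to translations of age or CAG length, and the
centres are frozen in the fit so new individuals can be scored against a
training cohort (predict-then-subtract). The somatic expansion score is
the SEQ1 residual; it averages zero over the fitting cohort by
construction and enters later models uncentred.

**Q2 small cells.** The lone-CAA category (Q2 = 3) occurs at cell size ~1
in realistic cohorts; it is retained in Q1-only models but dropped from
Q2-contrast models, where a single-record level would be aliased with its
own interaction column. Aliased coefficients elsewhere are reported as
`NA` with a warning, never silently dropped.

**Time-to-onset.** `fit_cox()` uses age as the time scale: the event is
motor onset, non-manifest participants are censored at their last visit,
and sex × cohort cells are strata, so each carries its own baseline
hazard. Ties use the Breslow approximation by default (the simplest
documented choice; Efron is a flag). Proportional hazards are checked per
covariate with scaled Schoenfeld residuals. Adjusted survival curves are
evaluated at covariate means with the grouping variable (Q2 category, or
the score dichotomized at zero with zeros going to the positive group) set
per level; the displayed curve averages the per-stratum curves weighted by
stratum size, and the median onset age is the first age at which it drops
to 0.5, reported as not-reached when it never does.

**Permutation inference for Q2.** Asymptotic p-values for terms carried by
a handful of atypical-allele carriers are unreliable, so Q2 labels are
permuted across participants with everything else fixed, and the observed
t (linear) or z (Cox) statistic — or the F / likelihood-ratio χ² for
nested model comparisons — is referred to its permutation null with the
add-one rule $p = (1 + \#\{|s^\*| \ge |s|\})/(B+1)$, two-sided, smallest
attainable $1/(B+1)$. Failed refits (rank-deficient relabellings) are
dropped and counted, with a warning above 5%. The reference analysis uses
$10^5$ permutations; tests and the bundled pipeline default to 999, which
resolves p down to $10^{-3}$ — the scale at which a permutation p is
useful for FDR within these small families.

**Model comparison.** Equal-df models (Q1- vs QT-based) are compared by
nonparametric bootstrap of the r² (linear) or partial log-likelihood (Cox)
difference over participants, with a bias-corrected accelerated interval:
bias correction $z_0$ from the proportion of bootstrap values below the
observed difference, acceleration from the jackknife skewness, endpoints
by normal-quantile interpolation of the order statistics. Degenerate
cases are explicit: identical models give a zero-width interval at zero;
a bootstrap distribution with no spread otherwise raises an
interval-undefined condition rather than fabricating limits.

**Outcome models and least-square means.** Baseline TMS, the progression
score, and TMS/TFC rates of change are linear models with the covariates
appropriate to each response (rates additionally adjust for the baseline
value and age; the progression score is consumed already age- and
CAG-adjusted). Participant-specific rates are BLUPs from a mixed model
with correlated random intercepts and slopes (fixed years-of-follow-up
effect); a singular random-effects fit falls back to per-participant OLS
slopes with a warning. Least-square means per Q2 genotype are predictions
at the cohort-average design row with the Q2 dummies forced to each level
— identical, for a linear model, to averaging predictions over the cohort
under each Q2 assignment. BH-FDR is applied within each named family
(onset models; progression; rates; baseline TMS; SNP association).

**SNP association and meta-analysis.** Per SNP: additive dosage regression
of the score with sex as the only covariate (complete-case; monomorphic
markers flagged untestable; a single-sex cohort drops the covariate with a
warning), and an exact Hardy-Weinberg test that enumerates heterozygote
configurations conditional on allele counts and sums probabilities no
larger than the observed one (plain exact by default; mid-p by flag).
Cohorts are combined by the sample-size-weighted z scheme:
$z_i = \mathrm{sign}(\beta_i)\,\Phi^{-1}(1-p_i/2)$, weights $\sqrt{n_i}$,
$Z = \sum w_i z_i / \sqrt{\sum w_i^2}$.

## What the generator emulates — and what it does not

`synth_config()` holds every generator parameter; `gen_cohort()` is the
analysis models run forward. Defaults were chosen once, to match the
published cohort setting:

* disease-allele structures: typical 96%, CAACAG duplication 2.5%,
  deletion 1%, lone-CAA interruption 0.5%; pure CAG on 40–50 with
  discretized-normal weights (mean 43.2, SD 2.3); normal alleles modal at
  17 CAG;
* demographics: age ~ N(47.8, 11.8²) truncated to 18–75, 54% female, two
  cohorts in proportion 203 : 531;
* expansion-ratio surface: intercept 0.45 at the reference (age 47.8,
  Q1 43.2), age slope 0.006 yr⁻¹, Q1 slope 0.06 per CAG, age × Q1
  0.0015, small sex/cohort shifts; individual propensity SD 0.065
  (inclusive of SNP effects), measurement SD 0.026. The implied model r²
  is ≈ 0.84 analytically; truncation of the age and Q1 ranges brings the
  fitted value to ≈ 0.81, the intended order of magnitude for a strongly
  age- and length-driven ratio;
* onset: Weibull(shape 4, scale 50.4) baseline — median onset ≈ 46 y —
  under proportional hazards with log-HR 0.45 per centred CAG, log(3.05)
  per unit of the latent expansion propensity, and 1.0 for Q2 = 0
  (≈ 10 y earlier onset); censoring at a last visit 2–8 y after baseline;
* clinical outcomes: baseline TMS with a +2.3-unit Q2 = 0 shift and a
  score effect; progression and TMS/TFC slopes with effects of the same
  sign structure; four annual visits per participant;
* SNPs: a six-marker candidate panel at MAFs 0.24–0.35 with per-allele
  effects of 0.02–0.05 score units (one null marker), drawn in
  Hardy-Weinberg proportions and acting additively on the individual
  propensity.

Read-level data follow a multinomial over lengths: unit mass at the
progenitor, a heavy downward-stutter tail (total mass 0.9, geometric decay
0.55), a tiny upward-slippage tail (mass 0.002), and an expansion tail
whose mass relative to the progenitor equals the target ratio — so the
definitional count ratio is unbiased for the target by construction. The
expansion-tail *shape* (geometric, decay 0.5) is a modelling convenience:
only its total mass is analysis-relevant.

The generator deliberately does **not** emulate: sequencing error inside
reads (the parser's rejection path is exercised separately), haplotype
structure or linkage between SNPs, brain-tissue mosaicism,
cohort-specific visit schedules or dropout, non-Gaussian individual
variation (Gaussian is the declared default; nothing is known about the
true shape), or the dependence of sampling age on disease state. Passing
tests therefore demonstrate that the estimators and inference machinery
are correct and calibrated under the stated model — not that the model
captures every feature of real cohort data.

## Numerical choices and degenerate inputs

* Permutation counts use exact `>=` comparisons; enumeration oracles in
  the tests allow a 1e-9 tie tolerance for the identity assignment.
* The BCA interval requires the observed statistic to lie inside the
  bootstrap range; otherwise an interval-undefined condition is raised.
* The exact HWE test works in log-space (`lgamma`) and tolerates a 1e-10
  relative slack when summing configurations "no more probable than
  observed", matching the standard enumeration to 1e-12.
* Progenitor ties break upward; scores of exactly zero group as positive;
  q2 = 3 records drop from contrast models only. Each is a documented
  tie-break, not an emergent behaviour.
* Empty read distributions, zero progenitor counts, monomorphic markers,
  constant covariates, unimodal allele histograms and missing phenotype
  columns all raise classed conditions or flagged warnings before any
  model fit.

## Problem sizes

The test suite exercises the full cohort scale where the criterion demands
it (200 replicates at n = 734 for CI coverage; 500 replicates at n = 200
with 999 permutations for null calibration; a 200-participant end-to-end
pipeline run with 999 permutations and 500 bootstrap replicates, executed
twice to verify byte-identical outputs) and small fixtures everywhere an
oracle must be enumerable: 8 subjects for the grid-search partial
likelihood, 12 for exhaustive permutation enumeration, 30 for the seeded
bootstrap replay, totals ≤ 200 for HWE enumeration. These sizes were
chosen so that each check is exact or has known Monte-Carlo error, and so
the whole suite completes in a few minutes on a single core.

## Known limitations

* The genotyper is a clean-room grammar, not a reimplementation of any
  published pipeline's aligner-based caller; outputs agree at the level of
  structure calls on error-free reads but are not expected to match any
  specific tool read-for-read.
* The progression score is consumed as a covariate; the PCA that defines
  it is out of scope, so "recalculating" it under Q1 is represented in the
  generator rather than recomputed from imaging/cognitive inputs.
* The mis-sizing offsets are defined only for Q2 ∈ {0, 2, 3, 4}; other
  structures raise an unsupported-structure condition.
* Permutation p-values at the bundled default (999) cannot go below
  1e-3; analyses chasing smaller Q2 p-values must raise `n_perm` toward
  the reference 1e5 and pay the proportional cost.
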