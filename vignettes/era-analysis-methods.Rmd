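---
title: "Methods: compositional era analysis of longitudinal microbiome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional era analysis of longitudinal microbiome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxera)
```

## The problem

Hospitalized patients sampled longitudinally (here: stool samples collected
roughly twice weekly during inpatient chemotherapy) fall into two clinical
eras — for instance before and after a hospital-wide change in infection
precautions. The question is which genus-level gut taxa differ between eras
once sequencing compositionality, antibiotic exposure, and time in hospital
are accounted for, and whether any finding survives the fact that each
patient contributes several correlated samples.

`taxera` implements that analysis as a chain of testable stages, each usable
on its own, and ships a synthetic cohort generator with planted ground truth
so the whole chain can be validated without access to patient data.

## The model and procedure

### Compositional scale

Sequencing counts carry only relative information, so all abundance
statistics operate on the centered log-ratio (clr) scale: for counts
$c_1,\dots,c_p$ of one sample and pseudocount $\epsilon$,

$$x_i = \log(c_i + \epsilon) - \frac{1}{p}\sum_j \log(c_j + \epsilon).$$

Rows sum to zero, and the Euclidean distance between clr vectors is the
Aitchison distance used for all ordination. The pseudocount defaults to 1 —
the simplest standard zero-replacement — and is exposed in every entry
point; the cost is a compression of clr differences for taxa whose counts sit
near zero (see "Limitations").

Before the transform, samples with fewer than 500 reads and then taxa
accounting for (strictly) less than 0.01% of retained reads are removed.
Ties at exactly 0.01% are kept: the rule is a strict "less than". The sample
filter runs first so that failed libraries do not contribute to global taxon
frequencies; `filter_table(samples_first = FALSE)` swaps the order for
sensitivity checks. The taxon frequency is computed globally, across all
retained samples.

### Ordination and permutation tests

Era-level composition differences are tested with one-way PERMANOVA:
the total sum of squared Aitchison distances is partitioned into among- and
within-group parts, the pseudo-F is referred to its permutation distribution
(sample labels permuted, distances fixed), and
$p = (1 + \#\{F_\pi \ge F_{obs}\})/(1 + n_{perm})$ with 999 permutations by
default. Dispersion homogeneity uses the betadisper construction: samples are
embedded by principal-coordinates analysis, each sample's distance to its
group centroid is computed (axes with negative eigenvalues contribute
negatively to the squared distance, clamped at zero), and the one-way ANOVA
F on those distances is assessed by permuting group labels. Two deliberate
conventions: the group **centroid** is used rather than the spatial median
(closed form, deterministic), and every permutation stream is seeded, with
the seed recorded in the result. Sampling-week bins for the dispersion
analysis are week 1 = admission through day 7, weeks 2 and 3 the following
7-day blocks, week 4 = day 22 onward.

### Sparse discriminant selection

To rank taxa by how much they separate the eras, an sPLS-DA model is fitted
to the clr matrix against one-hot era indicators. Per component the full
weight vector is computed from the predictor/indicator cross-covariance, the
`keep` largest-magnitude entries are retained (soft-thresholding the rest at
the boundary value and renormalizing — the keepX semantics of the standard
sparse-PLS formulation), and the pair of weight vectors is iterated to
convergence (tolerance 1e-9, max 500 iterations) before deflation. Columns
are centered and unit-variance scaled by default (`scale = FALSE` to
disable). The keep count for component 1 defaults to 50 and is fixed *a
priori* — it is not tuned by cross-validation. |weight| ties at the keep
boundary break lexicographically by taxon label, so fits are deterministic.
Component-1 signs are fixed so a positive loading means higher in the covid
era.

Selection robustness is quantified by leave-one-out cross-validation: each
fold refits component 1 without one sample and records the selected set. A
taxon's stability is the fraction of folds selecting it, and the candidate
set passed to regression is the subset at stability exactly 1.0. Each fold
also scores its left-out sample, giving an honest cross-validated AUROC for
era discrimination (Mann-Whitney formulation, ties count 1/2). The apparent
(in-sample) AUROC is reported alongside, because published figures of this
kind are often apparent values; both are in the pipeline report.

### Antibiotic-exposure history

Exposure to 7 antibacterial classes (fluoroquinolones, 3rd+ generation
cephalosporins, metronidazole, piperacillin-tazobactam, IV
vancomycin/daptomycin/linezolid, oral vancomycin, carbapenems) is encoded
per sample as a daily 0/1 series from hospital admission through the day
before collection, day 0 being the first day of chemotherapy. Each series is
collapsed by an unnormalized decaying weighted sum

$$\mathrm{score} = \sum_{j\ge 0} s_{\text{last}-j}\,\delta^{-j},$$

with decay factor $\delta = 2$ by default (each day weighs twice the day
before it; $\delta = 1.5$ is the standard sensitivity setting). Three
conventions are implemented deliberately and prominently:

* the window **excludes the collection day itself** — the most recent
  completed day carries weight $\delta^0$;
* the sum is **not divided by the total weight** — for the canonical
  six-day example series `(0,0,1,1,1,0)` with $\delta = 2$ the score is
  exactly $2^{-1}+2^{-2}+2^{-3} = 0.875$;
* a day is binary regardless of dose or number of administrations.

The score is bounded by $\delta/(\delta-1)$, approached only by an infinite
all-ones history. PCA on the samples-by-7 score matrix yields the two
antibiotic-history covariates `abx_pc1`, `abx_pc2`; a fully
antibiotic-naive cohort gives a constant matrix and zero covariates with a
warning. Per-class era comparisons of the scores use Welch t-tests (the
equal-variance assumption has nothing to recommend it here).

### Per-taxon regression, volcano selection, robustness

For each stability-1.0 taxon, ordinary least squares regresses the clr
abundance on era (pre = 0, covid = 1), collection day (raw integer), and the
two exposure covariates. The era coefficient is the effect size; its
two-sided t-test p values are BH-adjusted across the candidate taxa. A taxon
is reported when $|\beta_{era}| > 2$ and $q < 0.05$, both strict, split by
sign into covid- and pre-associated sets.

Samples — not patients — are the units of analysis, and no random effects
are fitted; this is a deliberate fidelity choice, with the
leave-one-patient-out screen as the clustering safeguard: the battery is
re-run once per patient, dropping all of that patient's samples, BH re-applied
**within each run** (each run is a complete re-analysis, not an inheritance
of the full-data q values), and only taxa passing the volcano thresholds in
every run are reported as robust. A finding carried by one patient's samples
fails exactly the run without that patient.

### Pipeline

`run_pipeline()` chains the stages in the order above. Each stochastic stage
derives its own sub-seed deterministically from the master seed and the
stage name, so stages can be re-run in isolation and the whole report is a
pure function of (inputs, config) — byte-identical on repetition. Reports
have no timestamps for that reason; timings go to stderr.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the analysis assumes: two eras
with configurable patient counts (defaults 25 pre / 9 covid, matching the
roughly 3:1 sample imbalance of the motivating cohort), 123 genus-level
taxa, twice-weekly sampling (alternating 3/4-day gaps) from admission
(days −3..0) through day 28, negative-binomial depths with mean 20,000 reads,
and a configurable fraction (default 2%) of deliberately failed libraries
below 500 reads to exercise the filter.

Counts follow a logistic-normal–multinomial scheme: per sample the latent
log-composition is baseline + era effect + patient intercept + per-taxon
time trend + noise; a softmax maps it to a composition and a multinomial
draw produces counts. The logistic-normal (rather than Dirichlet) choice
makes planted era effects **additive in clr units**, the scale of the whole
analysis, so recovery is exact in expectation: a planted effect $\delta$ on
one taxon appears as a clr difference of $\delta(1 - 1/p)$ after centering
(the tests use this closed form as their oracle). Default variance
components — patient intercept sd 0.5, sample noise sd 1, time-trend sd 0.02
clr/day, baseline log-abundance sd 2 — are ordinary magnitudes for
genus-level 16S data: within-subject correlation weaker than between-subject
differences, sample-to-sample noise of about one clr unit, and 4–5 orders of
magnitude between common and rare genera. Antibiotic courses are drawn per
patient and class from a policy table (course probability per era, start
window, duration); the default emulates near-universal fluoroquinolone
prophylaxis from about day 0 plus sporadic escalation courses, and era skew
is expressed by making the per-era probabilities differ.

The recovery benchmark used in the acceptance suite plants four |clr| = 3
effects: the two depletions on abundant taxa (abundance ranks 5 and 8 of
123) and the two enrichments on mid-abundance taxa (ranks 30 and 45). The
asymmetry is deliberate and was fixed before any benchmark was run: a −3 clr
depletion is only measurable when the baseline sits well above the
pseudocount floor — depleting an already-rare taxon drives its counts to
zero, where log(c + 1) saturates and the observed effect attenuates below
the |β| > 2 reporting threshold. Biologically this mirrors the real
situation: era-associated depletions can only ever be detected for genera
that were well quantified in the reference era.

### What a green test does and does not establish

The generator reproduces the statistical skeleton the methods assume —
compositionality, patient-level clustering, era imbalance, depth variation,
exposure-series structure — but not taxon-taxon correlation networks,
overdispersed zero inflation beyond the logistic-normal, taxonomic
assignment error, or any relationship between antibiotic exposure and taxon
abundance (exposure covariates are era-skewed noise with respect to the
counts). Green recovery tests therefore establish that the pipeline's
inferential machinery is correct on data satisfying its own assumptions;
they do not establish robustness to real-data pathologies outside that
model.

## Numerical and design choices

* **Permutation-test exactness.** The type-I acceptance harness generates
  its null cohorts with `patient_sd_clr = 0`. Sample-label permutation tests
  are exact only under exchangeability; with patient-level random intercepts
  *and* era assigned at the patient level, freely permuting samples is
  anti-conservative. That inflation is a property of the sample-as-unit
  design itself (the leave-one-patient-out screen exists precisely to
  compensate), not an implementation defect, so the calibration check is run
  in the regime where the test's guarantee applies.
* **Stability under pure noise.** Leave-one-out removes a single sample and
  barely perturbs the weight ranking, so even noise features routinely
  reach stability 1.0 *within* one dataset. The informative null signature —
  and the one tested — is that the identity of the stable set churns across
  replicate datasets, while planted sets are reproduced exactly.
* **PCA determinism.** Components are signed so the largest-magnitude
  loading is positive; variance fractions are non-increasing by
  construction.
* **Degenerate inputs.** Uniform compositions give zero clr rows; constant
  exposure matrices give zero covariates with a warning; singleton groups
  are dropped from dispersion tests with a warning; empty-after-filter
  tables and single-era designs are errors, not silent results.
* **Boundary semantics.** 500 reads is kept, 499 dropped; a taxon at exactly
  0.01% is kept; $|\beta| = 2$ and $q = 0.05$ are *not* selected. All
  comparisons match the strict wording they implement.
* **Open parameters decided here.** Era-specific patient counts are not
  published for the motivating cohort; the defaults (25/9) reproduce its
  sample-level imbalance and are config-exposed. Whether the published AUROC
  was apparent or cross-validated is unknowable from the text; both are
  computed. Welch rather than pooled t-tests for exposure comparisons, and
  per-run (rather than inherited) BH inside the leave-one-patient-out
  screen, are the two remaining interpretation calls; both are flagged in
  the function documentation.

## Worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n_patients_pre = 18, n_patients_covid = 12,
                     effect_taxa = c(5L, 8L, 30L, 45L),
                     effect_size_clr = c(-3, -3, 3, 3), seed = 1)
report <- run_pipeline(pipeline_config(simulation = cfg, seed = 1))
print(report)
```

## Limitations

* No mixed-effects alternative: patient clustering is addressed only by the
  leave-one-patient-out screen, by design.
* Single-factor PERMANOVA only; no strata, no multi-factor designs.
* The pseudocount induces attenuation of clr effects for rare taxa; effects
  planted (or occurring) below roughly the depth-reciprocal abundance scale
  are not recoverable at full size.
* Exposure encoding is binary per day; dose, route (beyond the class
  definitions), and pharmacokinetics are out of scope.
* Two-class discrimination only; `keep` is fixed a priori, never tuned.
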