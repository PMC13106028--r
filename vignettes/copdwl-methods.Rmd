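---
title: "Methods: weight-loss phenotyping and genetic association in COPD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weight-loss phenotyping and genetic association in COPD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdwl)
```

# The problem

Cachexia — unintentional wasting — is common in chronic obstructive
pulmonary disease (COPD) and is dominated, for risk prediction, by its
major criterion: weight loss (WL). Genetic studies of WL in COPD face a
phenotyping problem before any association can be run: cohorts differ
radically in how weight is recorded. Study-visit cohorts measure weight
a handful of times, months to years apart; electronic-health-record
(EHR) cohorts have dozens of irregular, noisy, sometimes frankly
erroneous measurements. `copdwl` implements one operational WL
definition on both record types, a covariate-adjusted single-variant
association stage, fixed-effects meta-analysis, rare-variant burden
testing with cross-study combination, and a generative model of the
whole data structure for validation.

# The WL phenotype

The operational definition, applied identically in spirit to both
record styles, is: **a loss of at least 5% of body weight over a
12-month scale (or between consecutive study visits) that is not fully
regained, or a final BMI below 20 kg/m²**.

## Visit-based classifier

For ordered visit weights $w_1, \dots, w_n$, a *loss event* occurs at
pair $(i, i+1)$ iff $(w_i - w_{i+1})/w_i \ge 0.05$. The event is
*regained* iff any later visit weight (including the last) reaches
$w_i$; ties count as regained, and a regained event reclassifies the
participant to control. A participant is a case iff at least one
non-regained loss event exists, or the final-visit BMI is below
20 kg/m².

Two readings of this rule were genuinely open and are fixed here
deliberately: "5% between study visits" is read as a
*consecutive-pair* comparison (not any visit against a running
maximum), and "fully regain" as *any* later visit reaching the
pre-loss weight. Both are the most literal readings; changing either
changes the phenotype and should never be done silently.

## EHR cleaning

Per participant, cleaning removes (1) physiologically implausible
records — weight < 20 kg or BMI < 10 kg/m² — then (2) in a single pass,
weights beyond $Q_3 + 3\,\mathrm{IQR}$ or $Q_1 - 3\,\mathrm{IQR}$,
where the quartiles are computed over that participant's
post-implausible weights. The IQR pass is deliberately **not** iterated
to a fixpoint: iteration would silently re-define the quartiles after
each removal, and one pass matches the stated procedure. A consequence
worth knowing: when the IQR is zero (constant weights), any deviation
from the common value is removed.

## EHR sliding-window classifier

Windows are anchored to the most recent record. Window starts run from
60 down to 12 months before the last record in 3-month steps — 17
windows — and each window ends 12 months after its start but never
closer than 6 months to the last record, so the final two windows span
9 and 6 months. In every window with at least 3 records, ordinary least
squares of weight (kg) on time (months) gives a slope $b$, its
two-sided t-test p-value (identical to the simple-regression F-test of
variance explained), and the annualized loss fraction

$$\mathrm{ALF} = \frac{-b \times 12}{\bar w},$$

with $\bar w$ the mean observed in-window weight. A window shows WL iff
$b < 0$, $p < 0.05$ and $\mathrm{ALF} \ge 0.05$. The participant is a
case iff the maximum observed weight across *all* WL windows exceeds
the final recorded weight, or the last available BMI is below 20.

Numerical and interpretive choices:

* **"Significant variance explained"** is implemented as the slope
  t-test at p < 0.05 — the only standard reading for a one-predictor
  regression.
* **Reference weight** for the 5% criterion is the mean in-window
  weight: robust, and avoids extrapolating the fit to the window edge.
  The alternative (fitted value at window start) shifts the effective
  threshold by roughly the within-window relative loss (≈ 2% at a
  5%/yr trajectory) and was rejected to keep the criterion centred.
* **Perfectly collinear points** have zero residual variance; the
  variance-explained criterion is then trivially met and the p-value is
  set to 0.
* **Multiple WL windows**: the final weight is compared against the
  maximum across all of them — the most inclusive reading of "the WL
  window".
* **Months are 30.4375 days** throughout, and window membership is
  half-open, $(\text{start}, \text{end}]$ in months-before-last, so a
  record lands in a window deterministically; records ≥ 60 months old
  are never used.
* **Degenerate inputs**: an empty cleaned series yields an explicit
  `indeterminate` call (distinct from control); windows whose records
  share a single day are skipped.

## Eligibility

Spirometric cohorts: age > 40, FEV1/FVC strictly < 0.7, and ≥ 10
pack-years (an ever-smoker flag may substitute where quantitative
smoking history does not exist, behind an explicit switch). EHR
cohorts: age 40–85, an ICD-10 code with prefix J41–J44, and a positive
smoking history. Missing required fields produce an explicit
`indeterminate` outcome rather than silent exclusion.

# Association

For each variant with minor-allele count (MAC) strictly above the
cohort's threshold (20 for visit-based, 40 for the EHR cohort in the
default pipeline), status is regressed on dosage plus age, sex and the
first five ancestry principal components by maximum-likelihood
logistic regression. The Wald test of the dosage coefficient gives the
p-value; the odds ratio is $e^{\hat\beta}$ with 95% CI multiplier
1.959964, chosen over a score test for self-consistency with reported
ORs and CIs. Standard errors are taken from the observed information
evaluated exactly at the MLE (the IRLS-weight approximation costs
about 10⁻⁷ relative error, which matters when validating against an
independent optimizer to six significant digits). Genome-wide
significance defaults to 5×10⁻⁸; the genomic inflation factor is
$\lambda = \mathrm{median}(\chi^2_1)/0.4549364$.

**This stage is deliberately an unrelated-sample simplification**: no
sparse-GRM mixed model is fitted. The synthetic cohorts contain no
relatedness, so the simplification is exact there; on real cohort data
with family structure it will inflate test statistics, and a
mixed-model tool should replace this stage. Quasi-separated fits
(runaway coefficient or exploded SE, expected for rare variants at
desk scale) are flagged `converged = FALSE` and excluded downstream;
no penalized fallback is applied by default so that the behaviour is
explicit.

# Meta-analysis

Effect-size (inverse-variance) pooling with weights $w_i = 1/se_i^2$:
$\hat\beta = \sum w_i\beta_i / \sum w_i$, $se = (\sum w_i)^{-1/2}$,
normal p-value. The effect-size scheme (rather than sample-size-weighted
z-scores) is required to report pooled ORs with CIs. Heterogeneity:
Cochran's $Q = \sum w_i(\beta_i - \hat\beta)^2$ on $k-1$ df and
$I^2 = \max(0, (Q - (k-1))/Q)\cdot 100$, defined as 0 when $Q = 0$.

Harmonization before pooling: variants match on chromosome, position
and *unordered* allele pair; a study reporting the swapped orientation
has its $\beta$ negated and AAF complemented. Any position carrying
more than one distinct allele pair anywhere is removed entirely
(multivalent), and variants present in fewer than two studies are
dropped. No strand flipping is attempted — all inputs are assumed to
share one sequencing build, where strand ambiguity does not arise.
Direction strings always carry one character per configured study
(`+`, `-`, or `?` for absent), a fixed-length contract.

No genomic-control correction is applied before pooling: the
association stage is expected to be calibrated (and its calibration is
measured, not assumed — see the test suite).

# Gene-level tests

Within an annotation mask (consumed from a group file — annotation
construction is out of scope), member variants with in-sample
minor-allele fraction strictly below 0.01 are collapsed into a
per-participant burden: dosages oriented to count minor alleles
(flipped when AAF > 0.5), then summed. The burden enters the same
logistic model as a single predictor. This is a burden-only stand-in
for kernel+burden omnibus tests: the burden component is the
reproducible surface at desk scale, and the omnibus machinery is
documented out of scope rather than approximated badly.

Significance uses a Bonferroni correction for 20 000 independent gene
tests at $\alpha = 0.05$: threshold $2.5\times 10^{-6}$. Cross-study
combination uses Fisher's method, $-2\sum \ln p_i \sim \chi^2_{2k}$,
which with $k = 1$ returns the input p exactly — a property the test
suite asserts to near machine precision. Which per-gene quantity feeds
the combination is an open question in mixed-tool settings; here the
burden p is combined, consistently on both sides.

# The synthetic cohort generator

The generator emulates the data structure the pipeline assumes, with
known truth at every level:

* **Genotypes**: biallelic dosages drawn Binomial(2, AAF) per variant
  under Hardy–Weinberg, AAFs recycled from a configured spectrum
  (defaults 0.3, 0.2, 0.1, 0.05, 0.005 — common through rare); one
  variant panel shared by all cohorts of a study so meta-analysis can
  match on position and allele pair.
* **Phenotype**: a logistic liability — planted variant log-ORs plus
  covariate effects (age, sex, PCs) — with the intercept calibrated by
  bisection on the realized linear predictors so the expected case
  fraction hits the target (default 0.45, the mid-range of observed WL
  prevalences; realized fraction lands within 0.02 at n ≥ 2000).
* **Trajectories**: piecewise-linear in time — baseline plateau,
  linear loss at an annualized rate drawn from 0.05–0.15 of body
  weight per year for 18–24 months, then plateau (cases) or linear
  regain (some controls). Piecewise-linearity matches the slope
  detector's model class, so detection limits are interpretable.
  Heights are fixed per participant and BMI = weight/height²; a
  configured fraction of cases (default 0.1) instead expresses WL as a
  flat trajectory ending below BMI 20. Visit-based cohorts get 2–8
  visits including baseline and final; EHR cohorts get
  Poisson-process-like timestamps (default intensity 12/year) over 72
  months. Gaussian noise (default sd 0.5 kg) is added to every record.
* **Consistency constraints**: truth labels follow the EHR-algorithm
  semantics (episode not fully regained, or final BMI < 20), so the
  generator must not contradict them. Baseline BMI is floored at 22.5
  for participants who are not low-BMI cases, so control drift
  (< 2%/yr) cannot end below the BMI-20 rule; fully regained episodes
  overshoot baseline by 2% (weight cycling), so a regained control's
  final weight clears the episode maximum even under measurement
  noise. Without the overshoot, the case rule "episode maximum >
  final weight" degenerates to a coin flip on noise for exact-regain
  controls — a generator artefact, not a property of the classifier.
* **Contamination**: with configured per-participant probabilities,
  records are injected that the cleaning rules must remove — weights
  below 20 kg, records implying BMI < 10, and values beyond three IQRs
  of the participant's clean weights — each tagged so cleaning recall
  is measurable.

What the generator does **not** emulate: relatedness and population
structure (PCs are pure noise covariates), height dynamics,
informative-visit processes (visit timing is independent of health
state), the true error distribution of EHR weight entry (the Gaussian
noise sd is a free parameter, not a claim about any real system), and
sequencing/QC artefacts. Passing benchmarks on synthetic data therefore
demonstrates algorithmic correctness and statistical calibration under
the stated generative model — not performance on any real cohort.

# Validation strategy and problem sizes

Every stage is validated two ways: against hand-computable examples
and against independent re-implementations (a textbook Newton–Raphson
logistic fit; closed-form moment-sum OLS with an F-test through $r^2$;
the finite Poisson series for even-df chi-square tails; explicit-loop
inverse-variance pooling). The acceptance suite measures, at sizes
chosen to keep the whole suite around a minute of CPU: phenotyping
oracle agreement on 1000 random series; threshold sharpness at 5.0 vs
4.9 %/yr; cleaning soundness; type-I error at α = 0.05 over 2000 null
variants × 2000 participants against the binomial 99% interval;
genomic λ on 10⁵ uniform p-values within 1 ± 0.02; meta-analysis
closed-form identities and 10⁻¹⁰ brute-force agreement;
planted-effect coverage (β̂ within 2 SE of ln 1.5 in ≥ 90 of 100
replicates at n = 5000); and the Fisher k = 1 identity. The
`scripts/acceptance.R` entry point recomputes the same quantities from
a caller-supplied seed.

One floating-point subtlety is worth recording: the sharpness check
constructs its 5.0 %/yr series with a +10⁻⁹ relative margin on the
annualized loss fraction, because exact equality of a
regression-derived quantity with the literal threshold is not testable
at the last ulp; 10⁻⁹ is ten orders of magnitude below any
physiological scale.

# Known limitations

* Real relatedness and stratification are not handled (by design);
  substitute a mixed-model association stage for real cohorts.
* The consecutive-pair visit rule misses slow losses sampled densely
  (three 2.5% drops never trigger a 5% pair) — a property of the
  definition itself, inherited deliberately.
* Burden-only gene tests lose power against heterogeneous-direction
  rare-variant architectures that kernel tests would catch.
* Cleaning thresholds are fixed constants; cohorts with different
  units or paediatric ranges need different values via
  `pheno_params()`.
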