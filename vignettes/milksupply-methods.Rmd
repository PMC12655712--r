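---
title: "Methods: classifying and diagnosing low milk supply"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and diagnosing low milk supply}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement problem

Low milk supply (LMS) is a leading reason for unplanned formula
supplementation and early weaning, yet it is usually defined either by
maternal perception or by a fixed cut on 24 h milk production (MP), most
commonly 600 mL/24 h. Both definitions misclassify: perception correlates
weakly with measured production, and a fixed cut ignores the infant's
actual intake and growth. `milksupply` implements a data-driven
alternative: measure production and intake by test-weighing, describe each
mother–infant dyad by five indicators, let a latent profile model find the
supply phenotypes, and only then derive diagnostic thresholds and risk
factors from the fitted classes.

## From scale readings to dyad measures

A test-weighing diary records the infant's weight immediately before and
after every feed for 24 h plus one feed (the pump set is weighed for
expression sessions). Each event's milk mass is the weight difference,
converted to volume with the 1.03 g/mL density of human milk. Production
over the diary is

    MP = ( sum of removal volumes after the first feed ) * 24 / T

where a *removal* is a breastfeed or a pump expression and `T` (hours) runs
from the end of the first removal to the end of the last. The first feed's
volume is excluded because that milk was synthesised before the window
opened; with the "24 h plus one feed" protocol `T` is about 24–26 h and the
24/T factor normalises to a day. Diaries outside a configurable 20–30 h
window, or with fewer than two removals, are rejected.

Intake is tallied over the same window: direct breastfeeds plus bottle-fed
expressed milk form breast-milk intake, formula bottles add to it to form
total intake. Expressions count toward production but not intake;
bottle-fed expressed milk counts toward intake but not production (it was
produced, and weighed, earlier). Negative weight differences within the
±2 g scale accuracy clamp silently to zero; larger negatives clamp with a
data-quality warning, and are never propagated as negative intake.

Growth is expressed as weight-for-age z-scores (WAZ) by the
lambda–mu–sigma (LMS) method, `z = ((W/M)^L − 1)/(L·S)`, with the
parameters linearly interpolated in age from a pluggable `(sex, age_days,
L, M, S)` table. The bundled table is *synthetic* (smooth, WHO-like 0–6
month curves; `growth_reference_synthetic.csv`); analyses of real cohorts
should substitute a real standard. ΔWAZ is the current minus the birth
z-score. When a naked weight is not measured, the first pre-feed weight
minus 200 g (clothing and diaper) stands in. Average daily weight gain
divides the weight gained since birth by age minus 8 days, because healthy
newborns regain their birth weight around day 8; the formula-to-growth
ratio (mL of formula per gram of daily gain) is 0 for fully breastfed
dyads and +Inf when formula is given but gain is zero or negative — the
severest presentation, deliberately ranked at maximal risk by the ROC
machinery. Breast volume comes from a configurable band/cup lookup (the
shipped table is a placeholder; only the *change* in volume and the
100 cm³ minimal-growth threshold matter downstream). Overweight is
BMI ≥ 25 kg/m², advanced maternal age ≥ 35 y; all derived flags are
missing when their inputs are missing, so descriptive tables keep
per-variable denominators.

## Latent profile analysis

Five indicators describe each dyad: MP, total intake, formula intake, WAZ
and ΔWAZ. Columns with absolute sample skewness above 1 are square-root
transformed (in practice this catches the zero-inflated formula column),
then every column is z-standardised; which columns were transformed is
recorded so class means can be reported on the measurement scale.

The profile model is a K-component Gaussian mixture with diagonal
covariance, fitted by EM with k-means++ style initialisation, 20 random
restarts, a 1e-8 absolute log-likelihood convergence tolerance, a cap of
1,000 iterations, and a monotonicity assertion on every iteration. Two
numerical choices deserve explanation:

* **Class-varying diagonal variances are the default.** The classical
  equal-variance profile model is available (`variance = "equal"`), but it
  is provably ill-suited to a zero-inflated indicator: with >80% of dyads
  at exactly zero formula, the pooled within-class variance of that column
  collapses, and the likelihood then rewards splitting the supplementing
  class — or parking the light supplementers in their own class — over
  separating genuine supply phenotypes. With class-varying variances the
  structural-zero classes simply take a small formula variance and the
  real structure is recovered.
* **The variance floor is 0.05 on the standardised scale** (σ ≈ 0.22).
  A conventional tiny floor (1e-6) lets a structural-zero class become a
  near point mass, which then rejects every dyad with any formula at all;
  the moderate floor keeps occasional light top-ups inside their true
  class and prevents degenerate spikes.

Classification quality is summarised by the normalised entropy
`1 − Σ(−p·log p)/(n·log K)` (1 = perfect separation; defined as 1 at
K = 1). K is compared to K−1 with a parametric bootstrap likelihood ratio
test (BLRT): simulate from the fitted (K−1)-model, refit both models on
each replicate, and use the `(1 + #{boot ≥ observed}) / (n_boot + 1)`
convention (99 replicates by default). Each bootstrap refit is
warm-started at the observed-data estimates plus cheap random restarts —
without the warm start an under-fitted null refit inflates the bootstrap
statistics and destroys power.

Model selection applies five criteria: BIC lower than at K−1; entropy at
least 0.8; a significant BLRT (p < 0.05); average posterior membership of
at least 0.5 in every class (as printed in the source criteria — an
unusually permissive bar, so it rarely binds); and the smallest class
holding more than 5% of dyads. The selected model is the *largest* K
passing everything; K = 1 satisfies the within-model criteria trivially
(its entropy and posteriors are 1), so an impossible criterion (e.g. an
entropy bar above 1) selects no model at all.

Fitted classes are mapped to stable clinical labels from their
original-scale means: the highest-production class whose production
exceeds intake is *oversupply*; of the rest, the lowest-production class
is *severe LMS* (it should also carry the highest formula use — anything
else is flagged); the lowest-WAZ class is *slow growth*; the remainder is
*adequate*. Adequate and oversupply form the normal-supply (NMS) group,
severe LMS and slow growth the LMS group. Dyads are assigned modally;
posterior ties go to the lower canonical index and are reported.

## Diagnostic thresholds

ROC curves are built on thresholds at midpoints between consecutive
distinct scores plus ±Inf sentinels; direction ("lower-is-LMS" for
production, intake and gain; "higher-is-LMS" for formula intake and the
formula-to-growth ratio) is a sign convention, never a data mutation. AUC
is computed both as the trapezoidal area and as the tie-corrected
Mann–Whitney rank statistic, and the two must agree to numerical
precision. The optimal cut maximises Youden's J = sensitivity +
specificity − 1, with ties broken toward higher sensitivity: in supply
screening a false negative (a missed LMS dyad) delays intervention and is
the costlier error, while a false positive leads to extra breastfeeding
support. Thresholds are reported on the measurement scale. The panel
restricts formula intake and formula-to-growth to partially breastfeeding
dyads, flags subgroups below 20 usable dyads, and reports a reason instead
of a curve when one group is absent. A comparison helper evaluates the
legacy 600 mL/24 h production cut against the derived one with exact
confusion counts.

## Risk-factor models

Class membership (4-level, class 1 = adequate as reference) is regressed
on ten candidate maternal risk factors — overweight, advanced age,
gestational diabetes, minimal breast growth (< 100 cm³), fertility
issues, thyroid disorders, PCOS, nipple piercing/breast surgery,
postpartum haemorrhage, hypertensive disorders — with five locked
confounders: infant age at measurement, sex, birth weight, birth mode and
parity. The multinomial fit is Newton–Raphson on the multinomial
log-likelihood with step-halving, a 1e-6 gradient-norm convergence bar, a
1e-8 ridge stabiliser, internal column standardisation for conditioning
(coefficients and covariance are mapped back exactly), Wald covariance
from the observed information, and an explicit separation warning with a
stronger ridge fallback — never silent shrinkage. Complete cases per
model, listwise.

Variable selection is stabilised by the bootstrap: 500 resamples by
default (200 in the bundled acceptance run), each running backward
elimination by AIC over the ten risk factors with the confounders locked;
factors selected in more than half the resamples are retained for the
final model on the original data. The per-resample selector is a design
choice — the retention rule (frequency > 0.5) is the specified part, and
backward-AIC is the most common companion; a p-value-based backward pass
would be a drop-in alternative. Co-occurring factors are modelled as
four-level composites (neither / A only / B only / both, reference
"neither") in separate models that keep the confounders and the other
retained predictors but drop the two source flags as separate terms.

Descriptive machinery follows printed-table conventions: percentages are
half-up rounded to one decimal with available-data denominators (total
denominators for missingness rows and class-size denominators in the
class-by-factor table, with a switch), pairwise Wilcoxon rank-sum tests
use the exact distribution for combined n ≤ 20 without ties and the
tie-corrected normal approximation otherwise, and the two-sided Fisher
exact test uses the point-probability rule (the base-R convention). The
class-by-factor report replaces compact significance letters with an
explicit pairwise p-value matrix, since letter assignment is
presentation-only and ambiguous.

## The synthetic cohort

Real test-weighing cohorts of this kind are not publicly deposited, so the
package ships a generator that emulates the study conditions and carries a
full ground-truth ledger (true class, true indicator values, true flags)
for every run. Its defaults are the study conditions: 460 dyads in four
classes of 254/30/56/120 with production centres 789/1171/427/604 mL/24 h,
class-conditional risk-factor prevalences at the reported per-class rates,
MCAR missingness at the reported per-variable rates (breast-volume change
16.1%, BMI 11.1%, maternal age 0.9%, birth mode 3.7%), infants aged 4–26
weeks, 45% male, birth weights placed on the growth reference at the
target birth z-scores.

Class sizes are fixed at the target composition (largest-remainder
apportionment, randomly permuted across dyads) rather than drawn
multinomially, with `class_sampling = "multinomial"` available. The
composition *is* the condition being emulated; under a multinomial draw
the smallest class (6.5%) would fall below the 5% selection criterion in
roughly a tenth of cohorts through sampling noise alone, which tests the
draw, not the method.

The free parameters — within-class spreads, formula-use rates and
volumes, ΔWAZ centres — were fixed once against the reported marginal
calibration targets: pooled production ≈ 734 ± 228 mL/24 h (the generator
realises ≈ 722 ± 220), mean formula ≈ 51 mL/24 h, around 80 partially
breastfeeding dyads, pooled ΔWAZ mean ≈ −0.7, average daily gain
≈ 29 ± 9 g/day — under the constraint that the four-class structure is
actually identifiable at n = 460 (the point of a validation generator).
That constraint costs some marginal dispersion: pooled WAZ/ΔWAZ spreads
run 15–20% below the reported SDs, fully-breastfeeding sits near 84%
versus the reported 82.4%, and the fitted classification entropy
(≈ 0.90) exceeds the reported 0.821. Formula supplementation is
concentrated in the severe class (all supplemented, mean 370 mL/24 h)
with 5% light top-ups (mean 25 mL) in the adequate and slow-growth
classes.

Each dyad also gets an event-level diary whose recomputed production,
breast-milk intake and formula intake land within 1% of the targets: feed
volumes are drawn log-normally and rescaled, and the ledger split rule
keeps the books consistent (intake below production → the surplus is
pump-expressed; intake above production → the excess is bottle-fed stored
milk). What the generator does *not* emulate: circadian feeding patterns,
informative missingness, measurement drift, twins or preterm infants, or
a real growth standard. Passing tests therefore demonstrate correctness
of the machinery under the stated generative model, not clinical validity
on real cohorts.

## Problem sizes and reproducibility

Every stochastic stage takes a seed; the pipeline derives per-stage seeds
deterministically from one master seed so stages can be rerun stably, and
reruns are byte-identical. The bundled acceptance run uses the default
460-dyad cohort, K from 1 to 5 with 99 BLRT replicates, and 200
stability-selection resamples. The test suite exercises recovery with 20
independent 460-dyad cohorts, a 200-replicate BLRT type-I simulation at
n = 120 with 19 bootstrap replicates, 400-replicate Wald-coverage and
single-run stability-selection calibrations at n in the hundreds to low
thousands — sizes chosen to make the suite a routine desk run.

## Known limitations

The growth reference is synthetic; WAZ values are internally consistent
but not WHO values. The bra-volume table is a placeholder. The BLRT
inherits the usual caveat that real data are never exactly mixture-Gaussian,
so at scale it tends to favour more classes; the share, entropy and BIC
criteria are what stop K in practice. Composite models with rare
combinations can have empty levels (reported, with the OR undefined).
Missingness is handled by listwise deletion throughout, matching the
source analysis; no imputation is attempted.
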