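---
title: "Whole-test severity classification of exertional symptoms: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-test severity classification of exertional symptoms: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlascpet)
```

## The problem

During incremental cardiopulmonary exercise testing (CPET) a subject pedals
against a work rate that rises in 10–20 W steps every 1–2 minutes and rates
dyspnea and leg effort on the Borg CR10 scale (0–10) in the last 30 seconds
of each stage. Convention keeps only the rating at peak exercise. That single
number is misleading in impaired populations: a severely limited patient who
stops at 50 W may report the same peak score as a mildly limited patient who
reaches 115 W, while carrying a far larger symptom burden at every shared
work rate. The whole-test *trajectory* of scores against work rate, read
against what healthy sedentary subjects of the same sex and age would report
at the same work rates, is the quantity of clinical interest.

The classifier in this package takes one subject's trajectory
$(w_i, s_i)_{i=1..n}$ and a family of seven reference centile curves —
the minimum envelope, the 5th, 25th, 50th, 75th and 95th centiles and the
maximum envelope, written $c_k(w)$ in ascending order — and decides which of
the six inter-centile bands most plausibly contains the trajectory. The band
maps onto a four-level severity scale: everything up to the 50th centile is
*mild*, 50th–75th *moderate*, 75th–95th *severe*, and above the 95th
*very severe*. Peak scores are classified on the conventional scale
(0–2 mild, 3–4 moderate, 5–6 severe, ≥ 7 very severe) for comparison.

## The scoring model

**Reference curves.** Centile tables are consumed as tabulated grids
(JSON schema in `read_centiles()`), not as equations: the published
normative equations are external to this package and any table in the same
schema can be supplied. Curves are evaluated by linear interpolation between
the shared work-rate knots and held flat beyond either end of the table.
Linear interpolation on a shared knot grid is the one scheme that
automatically preserves the ordering of the seven curves at every query
point; higher-order schemes do not guarantee this. The minimum and maximum
are stored as ordinary work-rate-dependent curves, since reference envelopes
narrow to zero at low load and widen with work rate.

**Fit score per curve.** Each curve $c_k$ receives a reciprocal
exponential loss (REL):

$$\mathrm{REL}_k \;=\; \max\!\left(\ell_{\min},\;
\frac{\sum_i u_i\, e^{-\alpha\, d_{ik}}}{\sum_i u_i}\right),
\qquad d_{ik} = \min\bigl(|s_i - c_k(w_i)|,\; D\bigr),$$

with weights $u_i$ described below, steepness $\alpha$ (per Borg unit),
deviation clamp $D$ and floor $\ell_{\min}$. Being a *reciprocal* loss, a
better fit yields a larger score: $\mathrm{REL}_k = 1$ exactly when the
trajectory lies on the curve, and the score decays exponentially — hence
sensitively — as points move away. The weighted *mean* (rather than a
product) of the per-point terms keeps the score in $(0, 1]$, makes it
invariant to trajectory length, and reads directly as "average closeness to
this curve".

**Band scores and probabilities.** Each of the six bands is scored by the
product of its two border RELs — the 25th–50th band scores
$\mathrm{REL}_{25}\cdot\mathrm{REL}_{50}$ — so a band is rewarded when the
trajectory hugs *both* of its borders, and a band adjacent to a
well-fitting curve inherits part of that fit. The six scores are normalized
to sum to one and read as the probability that each band is the most
representative. The floor $\ell_{\min}$ guarantees all scores are positive,
so normalization is always defined; the floor is applied per centile first
and the normalization afterwards.

**Band selection.** The winning band is not simply the arg-max. A
generalized binary search walks the severity-stratum boundaries
(50th, then 75th, then 95th centile): at each boundary the *summed*
probability of the surviving bands below is compared with the summed
probability at or above, and the heavier side survives. When a single
stratum remains, its highest-probability band is reported. Comparing summed
masses prevents the mild stratum — which spans three of the six bands —
from being outvoted band-by-band, and conversely prevents a diffuse spread
of mass across the three mild bands from beating a concentrated moderate
band. Exact ties go to the higher side by default (`tie_rule = "higher"`),
a deliberately conservative choice that never understates burden.

**Inertial points.** At low work rates the reference curves coincide near
zero: healthy subjects report essentially no symptoms below a load
threshold. An observation there cannot tell the bands apart, but it still
contributes $e^{-\alpha d}$ terms to every curve — nearly 1 for all of
them — diluting the contrast carried by the informative later stages. Such
points are down-weighted to `inertial_weight` (default 0.25), with the
weights rescaled to sum to $n$. A point counts as inertial when the
5th–95th spread at its work rate is below `inertial_spread`, default one
Borg unit: when the entire normal band spans less than one Borg category, a
rating made in whole or half categories cannot resolve position within it.
Setting `inertial_spread = 0` restricts the rule to work rates where the
curves coincide exactly; on tabulated real-world references, whose low-load
centiles are recorded as identical zeros, the two settings agree, but on
smooth synthetic curves the exact-coincidence rule almost never fires and
the low-load dilution returns — which is why the resolution-based default
was adopted.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `alpha` | 1 | per Borg unit | loss steepness; larger = less lenient toward neighbouring bands |
| `min_loss` | 1e-4 | — | floor on each curve's REL; keeps normalization defined |
| `clamp_dev` | 5 | Borg | deviation cap; one wild outlier cannot zero a curve's score |
| `inertial_weight` | 0.25 | — | weight of low-information early points |
| `inertial_spread` | 1 | Borg | 5th–95th spread below which a point is inertial |
| `tie_rule` | "higher" | — | side that wins exact ties |
| `threshold_order` | p50, p75, p95 | — | binary-search split points (the stratum boundaries) |

None of these is learned from data; the classifier involves no training.
`alpha` is the leniency dial: at the default, a point one Borg unit from a
curve contributes $e^{-1} \approx 0.37$. The defaults are fixed, documented
choices; all are overridable per run via `atlas_config()` or a YAML/JSON
config file.

Diagnostics attached to each result are heuristics, not part of the
selection rule: `few_points` (< 3 observations), `low_confidence` (winning
band below probability 0.35), `degenerate_floor` (some curve hit
`min_loss`; with the default clamp this requires $\alpha \gtrsim 1.8$).

## The synthetic study generator

Real normative tables and the patient cohort behind this method are not
redistributable, so the package ships a generator that emulates both and
makes every analysis reproducible end to end.

**Centile tables.** Each curve is zero up to a per-centile onset work rate
and then rises as a power function of the excess load,
$T_k \left((w - o_k)/(W - o_k)\right)^{1.8}$, reaching its terminal Borg
value $T_k$ at the top of the 0–160 W grid. The power form follows the
psychophysics of the Borg scale (perceived intensity grows as a power
function of the stimulus); the exponent 1.8 and the onset stagger are
plausible invented values, exposed in `synthetic_spec()`. Onsets fall and
terminals rise with centile order, which guarantees a valid, ordered table
for any conforming parameter set; the defaults keep the minimum, 5th and
25th centiles at zero through 80 W, as real leg-effort references do.

**Trajectories.** A subject targeted at a band follows its midpoint curve
(the shared curve value where the band has zero width), plus Gaussian noise
(default sd 0.3 Borg), optional sudden persistent +1.5-Borg jumps, clipping
to [0, 10] and rounding to the nearest half point — the usual granularity
of CR10 ratings in practice.

**Cohorts.** Subjects draw a true severity from a configurable mix
(default 35/25/25/15%), a target band within that stratum per symptom, and
three two-level impairment labels (GOLD stage I–II vs III–IV, critical
mechanical constraint, low peak VO2) whose adverse probability rises
linearly with severity rank at rate `coupling` (0 = independent; default
0.6). Crucially, more severe subjects terminate two stages earlier per
severity step: their peak scores are sampled from lower work rates, which
reproduces the phenomenon motivating the method — peak-score
classification systematically understates the burden of the most impaired.

What the generator does *not* emulate: real centile shapes fitted to
healthy cohorts, within-subject autocorrelation of ratings beyond the step
events, rating idiosyncrasies (digit preference, anchoring), missing
stages, or any gas-exchange physiology. Tests passing on synthetic data
therefore demonstrate the algorithm's internal correctness and its
behaviour under the stated noise model — not clinical performance on real
patients.

## Cohort statistics

The cohort layer reproduces the comparative analyses used to evaluate the
method against peak scores: a 4 × 4 cross-tabulation of the two
classifications, McNemar's test of paired disagreement, and chi-squared
discrimination of impairment groupings by each method's categories.

McNemar's test dichotomizes the four categories at severe-or-worse versus
below (the cut is configurable); with fewer than 25 discordant pairs the
exact two-sided binomial p-value is used, otherwise the
continuity-corrected statistic $(|b-c|-1)^2/(b+c)$ on one degree of
freedom — the conventional switch point, at which the two forms agree to
within 0.02 wherever the corrected p is below 0.2. With no discordant
pairs the test is degenerate and p = 1 is reported. The chi-squared test
is the uncorrected Pearson statistic; empty severity rows are dropped from
discrimination tables before testing (they carry no information), and a
constant grouping is reported as non-discriminating rather than an error.
The "main limiting symptom" is the one with the higher peak score; ties
are labelled `both` and conventionally excluded from two-way comparisons.

## Numerical and degenerate-input choices

- Interpolation is linear with flat extrapolation; queries below the first
  knot return the first knot's value.
- Probabilities are validated to sum to 1 within 1e-9.
- Exact probability ties in the selector are resolved by `tie_rule`; ties
  in the final within-stratum arg-max use the same rule (higher band wins
  by default).
- Coincident borders are handled with no special casing: both borders
  receive the same per-point deviation there, which is precisely why
  point-in-band logic is absent throughout — a point's position *between*
  coincident curves is undefined.
- A single-point trajectory is classified normally and flagged
  `few_points`.
- All randomness is seed-controlled; identical inputs, config and seed give
  bit-identical results.

## Problem sizes

The test suite and the acceptance script run at deliberately modest scale:
200 trajectories per recovery experiment, 1000 random probability vectors
for the selector/normalization properties, 100-subject cohorts for the
end-to-end comparisons, and 200 replicates of 120-subject cohorts for the
type-I-error check of the discrimination pipeline. These sizes give stable
rates (binomial s.e. ≈ 1.5–2 percentage points) while keeping a full run
around a minute.

## Known limitations

- The exact constants of the reference implementation's auxiliary
  operations (reweighing, clamping, floor, threshold schedule) are not
  published; the values here are this package's own documented choices,
  isolated in `atlas_config()` so alternatives can be substituted without
  code changes.
- Severity recovery rates quoted anywhere in this documentation are
  properties of the synthetic generator's noise model, not clinical
  accuracy estimates.
- The classifier assumes scores do not decrease in information value with
  work rate other than through the inertial-spread rule; protocols with
  very coarse increments (20 W, 1-min stages) yield few points and wider
  uncertainty, surfaced via the `few_points` and `low_confidence` flags.
- Only the exponential loss family is implemented; alternative losses
  change leniency in ways not explored here.
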