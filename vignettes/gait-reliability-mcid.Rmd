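---
title: "Reliability and minimal clinically important differences of gait metrics"
author: "gaitmcid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability and minimal clinically important differences of gait metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmcid)
```

## The problem

Chronic peripheral vestibular failure — unilateral or bilateral loss of
inner-ear balance function — produces a *sensory ataxic* gait: increased
stride-to-stride variability, left–right asymmetry and a compensatory
broad-based stance, all amplified when walking slowly or with eyes closed.
Quantitative gait metrics from instrumented walkways are attractive trial
endpoints for this population, but an endpoint is only useful if one knows
(a) how reproducible it is across repeated measurements and (b) how large a
change is clinically meaningful rather than noise. This package implements
that evaluation as a reusable, fully testable pipeline: metric extraction
from step-level footfall events, test–retest reliability, minimal
detectable change, and triangulated MCID estimation, for three walking
conditions (preferred speed, slow, eyes closed) with two analyzed walks per
condition (each walk pooling two recorded walkway trials to accumulate
enough gait cycles).

## From footfalls to metrics

The raw unit is a footfall event: side, heel-strike and toe-off times, heel
coordinates. Strides are segmented per trial as successive same-foot
contacts; no stride ever spans the pooled-trial boundary. Thirteen metrics
in five domains are computed per walk:

* **Pace** — velocity (total progression distance over total ambulation
  time, per trial and then combined across the pooled pair, so the spatial
  reset between trials cannot bias it), mean stride length, mean stride
  time.
* **Phase** — swing and double support as a percentage of each stride's
  cycle time, then averaged. Double support is measured from the
  overlapping stance intervals of the two feet inside each cycle; a cycle
  whose start is not covered by the opposite foot's recorded contact
  history (the leading foot's first cycle in each trial) contributes `NA`
  rather than an undercounted value.
* **Variability** — CV (100·SD/mean) of stride length, stride time and
  swing percentage, strides of both feet pooled into one sample per walk.
  Pooling maximizes the cycles per estimate, which matters because
  variability estimates below roughly 15 cycles are unstable (the package
  warns there).
* **Asymmetry** — the symmetry-index form
  `100·|mean_L − mean_R| / (½(mean_L + mean_R))`, reported as an absolute
  value. This is the most common walkway convention and matches the
  magnitude scale of published vestibulopathy cohorts (stride-length
  asymmetry well below 1%). A log-ratio alternative
  (`100·|log(mean_L/mean_R)|`) is available behind the `asym_form` switch;
  the two agree to first order at these magnitudes.
* **Postural control** — mean and CV of the base of support, defined per
  step as the perpendicular distance from a heel point to the line through
  the opposite foot's two temporally flanking heel points.

The progression axis is re-estimated per walk as the principal axis of the
*per-foot mean-centered* heel positions. Centering each foot separately
matters: a pooled principal component is pulled by the constant lateral
offset between left and right feet and acquires a small spurious tilt,
whereas the within-foot axis is exactly the walking direction for clean
straight-line gait. This keeps the deterministic-gait round trip exact and
is robust to lateral drift.

Variability and asymmetry metrics require at least 4 strides per foot
(hard floor); below it they propagate as missing values, never as zeros.

## Reliability

For each metric × condition the two walks form an n-subjects × 2 matrix.
A balanced two-way decomposition (rows = subjects, columns = walks) yields
mean squares `MS_R`, `MS_C`, `MS_E`, from which the single-measure ICC is

* consistency: `(MS_R − MS_E) / (MS_R + (k−1)·MS_E)`
* absolute agreement: `(MS_R − MS_E) / (MS_R + (k−1)·MS_E + (k/n)(MS_C − MS_E))`

with `F = MS_R/MS_E` on `(n−1, (n−1)(k−1))` degrees of freedom. Published
gait-reliability work commonly labels its coefficient "ICC(3,1), absolute
agreement, two-way mixed", a label that mixes two conventions (the classic
3,1 form is the consistency ratio; absolute agreement adds the
between-walk term). Both forms are implemented; the pipeline default is
**absolute agreement**, honoring the stricter reading, and every report
records which form produced each number. With k = 2 and a small walk
effect the two nearly coincide, which is why the package's own guarantees
are stated as properties (oracle agreement, interval coverage) rather than
as reproductions of any particular published ICC column.

Confidence intervals are exact F-based for the consistency form and the
McGraw–Wong approximation with Satterthwaite degrees of freedom for
absolute agreement; the implementation reproduces a reference
implementation's point estimates to 10 decimals and its intervals to the
printed precision (see `test-reliability.R`). Interpretation bands follow
the usual cut-points — below 0.5 poor, 0.5–0.75 moderate, 0.75–0.9 good,
above 0.9 excellent — with boundary values assigned to the higher band
except 0.9 itself, which is good (the excellent band is strictly above
0.9). Subjects with a missing walk value are dropped listwise per metric ×
condition and counted in the run manifest.

Degenerate agreement (`MS_E = 0`) reports ICC exactly 1 for the
consistency form with interval [1, 1]; for absolute agreement the estimate
and interval remain defined through their `MS_E → 0` limits.

## Measurement error and MCID

`SEM = SD·√(1 − ICC)` and `MDC95 = 1.96·√2·SEM`. The SD entering SEM, the
distribution-based MCIDs and the anchor regressions is the cohort SD
pooled over both walks of the condition, after outlier removal — one SD
per metric × condition, matching the single mean ± SD a cohort table
reports. MDC95 is strictly decreasing in ICC at fixed SD, which the tests
assert together with the closed-form limits (ICC = 1 ⇒ MDC95 = 0;
ICC = 0, SD = 1 ⇒ MDC95 = 2.7719).

Three MCID routes are triangulated:

* **Distribution-based**: 0.2/0.5/0.8 × SD (small/medium/large effect).
* **Anchor-based**: each clinical anchor (FGA, FES-I, PCS-12) qualifies
  for a metric only when the Pearson correlation with the per-subject
  metric value exceeds |r| > 0.3 and at least 10 complete pairs exist.
  For a qualifying anchor, the MCID is the unstandardized regression
  slope B times the anchor's established meaningful change, signed by the
  anchor's improvement direction (FGA +4 points, FES-I −8 points, PCS-12
  +10 points), so that a clinically meaningful anchor improvement maps to
  the metric's own improvement direction. The per-subject metric value
  entering these regressions is the mean of the two walks, which halves
  walk-level measurement noise in a cross-sectional anchor design.
* **Triangulated**: the arithmetic mean of the available members of
  {medium-effect distribution estimate, FGA-, FES-I-, PCS-12-based
  estimates}; with fewer than four available, the mean of those present.

All report-level estimates carry the metric's improvement sign (positive
for velocity, stride length, swing; negative for stride time, double
support, all variability/asymmetry markers and stride width). Rows where
the triangulated MCID does not exceed MDC95 in magnitude are flagged: for
those metrics, individually meaningful change is not separable from
measurement error — in practice this concentrates in the variability and
asymmetry domains, whose reliability is lowest.

Reported tables round to 2 decimals, half away from zero.

## Preprocessing and group comparison

Before any reliability or MCID computation, a pairwise ±3 SD outlier rule
runs per metric × condition: a subject's walk pair is removed when either
walk value is beyond 3 SD of that walk's cohort mean (computed once,
non-iteratively); both walks are removed together, for that metric and
condition only. Under Gaussian cohorts this removes well under 3% of
measurements. Normality is screened with Shapiro–Wilk. Patients are
compared with healthy controls per metric × condition by two-sided
independent-samples t-tests on the per-subject condition means; the
default is the Welch form, because the two groups differ in size (60 vs
30) and homoscedasticity is not guaranteed — the pooled-variance Student
form is available by switch, with no multiplicity correction across the
13 × 3 grid (raw p-values are reported per metric).

## The synthetic-cohort generator

The generator exists at two levels because the pipeline needs testing at
two levels.

**Metric level** (`simulate_metric_cohort()`): for each metric with
population mean μ, SD σ and target ICC ρ, subject true values carry
variance ρσ² and each walk adds independent noise of variance (1−ρ)σ², so
the expected two-walk single-measure ICC is exactly ρ and the marginal SD
is σ. A standard-normal latent mobility-impairment factor carries a 0.6
loading of every metric's subject-level deviation (signed so that worse
mobility worsens the metric), and anchors are linear in the same factor:
FGA 18 − 5z (residual SD 3.5, clipped to 0–30), FES-I 32 + 7z (SD 5,
clipped 16–64), PCS-12 38 − 6z (SD 5), MCS-12 50 + 0·z (SD 9, carried but
unused). These defaults produce metric–anchor correlations of roughly
0.4–0.6 — deliberately above the |r| > 0.3 gate, so the anchor-based MCID
path is exercised by default; published cohorts do not report their
metric–anchor correlation magnitudes, so this is a stated design choice,
not an empirical calibration. Default means/SDs/ICCs per metric and
condition come from `vestibular_cohort_defaults()`, a chronic
vestibulopathy calibration; cycles per pooled walk default to 21.8 ± 4.5
(preferred), 29.2 ± 4.8 (slow) and 30.4 ± 8.5 (eyes closed).

**Step level** (`synthesize_step_stream()`): per-cycle stride times,
stride lengths and swing fractions are drawn per foot from normal
distributions and *moment-matched* — affinely rescaled to exact sample
means and SDs — so the extracted means, CVs and asymmetries hit their
targets essentially exactly rather than in expectation. Within-foot SDs
are solved from the pooled-CV target given the between-feet mean split, so
the pooled-stride CV is exact even under asymmetry. Heel positions are
laid along the progression axis with lateral offsets ±swidth/2 plus noise;
the lateral noise scale is calibrated by running the package's own
base-of-support extraction on a unit-scale draw and exploiting the
near-linearity of the extraction in the lateral coordinates (two fixed-
point iterations), so extracted stride-width mean and CV also match
targets tightly. The extractor itself is validated independently by
hand-computed deterministic cases, so this inversion does not make the
round-trip tests circular.

Three structural facts about the step model are worth knowing:

* **Velocity and double support are emergent**, not drawn:
  `vel = slen/stime` and `dsupp = 100 − swing_L − swing_R`. Published
  cohort means are not exactly self-consistent across these identities
  (rounded summary rows differ by ~1%), so emergent metrics land within
  about 1.5% of their nominal targets rather than exactly on them — and in
  cohort simulations their reliability is inherited from the metrics they
  derive from, not independently controllable.
* **Stride-time asymmetry saturates.** Both feet share each trial's total
  duration, so a persistent left–right stride-time difference is
  physically unsustainable: it accumulates as inter-foot phase drift. The
  generator realizes it as a bounded linear phase schedule per trial
  (right-foot contacts follow left-foot contacts; the cumulated drift is
  capped so the phase stays inside the double-support band). For short
  trials — the realistic regime, ~5 strides per foot per trial — targets
  are fully realized; for very long trials the realized asymmetry
  saturates below large targets, and the realized value is recorded in
  the `planned` attribute. Stride-length asymmetry has no such constraint
  (spatial drift between feet is benign) and is realized exactly, as is
  swing asymmetry.
* **Infeasible targets are rejected**, not silently repaired: swing ≥ 50%
  of the cycle (negative double support), CV/asymmetry combinations whose
  between-feet spread exceeds the pooled variance, and swing or timing
  distributions that reach non-positive values all raise descriptive
  errors. When the *cohort* simulator draws per-walk targets that stray
  into these regions (Gaussian tails of CV or asymmetry targets), the
  full-study generator clamps them to the feasible boundary; this mildly
  inflates the realized ICC of strongly clamped, low-reliability metrics
  (visible for eyes-closed stride-width CV).

What the generator does *not* emulate: turning, stopping, non-straight
paths, joint kinematics, ground-reaction forces, walkway edge effects,
non-Gaussian metric distributions, or learning/fatigue effects across
trials. Passing round-trip tests therefore demonstrates the correctness of
the extraction and statistical machinery under the stated stochastic
model, not the behavior of any particular hardware's proprietary event
segmentation.

## Numerical and design choices

* Walks are formed from trials (1,2) and (3,4) in recording order; the
  pairing rule for the four recorded trials is not standardized in the
  literature, and consecutive pairing is the natural reading.
* The footfall dialect is plain CSV (UTF-8, header row, seconds and
  centimetres); vendor-proprietary exports are out of scope, as is
  pressure-image processing — events are assumed already segmented.
* Outlier means/SDs are computed once, not iteratively; the rule is
  deliberately surgical (a single planted 5-SD value removes exactly that
  subject's pair).
* Ties and boundaries: ICC bands assign boundary values upward except 0.9
  (good); report rounding is half away from zero; `MS_E = 0` is handled
  through limits, with the p-value reported below machine precision.
* Seeds are part of every generator signature; there is no hidden global
  randomness, and a fixed spec reproduces byte-identical study files.
* Problem sizes used by the test suite: oracle agreement on 200 random
  matrices (n ≤ 10), interval coverage on 1000 replicates of a 60 × 2
  design, calibration recovery on a 5000-subject single-metric cohort,
  step-stream round trips at 200 cycles, and one full 60-subject,
  three-condition study for end-to-end structure and coverage. These
  sizes make the whole suite run in well under a minute of simulation
  time while keeping Monte-Carlo error far below the asserted tolerances.

## Known limitations

* MCIDs are estimated cross-sectionally (between-person regression against
  anchor levels), a proxy that may underestimate longitudinal sensitivity
  to change; no ROC-based or within-person MCID estimation is included.
* No average-measures ICC(·,k), no Bland–Altman analysis, no step-level
  (half-cycle) metrics, cadence, or turning detection.
* Anchor-based estimates depend on which anchors clear the correlation
  gate; metrics whose triangulated MCID rests on the distribution-based
  route alone should be interpreted with caution.
* The absolute-agreement interval is approximate (Satterthwaite); its
  empirical coverage at the study's design (n = 60, k = 2, ICC 0.9) is
  about 94%, inside the asserted [0.93, 0.97] band, but it is not exact.
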