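---
title: "Latent class trajectories of daily step counts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent class trajectories of daily step counts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steptraj)
```

This vignette documents the statistical model behind `steptraj`, the
preprocessing rules, the numerical scheme, what the synthetic generator
does and does not emulate, and the design choices that were genuinely
open.

## The scientific question

Step counts from phone health apps give an objective, year-long record
of physical activity, but simple averages hide the *direction* of
change: two people averaging 7,000 steps/day may be on very different
paths — one ramping up from 5,000 to 9,000, the other declining. In
adults with BMI ≥ 25 kg/m², the question is whether a sustained rise in
daily steps predicts a clinically meaningful weight loss (≥ 3 % of body
weight, the threshold at which obesity-related risk factors measurably
improve) over the year between two annual health checkups, beyond what
the average level predicts.

## Preprocessing

Raw device-day records pass through filters applied in a fixed order:

1. **Checkup pairing.** A participant's first checkup is paired with the
   later checkup whose distance from 12 calendar months is smallest,
   provided the interval lies in 10–14 months (inclusive); otherwise the
   participant is excluded. Month arithmetic is calendar-based with the
   day-of-month clamped to month ends, because checkups are scheduled on
   a calendar, not in 30-day blocks.
2. **Dual-device deduplication.** When both phone platforms report the
   same day, the larger value is kept.
3. **Range filter.** Days with fewer than 200 or more than 50,000 steps
   are dropped (bounds retained) as device artifacts; these are the
   conventional plausibility cut-offs for smartphone step data.
4. **Variance filter.** Participants whose individual daily-step
   variance exceeds `multiplier` × the pooled variance of all retained
   daily records are excluded. The comparison statistic for this filter
   is not uniquely determined by its verbal description ("higher
   variance than all step count data"), so the multiplier is exposed as
   a configuration knob with the literal reading, 1.0, as default; with
   realistic settings it excludes almost nobody.
5. **Weekly averaging.** Week *j* covers days 7(*j*−1)+1 … 7*j* after
   the first checkup; the checkup day itself is excluded (the convention
   had to be fixed somewhere; day-after is the simplest). The weekly
   value is the mean over available days. A participant with any week
   containing no valid day is excluded — a deliberate trade of sample
   size for series completeness. The number of started weeks is capped
   at 56; longer series are truncated rather than excluded, since
   truncation preserves the participant while keeping series lengths
   bounded.
6. **Eligibility.** Pre-checkup BMI ≥ 25 kg/m² and age 40–74 years,
   both boundaries inclusive.

Every stage counts its exclusions, so the pipeline emits a
flowchart-style accounting of where participants went.

## The latent class mixed model

Weekly means $Y_{ij}$ at elapsed week $t_{ij}$ follow, conditional on
latent class $g \in \{1,\dots,G\}$,

$$Y_{ij}\mid g=\beta_{0g}+\beta_{1g}t_{ij}+\beta_{2g}t_{ij}^2+u_i+
\varepsilon_{ij},$$

with random intercept $u_i\sim N(0,\sigma_u^2)$ and residual
$\varepsilon_{ij}\sim N(0,\sigma_\varepsilon^2)$. Class-specific mean
curves are quadratic — flexible enough for rise-then-fall shapes,
parsimonious enough to label. The random intercept and the residual
variance are shared across classes: the model statement gives a single
$u$ and a single $\sigma_\varepsilon^2$, and class-specific variances
would weaken identifiability of small classes; this choice is flagged
here because a class-specific extension is conceptually straightforward.

Integrating $u_i$ out, a series of length $T$ is multivariate normal
with compound-symmetry covariance
$\Sigma=\sigma_u^2 J+\sigma_\varepsilon^2 I$, whose inverse and
determinant have rank-1 closed forms; the package never inverts a dense
$T\times T$ matrix. Class membership is multinomial-logit,
$\pi_g=e^{\gamma_g}/\sum_l e^{\gamma_l}$ with $\gamma_G\equiv 0$ for
identifiability, and estimation maximises the marginal log-likelihood
$\ell(\theta)=\sum_i\log\sum_g\pi_g L_g(Y_i\mid t_i,\theta)$.

### Numerical scheme

* **EM.** The E-step computes posterior responsibilities in log space.
  The M-step updates each class curve by weighted generalised least
  squares against $\Sigma$, the membership intercepts in closed form,
  and the two variance components by the closed-form M-step of the EM
  that treats the random intercept as latent data (conditional mean and
  variance of $u_i$ given the series and class). Every update provably
  increases the marginal log-likelihood, and the full iteration trace is
  stored so ascent can be asserted in tests.
* **Newton polish.** After EM converges (relative log-likelihood change
  below 10⁻⁸, at most 500 iterations), a damped Newton refinement with a
  Marquardt ridge runs on the full parameter vector: the ridge is
  multiplied by 10 after a failed step and divided by 10 after a
  success, with at most 50 steps and only improving steps accepted. The
  polish is applied to the best EM start only — the polish basin equals
  the EM basin, so polishing inferior starts buys nothing.
* **Initialisation.** Per-participant level and linear trend are
  clustered by k-means into $G$ groups, and class curves start from
  pooled quadratic OLS fits within clusters. (Clustering raw
  per-participant *quadratic* coefficients is noticeably worse: with
  short series the curvature coefficient is noise-dominated and drowns
  the informative level dimension.) Additional starts jitter the
  resulting curves under the seed-controlled generator.
* **Conditioning.** Internally the week index is mapped to [0, 1];
  reported coefficients are back-transformed to the week scale.
* **Canonical ordering.** The mixture likelihood is invariant to class
  relabeling, so classes are reported in descending order of mean fitted
  level; modal-assignment ties (a zero-probability event in continuous
  data, but possible in principle) break toward the lowest, i.e.
  largest-mean, class index.
* **Unbalanced series.** Participants may have different $T$; the
  covariance closed form is per participant, and internally participants
  are grouped by series length for vectorised evaluation.

### Choosing the number of classes

Models with $G$ in 1–5 classes are fitted and a model is *admissible*
when every class holds at least 5 % of participants under modal
assignment and every class's mean posterior among assigned members is at
least 0.90. Among admissible models the one with minimal BIC
($-2\ell + k\log N$, $k = 3G+(G-1)+2$) is selected; an exact BIC tie —
which the selection rule must handle even though it will essentially
never occur — breaks toward the smaller $G$. The "approximately 90 %"
posterior condition is implemented as exactly 0.90 by default and is
configurable, since the approximation intended by the verbal rule is not
otherwise pinned down.

### Archetype labels

Fitted curves are named by shape. A curve whose relative range over the
window — (max − min)/mean level — is below 0.10 is `FLAT`; otherwise the
endpoint slopes $s_1=\beta_1+2\beta_2$ and $s_T=\beta_1+2\beta_2T$
decide: both non-negative `UP`, both non-positive `DOWN`, rise-then-fall
`UP_DOWN`, fall-then-rise `DOWN_UP`. The 0.10 threshold separates the
default FLAT archetype (< 1 % change over the year) from the default UP
archetype (≈ 37 % change) by a wide margin on both sides; `DOWN_UP`
exists because the rule must be total even though realistic cohorts
rarely produce it.

## Outcome analysis

The outcome is a relative weight loss of at least 3 % between the two
checkups, inclusive at the boundary. Logistic regression (IRLS via
`glm`) regresses it on trajectory class, dummy-coded with `FLAT` — the
class that mirrors the overall cohort — as reference, adjusted for age
(years), sex, smoking, medication (any of diabetes / hypertension /
dyslipidemia drugs), and mean steps entered per 1,000 steps/day so the
coefficient is readable. Inference is Wald: 95 % CIs use the normal
quantile 1.959964 and p-values come from $b/\mathrm{se}$ against the
standard normal. Rows with missing model variables are dropped. A
sensitivity analysis refits the model on the no-medication subset with
the medication term removed, to separate trajectory effects from
treatment-related weight change. No interactions are fitted — the
analysis is a main-effects adjustment, not an effect-modification study.

## The synthetic cohort generator

Because app-linked checkup cohorts are not public, the generator
produces raw data with the exact latent structure the analysis assumes,
plus the messiness the preprocessing is designed to remove:

* **Classes and curves.** Four archetypes with shares 355/193/2045/185
  out of 2,778 (DOWN, UP/DOWN, FLAT, UP). Each quadratic curve is
  calibrated so its averages over weeks 1–28 and 29–52 equal the
  reference per-period class means (DOWN 8,024 → 6,278; UP/DOWN
  7,347 → 7,763; FLAT 5,243 → 5,270; UP 6,469 → 8,894 steps/day).
  Linear shapes fix $\beta_2=0$; the rise-then-fall class fixes its
  vertex at week 30, giving a marked rise (≈ +2,400 steps) then decline
  (≈ −1,400) while matching both period means and the ≈ 7,541 overall
  mean — an earlier, flatter calibration (vertex at week 40) failed to
  reproduce the identifiable rise-then-fall class the emulated
  conditions require.
* **Noise.** Between-person intercept SD 2,000 steps/day and day-level
  Gaussian SD 2,500 steps/day, chosen once as realistic for adult
  smartphone step data: observed within-class SDs of participant means
  (≈ 2,800) mix level spread with shape variation, and day-to-day
  variability within a person is of the same order as the mean. Daily
  noise also sits at the low end of the realistic range deliberately:
  the < 200-step plausibility filter left-truncates genuine days for
  low-level participants, and larger daily noise would bias their
  weekly means upward materially. Daily values are rounded and floored
  at zero — the weekly *model* is Gaussian, the daily layer is free, and
  flooring keeps the steps non-negative.
* **Messiness.** Days go missing at rate 0.15 (app-sync behaviour);
  recorded days are replaced by artifacts in [0, 199] at rate 0.005 and
  [50,001, 80,000] at rate 0.002, so the range filter has exact ground
  truth; a same-day lower duplicate from the other platform appears at
  rate 0.05, so deduplication has known resolution.
* **Outcome.** The ≥ 3 % loss flag is drawn from a logistic model whose
  class effects are log-odds offsets from FLAT calibrated to
  class-conditional rates of 21.1 / 24.4 / 22.3 / 41.1 % (the UP-vs-FLAT
  offset is ≈ log 2.4); covariate effects are small and centred. The
  post-checkup weight is back-filled from the drawn flag (loss uniform
  in [3 %, 12 %] when positive, (−10 %, 3 %) otherwise): the analysis
  consumes only the binary flag, so a continuous weight-change model
  would add machinery without adding testable structure.
* **Seeding.** One master seed; each participant draws from a
  deterministically derived substream, so the first $k$ participants of
  a large run equal a run of size $k$, and regenerating any subset is
  reproducible.

What the generator does **not** emulate: calendar effects (seasons,
holidays, epidemic waves), app-engagement dynamics (missingness is
independent of behaviour, while real gaps cluster), occupational or
dietary drivers of weight, heavy-tailed daily noise, and any correlation
between covariates and trajectory class. Passing tests therefore show
that the machinery recovers the assumed structure under realistic noise
— not that real cohorts satisfy the model.

## Problem sizes used in the checks

The test suite exercises parameter recovery on one 400-participant,
52-week cohort (modal-assignment accuracy and per-period curve means),
class-number selection on twenty such cohorts (seeds 1–20), likelihood
agreement against dense-matrix oracles on 100 random small instances
($N\le5$, $T\le6$, $G\le3$), and Wald-interval coverage over 500
logistic fits at $n=5{,}000$. These sizes were chosen so each check is
statistically meaningful at desk scale; at $N=400$ the two smallest
archetypes (shares 6.7 % and 6.9 %) occasionally draw below the 5 %
admissibility line, so a minority of selection runs legitimately settle
on fewer classes — the majority outcome is stable at four.

## Known limitations

* The random intercept is the only random effect; secular trends within
  person beyond the class curve (random slopes) are absorbed into the
  residual.
* Class membership does not depend on covariates; the membership model
  is intercept-only by design.
* The variance filter's comparison statistic is a convention (see
  above), and with the default multiplier the filter is nearly inert.
* Wald intervals can be optimistic in small classes; profile-likelihood
  intervals are out of scope.
* Between-person level spread estimated from range-filtered data is
  compressed relative to the generating value, because the < 200-step
  filter truncates low-level participants' days; the class curves and
  classification are essentially unaffected.
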