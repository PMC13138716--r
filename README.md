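# steptraj

Latent class trajectory analysis of daily step counts and weight loss.

`steptraj` is for epidemiologists and health-data scientists who have
roughly a year of daily step-count records from a phone or wearable,
linked to a pair of annual health checkups, and who want to know whether
the *pattern* of physical activity over the year — rather than its
average level — predicts a clinically meaningful (≥3 %) weight loss.
The package provides the full analysis pipeline: cleaning raw device
records, collapsing them to weekly series, clustering the series into
latent trajectory classes, choosing the number of classes, naming the
classes by shape (UP, DOWN, UP/DOWN, FLAT), and estimating adjusted odds
ratios of weight loss by trajectory. A synthetic cohort generator with
known ground truth makes every stage testable without access to any
private cohort.

## The model

Weekly mean steps $Y_{ij}$ of participant $i$ at elapsed week $t_{ij}$
belong to one of $G$ latent classes. Conditional on class $g$,

$$Y_{ij}\mid g \;=\; \beta_{0g} + \beta_{1g} t_{ij} + \beta_{2g} t_{ij}^2
  + u_i + \varepsilon_{ij},\qquad
  u_i \sim N(0,\sigma_u^2),\;
  \varepsilon_{ij} \sim N(0,\sigma_\varepsilon^2),$$

so each class has its own quadratic mean curve while all participants
share a random intercept and residual variance. Marginally each series
is multivariate normal with compound-symmetry covariance
$\sigma_u^2 J + \sigma_\varepsilon^2 I$. Class membership follows a
multinomial logit, $\pi_g = e^{\gamma_g}/\sum_l e^{\gamma_l}$ (with
$\gamma_G = 0$), and the parameters maximise the marginal log-likelihood

$$\ell(\theta)=\sum_{i=1}^N \log\Big(\sum_{g=1}^G \pi_g\,
  L_g(Y_i \mid t_i, \theta)\Big),$$

by EM with a damped-Newton (Marquardt-ridge) polish. Participants are
assigned to the class with the highest posterior probability
$\hat\pi_{ig} \propto \pi_g L_g(Y_i\mid t_i,\theta)$. The number of
classes is chosen by three conditions: every class holds ≥ 5 % of
participants, every class's mean posterior among its members is ≥ 0.90,
and, among models meeting both, BIC is minimal. The binary outcome
(relative weight loss ≥ 3 % between the two checkups) is then regressed
on trajectory class (FLAT as reference) with logistic regression,
adjusted for age, sex, mean steps (per 1000), smoking, and medication,
with Wald confidence intervals and p-values.

## Worked example

Simulate a 400-participant cohort from the default four-archetype
configuration, preprocess it, fit the 4-class model, and estimate the
weight-loss odds ratios:

```r
library(steptraj)

cfg  <- default_config(n_participants = 400, seed = 42)
pop  <- generate_population(cfg)
prep <- preprocess_steps(pop$steps, pop$checkups)
prep
#> Preprocessed step cohort: 391 of 400 participants retained
#> Participant exclusions by stage:
#>   no_shc_pair        0
#>   high_variance      1
#>   empty_week         8
#>   low_bmi            0
#>   age_out_of_range   0
#> Records removed: 6008 duplicates, 6572 out-of-range days

fit <- fit_lcmm(prep$weekly, G = 4, n_starts = 3, seed = 1)
label_classes(fit)[, c("class", "archetype", "n", "share", "mean_posterior")]
#>   class archetype     n  share mean_posterior
#> 1     1 UP           21 0.0537          1.000
#> 2     2 DOWN         49 0.125           1.000
#> 3     3 UP_DOWN      30 0.0767          0.986
#> 4     4 FLAT        291 0.744           0.992
```

The nine dropped participants had either a week with no usable record or
an outlying day-to-day variance; the removed records are same-day
dual-device duplicates (larger value kept) and implausible days
(< 200 or > 50,000 steps). Classes are reported in descending order of
mean level and every class is far above the 0.90 mean-posterior bar.

```r
cohort <- dplyr::left_join(prep$cohort, fit$assignment, by = "participant_id") |>
  dplyr::left_join(label_classes(fit)[, c("class", "archetype")], by = "class") |>
  dplyr::mutate(outcome = weight_loss_flag(pre_weight, post_weight))
summarize_outcomes(cohort)
#>   class       n n_loss pct_loss
#> 1 DOWN       49     12     24.5
#> 2 FLAT      291     71     24.4
#> 3 UP         21      8     38.1
#> 4 UP_DOWN    30      7     23.3
#> 5 Overall   391     98     25.1

fit_logistic(cohort)
#> Weight-loss logistic model (n = 391, reference class FLAT)
#>          term estimate std_error odds_ratio  ci_low ci_high p_value
#>   (Intercept) -0.60060   1.19293     0.5485 0.05293   5.683 0.61464
#>          DOWN -0.02665   0.39400     0.9737 0.44983   2.108 0.94608
#>            UP  0.64002   0.49998     1.8965 0.71182   5.053 0.20052
#>       UP_DOWN -0.12511   0.47819     0.8824 0.34564   2.253 0.79361
#>   ...
```

The `UP` class — rising step counts through the year — reaches a 38 %
weight-loss rate versus 24 % for `FLAT`, with an odds ratio near 1.9 (at
this cohort size the interval is wide; the configured generating
odds ratio for UP is ≈ 2.4). `select_G()` automates the 1–5 class search
with the three admissibility conditions, and `run_pipeline()` chains all
stages and writes every artifact as delimited text. `autoplot()` methods
draw the fitted class curves, the BIC search, and a forest plot of the
odds ratios.

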