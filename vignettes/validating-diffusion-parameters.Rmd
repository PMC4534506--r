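---
title: "Validating diffusion-model parameters by simulation and recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating diffusion-model parameters by simulation and recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`driftval` implements the seven-parameter drift-diffusion model of fast
binary decisions. Within a trial, evidence `X(t)` starts at `z = zr * a` and
follows a Wiener process with drift `v` and infinitesimal standard deviation
`s` between absorbing boundaries at 0 and `a`; the boundary reached first
determines the response (upper = "old", lower = "new") and the response time
is the absorption time plus a non-decision constant `t0`. Across trials the
drift is Normal(`v`, `sv`), the start point Uniform with range `sz`, and the
non-decision time Uniform with range `st`. The diffusion constant `s` is a
pure unit: `v`, `a`, `sv`, `sz` scale linearly in it (`rescale_params()`),
and the package defaults to the `s = 0.1` reporting convention.

All distributional machinery reduces to the first-passage problem of the
Wiener process. The lower-boundary defective density is evaluated with the
standard small-time and large-time series expansions, switching to whichever
needs fewer terms at truncation tolerance `1e-10`; the upper boundary
follows by reflection (`v -> -v`, `zr -> 1 - zr`). The defective CDF uses
the exponentially convergent tail series of the large-time expansion,
truncated adaptively; for arguments so small that more than 1000 terms would
be needed, the absorbed mass is below machine precision and 0 is returned
exactly. Both response types are combined on the *signed RT axis* (lower
boundary RTs negated), giving a single proper CDF per stimulus class
(`wfpt_signed_cdf()`); trial-to-trial variability is integrated out there by
deterministic quadrature — Gauss–Hermite of order 12 over drift,
Gauss–Legendre of order 8 over the two uniform ranges — so that the
degenerate (no-variability) case is exactly the composition of the
per-boundary CDFs, which the tests exploit.

## Simulation

`sample_trials()` draws trials by inverse-CDF sampling on a cached grid of
the signed-RT distribution (4096 points per boundary, horizon set where the
remaining first-passage mass falls below ~1e-9). Each boundary's branch is
inverted separately, so no draw can land inside the non-decision window.
With trial-to-trial variability, each trial first receives its own
(drift, start, non-decision) triple and is then drawn conditionally. An
Euler–Maruyama discretization was used as an independent cross-check of this
sampler during development but is not part of the package: the inverse-CDF
route is exact up to grid interpolation and orders of magnitude faster.

`experiment_design()` and `generate_experiment()` emulate three
recognition-memory studies:

* **exp1** (response bias): 2 groups x 30 participants; 140 old + 70 new
  test trials in the old-bias group, 70 + 140 in the new-bias group; group
  means differ mainly in `zr` (0.66 vs 0.49).
* **exp2** (speed–accuracy): 2 x 30, 140 + 140 trials; `a` (0.09 vs 0.17)
  and `t0` (0.54 vs 0.67 s) differ.
* **exp3** (encoding strength, within-subject): 28 participants x 3
  conditions (not presented / once / twice), 90 trials each; only the drift
  differs (-0.21 / 0.05 / 0.14).

Group means are the published group-level estimates of the corresponding
studies. Values those studies do not print needed a choice, made once:
`t0 = 0.6` s for exp1 (typical for recognition), `zr = 0.55` for exp2
(both groups were old-biased), `a = 0.12`, `zr = 0.5`, `t0` near 0.6 s for
exp3; recovery of the targeted parameter is insensitive to these. The
printed drift SDs of the speed–accuracy study are typographically impossible
(0.56–0.83 on a scale where the means are 0.04–0.17), so plausible values of
0.06–0.11 are used. Between-participant heterogeneity is Normal around the
group mean, truncated to the valid parameter region by rejection; `a`, `zr`,
`t0` are drawn once per participant and shared across conditions, drifts per
condition. Participants' parameters are drawn independently — the source
studies report no between-parameter correlations, and none are asserted. A
4-s response deadline flags (never drops) slow trials as censored; at these
parameter regimes censoring plus the 300/4000 ms trim removes well under 5%
of trials, matching the < 1% exclusion rates the studies report.

What the generator deliberately does **not** emulate: stimulus-level effects
(word concreteness, picture category), serial-position effects, feedback
dynamics within the test phase (the speed group's post-response feedback is
modelled only through its effect on the parameters), and contaminant
processes (lapses, fast guesses). Passing recovery tests therefore show that
the estimators invert the model faithfully under its own assumptions — not
that real data satisfy those assumptions.

## Estimation

**EZ** (`summarize_for_ez()`, `ez_fit()`) inverts accuracy and the
mean/variance of correct RTs in closed form, under `zr = 0.5` and zero
variability. Accuracies of exactly 0, 0.5 or 1 leave it undefined; by
default that is an error (the source studies simply excluded such
participants), with an optional `1/(2n)` edge correction.

**KS** (`ks_statistic()`, `ks_fit()`) computes, per stimulus class, the
supremum distance `T` between the empirical and predicted signed-RT CDFs,
converts it to a p-value with the asymptotic Kolmogorov distribution at that
class's `n` (no small-sample correction), and maximizes the product of
per-class p-values — equivalently minimizes minus the summed log p — with
Nelder–Mead in a transformed unconstrained space (log for `a`, `t0`, `sv`;
logit for `zr` and for the `sz`, `st` fractions of their admissible ranges).
The product combination across classes is a package choice mirroring how
multi-condition KS fitting is conventionally done; the overall reported
statistic is the maximum `T`. Starting values for `v`, `a`, `t0` come from
EZ on accuracy-coded data. Because EZ carries no information about the start
point, the optimizer runs from three deterministic starts (`zr` at 0.5, 0.3,
0.7) and then restarts from the best point until the objective improves by
less than `1e-4`; everything is deterministic, so identical data give
identical fits. Convergence tolerance on the objective is `1e-6`.

**Chi-square** (`chisq_statistic()`, `chisq_fit()`) bins each response
type's RTs at the 0.1/0.3/0.5/0.7/0.9 observed quantiles (six bins per
response, twelve per class — the conventional default of design-matrix
diffusion toolboxes, adopted here as an interpretation since exact defaults
are not printed) and minimizes Pearson `X^2` between observed and
model-expected counts. Two numerical choices matter. First, for the
*reported* statistic, adjacent bins are collapsed until every expected count
reaches 1, keeping `X^2` defined for participants with very few errors;
inside the *objective*, however, expected counts are floored at `1e-10`
instead — collapsing there would let a model that misses the data entirely
merge everything into one bin per response and score near zero. Second,
degrees of freedom are `#bins - #classes - #free parameters` (one sum
constraint per stimulus class). A warning (mirroring the behaviour of the
established toolbox) is emitted when a response type has fewer than 11
trials, where quantile edges are unstable.

`restricted_fit()` fits several conditions jointly with all parameters
shared except one (`v`, `a`, `zr` or `t0`) free per condition — the
theoretically disciplined way to test which process a manipulation moved: a
restriction that misattributes the manipulation reveals itself as misfit.

All fitted models carry a `screened` flag (`goodness-of-fit p <= 0.05`),
and `fit_study()` excludes screened participants from group inference, as
the source studies did. By default a screened participant is dropped from
the affected analysis only; dropping participants lacking estimates in *all*
conditions (the stricter convention of the chi-square toolbox) can be
reproduced by filtering the tidy estimates before `group_inference()`.

## Group inference

`group_inference()` reproduces the inferential toolkit of the validation
studies: per-parameter independent t tests (Student's t, switching to Welch
when an F pretest of variance homogeneity rejects at 0.05 — the studies
report both integer and fractional dfs without stating their rule, so the
pretest is a package decision), one-sample tests against reference points
(e.g. `zr = 0.5`), Cohen's d with the pooled SD, one-way repeated-measures
ANOVA with partial eta squared, Mauchly's sphericity test with
Greenhouse–Geisser correction applied when it rejects at 0.05 (no
Huynh–Feldt, matching the studies' reporting), ordered Helmert contrasts,
and the binomial exceedance probability `P(X >= k | n, alpha)` for counting
significant tests. No multiple-testing correction is applied across
parameters (alpha = 0.05 throughout, as in the source studies).
Per-participant `z/a` is formed by each participant's own `z` and `a`.

## Validation by recovery

`recovery_experiment()` is the package's core loop: simulate a cohort at
known truths, trim, fit, screen, and compare recovered group means with the
truths. `recovery_scenario()` provides the six standard scenarios — the two
response-bias conditions (KS), the two speed–accuracy conditions (KS) and
the two EZ-analysed encoding conditions — with generating truths equal to
the published group means and between-participant dispersion fixed at zero,
so that any discrepancy is attributable to the estimator. In these runs the
trial-level variability parameters are fixed at zero in the fitting design
as well; freeing them (`fit_design(free = c(...))`) is supported and tested
but costs quadrature-grid time. `run_validation()` adds the
convergent-validity check: data generated with only the targeted parameter
differing must show the largest standardized effect on that parameter.

Problem sizes: the standard scenarios use the original cohort sizes (30
participants for the between-subject studies, 26 for the EZ-analysed
within-subject one). The convergent-validity property is exercised in the
test suite at 10 participants per group (14 for the within design) across
seeds 1–5 — cohorts this size already separate target from non-target
effects by a factor of about 1.5–10.

## Known limitations

* The KS start-point estimate is noticeably noisier than the chi-square one
  at ~200 trials (SD across simulated participants ≈ 0.05 vs ≈ 0.03), with
  a small finite-sample downward tendency of a few thousandths; cohort means
  should be interpreted with their Monte-Carlo standard errors.
* The asymptotic Kolmogorov p-value is anti-conservative for very small
  classes; screening decisions below ~20 trials per class inherit that.
* Censoring at the deadline is handled by flag-and-trim, not by fitting
  truncated distributions; at the studied regimes the effect is negligible
  (< 1–5% of trials), but heavy censoring would bias estimates.
* EZ's assumptions (unbiased start, no variability) are imposed, not tested;
  applying EZ to biased-start data measures a blend, which is precisely why
  the response-bias scenario uses the distribution-fitting estimators.
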