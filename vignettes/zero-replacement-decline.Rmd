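---
title: "How zero-replacement constants manufacture a decline effect in lnRR meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How zero-replacement constants manufacture a decline effect in lnRR meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(declineRR)
library(dplyr)
```

## The problem

Meta-analyses of ocean-acidification (OA) effects on fish behaviour summarise
each experiment as a log response ratio,

$$\mathrm{lnRR} = \ln\!\left(\frac{\bar{x}_T}{\bar{x}_C}\right),$$

the log of the treatment mean over the control mean. Many behavioural
outcomes are recorded on bounded scales — percentages (0–100) or proportions
(0–1) — and strong experiments routinely produce means sitting exactly on a
bound: 0% response in one arm, 100% in the other. lnRR is undefined at zero,
so analysts substitute a small constant $c$ for zeros (and, symmetrically,
$\text{bound} - c$ for full-bound means) before taking the ratio.

The choice of $c$ is not innocent. For a 0% vs 100% contrast:

* $c = 1$: $\ln(99/1) = 4.6$
* $c = 0.1$: $\ln(99.9/0.1) = 6.9$ — a 50% inflation
* $c = 0.0001$: $\ln(99.9999/0.0001) = 13.8$ — double again

Because bound-valued records were much more common in the earliest OA
behaviour experiments (strong effects on naive species and highly
concentrated cues) than in later ones, a tiny $c$ selectively inflates early
effect sizes. Pooled by year, that gradient masquerades as an "extreme
decline effect" — apparent evidence that early findings failed to replicate —
when the underlying effects may be flat or declining only gently. This
package implements the full audit pipeline for that artifact: effect-size
computation under configurable replacement policies, rule-based screening,
variance-weighted pooling, trend estimation, a policy-by-screening
sensitivity grid, and a synthetic-corpus generator that makes the artifact's
appearance and disappearance demonstrable without any external data.

## Effect sizes and their sampling variance

`compute_lnrr()` applies the replacement policy to means only (SDs are left
as recorded) and attaches the standard delta-method sampling variance

$$v = \frac{s_T^2}{n_T\,\bar{x}_T^2} + \frac{s_C^2}{n_C\,\bar{x}_C^2},$$

evaluated at the replacement-adjusted means. This is the canonical lnRR
variance used for inverse-variance weighting; the source analyses say only
"variance-weighted", so the canonical form is adopted and checked in the
test suite against a finite-difference delta-method oracle.

Three named policies are compared throughout (`policy_presets()`):

| preset | percentage $c$ | proportion $c$ |
|---|---|---|
| `clements` | 0.0001 | 0.0001 |
| `munday_mid` | 0.1 | 0.001 |
| `munday_whole` | 1 | 0.01 |

All replace the upper bound symmetrically ($100 \to 100 - c$,
$1 \to 1 - c$); the worked arithmetic above (99, 99.9, 99.9999 in the
numerator) only makes sense under that convention, so `symmetric_upper`
defaults to `TRUE`. Proportion-scale records keep their own constant rather
than being rescaled to percentages, because the conventions being compared
prescribe distinct constants per scale. Records with both SDs zero (typical
for 0%-vs-100% contrasts) get $v = 0$ and are flagged unusable for
weighting; pooling floors them at the smallest positive variance in the
corpus rather than substituting an SD, since nothing in the analysed
conventions adjusts variability.

A record on a continuous scale with a mean of exactly zero is a hard error:
replacement policies are defined on bounded scales only, and such records
must be screened out by the analyst.

## Screening

`screen_corpus()` is a declarative rule engine over curation flags carried
by each record: sham treatments (procedural stimuli expected to show no
effect), fluctuating-CO₂ treatments (daily CO₂ cycles that attenuate
behavioural effects), procedural controls, opposite-direction results, and a
minimum CO₂ exposure (the ≥ 800 µatm strong-exposure restriction). Flags are
data, not derived quantities: they encode expert judgements that cannot be
recomputed from the numbers, so both the synthetic generator and any curated
real corpus must populate them. Exclusions are attributed to the first
matching rule in a fixed order (sham → fluctuating CO₂ → procedural control →
CO₂ threshold → opposite direction), which makes the audit deterministic:
input count always equals included count plus attributed exclusions.
Opposite-direction handling is an inclusion toggle, not a sign
transformation — the signed lnRR already carries direction, and the
methodological dispute is about exclusion. The procedural-control rule is an
independent toggle: whether removing 2009–2010 procedural controls should be
reversed in a corrected analysis is a judgement call, so the engine takes no
position. The `clements_like` preset enables it, mirroring the criticised
analysis; the `munday_screened` preset does not.

## Pooling and trend estimation

`yearly_weighted_means()` pools signed lnRR within each publication year.
Fixed-effect mode uses weights $w_i = 1/v_i$; the default random-effects
mode estimates between-study variance $\tau^2$ with the DerSimonian–Laird
moment estimator (truncated at zero) and weights by $1/(v_i + \tau^2)$.
Confidence limits are $\hat\mu \pm 1.96\,\widehat{\mathrm{se}}$. Random
effects is the default because species, life stages and behaviours differ
across studies; fixed mode is retained both for users and as the oracle
anchor (it must match a brute-force $\sum w y / \sum w$ to near machine
precision, and both modes are cross-checked against `metafor`). Which year
column bins records — year online (default, the usual meta-analytic
convention) or year print — is set at load time via `corpus_schema()`.

`loess_trend()` fits a degree-1 local regression of effect-size magnitude
(default; signed lnRR by flag) on year, `span = 0.75`, with 95% percentile
bootstrap bands over records (default 1000 resamples, seed 20221122 — all
exposed as arguments since the analyses being audited specify none).
Magnitude is the default response because the decline-effect claim concerns
the magnitude of effects through time. Yearly summaries come from per-year
pooling rather than a single model with year as moderator; anyone comparing
against externally published yearly means should note that difference.

Decline is summarised by two diagnostics defined by this package (they are
reported as such, not attributed to either disputed analysis):
`decline_ratio`, the ratio of the variance-weighted pooled effect over the
first two observed years to that over the last two (values above 1 indicate
decline); and `weighted_slope`, the inverse-variance-weighted linear slope
of the response on year. The early/late definition is motivated by the
dispute's framing of effects "in 2009 to 2010" versus "after 2015".

## The sensitivity grid

`run_grid()` crosses replacement policies with screening rule sets and runs
the full pipeline in every cell. Each cell's bootstrap seed is derived
deterministically from the master seed and the cell's name
(`derive_seed()`), so cells are independent: permuting the grid or adding a
cell never changes existing cells. Cells that empty the corpus after
screening, or leave too few effects for a trend, are marked degenerate and
the run continues — aggressive rule sets on small corpora are an expected
part of exploration. Two structural facts carry the scientific argument:

* On a corpus with **no** bound-valued means, the policy dimension collapses
  (all policy columns identical) — replacement constants only matter through
  zeros.
* On a zero-rich corpus with constant latent truth, the smallest constant
  shows the steepest decline — the artifact in its purest form.

## What the synthetic generator emulates

`corpus_config()` + `simulate_corpus()` generate a decade of study records
(default 2009–2019, 10 studies/year, 1–3 contrasts each, ≈ 220 records)
with:

* a latent true lnRR magnitude $\mu(\text{year})$ plus between-study
  heterogeneity $N(0, \tau_{\text{true}}^2)$, $\tau_{\text{true}} = 0.3$ by
  default so random-effects pooling has real heterogeneity to estimate. The
  default schedule declines gently from 2.5 to 0.8, echoing the corrected
  reanalysis's picture (strong early effects, moderate late ones, well above
  zero at the end); `schedule_constant()` gives the flat-truth variant used
  in the artifact demonstrations. Latent effects share one sign — the
  treatment/control ratio is centred on $e^{+\mu}$ — so pooled signed lnRR
  recovers $\mu$; `direction_opposite` is a curation flag only.
* arm means placed symmetrically about a geometric-mean baseline $g$ drawn
  from 10–90% of the bound, so the log-ratio of the two arms equals the
  latent effect exactly and typical ratios stay moderate (tiny non-zero
  means are rare, matching the curated corpus where only a handful of
  percentage values fall below 1). Draws whose spread cannot fit inside the
  bounds are resampled, with a bounded retry count and then a hard error.
* zeros imposed by truncation: with the year's zero prevalence (default
  linearly 0.4 → 0.02 across the range, "common early, rare late"), the
  smaller bounded-scale mean is forced to exactly 0 with SD 0, and with
  probability 0.5 the larger arm is forced to the full bound. Truncation of
  a latent continuous mean mirrors how floor/ceiling readings arise in
  behavioural assays and keeps the latent effect interpretable.
* SDs from per-arm coefficients of variation (0.2–0.6), shaped
  $cv\sqrt{m(\text{bound}-m)}$ on bounded scales so variability vanishes at
  the bounds as it does in real assay data; per-arm $n$ uniform on 6–30;
  sham records draw latent effects near zero (SD 0.05), fluctuating-CO₂
  records are attenuated ×0.3, and procedural-control flags occur only in
  the first two years, all matching the screening semantics they exist to
  exercise.
* reported means equal to the latent arm means. An optional
  `sampling_noise` mode perturbs them with delta-method-consistent lognormal
  noise; it is off by default because recomputing the variance from noisy
  means couples weights to errors (the small-denominator instability this
  package studies), visibly biasing pooled means and degrading CI
  calibration — with it on, the generator demonstrates that pathology rather
  than providing a calibrated testbed.

What the generator does **not** emulate: the real corpus's species and
behaviour composition, correlated effects within studies, publication bias,
reporting precision (means are not rounded), or any fit to the deposited
dataset. Passing tests therefore show that the pipeline's logic and the
artifact mechanism are correct, not that any particular real-data estimate
is reproduced.

## Numerical choices

* Variance floor: effects with $v = 0$ are floored at the smallest positive
  $v$ present, and the flooring is logged. Zero variance would mean infinite
  weight; the analysed conventions are silent, so the floor is the least
  informative repair.
* DL truncation: $\hat\tau^2 = \max(0, \cdot)$; whenever $Q \le k - 1$
  random-effects pooling reduces exactly to fixed-effect pooling.
* Loess: degree 1, `surface = "direct"` (exact evaluation, no interpolation
  grid), 80-point evaluation grid; bootstrap resamples that fail to fit
  (degenerate year draws) are dropped from the percentile computation.
* Ties in `compare_trends()` / grid ranking: every configuration attaining
  the maximal decline ratio is flagged steepest.
* Degenerate inputs: empty corpora screen to empty outputs with zeroed
  reports; a year with no effects is omitted rather than emitted as zero;
  trends require ≥ 10 effects over ≥ 3 distinct years and error otherwise.

## Experiment definitions used by the acceptance checks

The package's own calibration experiments, with the problem sizes chosen for
them:

* *Parameter recovery*: 200 corpora at the default size with
  $\mu \equiv 1$, no zeros, $\tau_{\text{true}} = 0.3$ and all flag rates 0
  (sham or attenuated records would contaminate the latent mean being
  recovered). The suite asserts that yearly DL intervals cover $\mu = 1$
  within the 95 ± 3 band — the z-interval's known small-$k$
  anti-conservatism plus mean-dependent weighting keep the rate near the
  band's lower edge — and that the mean weighted slope is centred on zero.
* *Artifact reproduction*: 50 seeds of the `early_zeros_constant_effect`
  fixture ($\mu \equiv 1$, zeros 0.4 → 0.02, flags 0). The decline ratio
  under $c = 0.0001$ exceeds that under $c = 1$ in effectively every seed,
  and the $c = 0.0001$ weighted slope is negative on average despite flat
  truth.
* *Pooling oracle*: 1000 random effect sets against brute-force
  $\sum wy/\sum w$ at $10^{-12}$.

## Worked example

```{r example, eval = FALSE}
fx <- make_fixture("early_zeros_constant_effect", seed = 1)
grid <- run_grid(fx$corpus, boot_reps = 200,
                 rulesets = preset_rulesets()["munday_screened"])
tidy(grid)
autoplot(grid)
```

## Known limitations

* The decline diagnostics are this package's own summaries; no published
  decline statistic exists to reproduce exactly.
* DL random-effects with z-intervals under-covers slightly at small $k$;
  Knapp–Hartung-type adjustments are deliberately out of scope because the
  audited analyses use plain variance-weighted means.
* No meta-regression with moderators, publication-bias tests, or multilevel
  (study-level) random effects — plausible extensions, none performed in the
  analyses being audited.
* Real curated corpora must supply the screening flags; the engine cannot
  re-derive expert judgements from free text.
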