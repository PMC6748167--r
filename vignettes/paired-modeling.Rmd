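---
title: "Paired modeling of 5-mC and 5-hmC: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired modeling of 5-mC and 5-hmC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualmark)
```

## The measurement problem

Sodium bisulfite (BS) conversion cannot distinguish 5-methylcytosine
(5-mC) from 5-hydroxymethylcytosine (5-hmC): both marks resist
conversion, so a BS experiment measures the *total* modified proportion
$\beta_{mC} + \beta_{hmC}$ at each cytosine. Oxidative bisulfite (oxBS)
first oxidizes 5-hmC so that only 5-mC survives conversion; the oxBS
channel therefore measures $\beta_{mC}$ alone. With the unmodified
fraction $\beta_C$, the three proportions live on a simplex:

$$\beta_{mC} + \beta_{hmC} + \beta_C = 1.$$

Pairing the two channels identifies both marks at base-pair resolution,
at the cost of making the two estimates statistically interdependent:
5-hmC is only ever obtained *through* 5-mC, by subtraction or by
maximum likelihood.

## Estimating (5-mC, 5-hmC) per probe and sample

`estimate_paired_mle()` maximizes the joint binomial log-likelihood

$$\log B(m_{bs};\, n_{bs},\, \beta_{mC}+\beta_{hmC}) +
  \log B(m_{ox};\, n_{ox},\, \beta_{mC})$$

over the constraint set $\{\beta_{mC} \ge 0,\ \beta_{hmC} \ge 0,\
\beta_{mC}+\beta_{hmC} \le 1\}$. When the channel proportions are
concordant the optimum is the plug-in pair
$(m_{ox}/n_{ox},\ m_{bs}/n_{bs} - m_{ox}/n_{ox})$, returned exactly in
closed form. When sampling noise makes the oxBS proportion exceed the
BS proportion, the optimum sits on the $\beta_{hmC}=0$ boundary, where
the problem collapses to a single-proportion binomial MLE with the two
channels pooled: $\hat\beta_{mC} = (m_{bs}+m_{ox})/(n_{bs}+n_{ox})$.
The boundary case is solved in closed form rather than numerically —
the constrained problem at $\beta_{hmC}=0$ *is* a pooled-proportion
problem — and flagged, because these clipped zeros are the source of
the characteristic zero-enrichment of estimated 5-hmC.

Two conventions deserve explicit mention:

* **Counts from intensities.** Array intensities are not integer
  counts; beta-value inputs are converted as $m = \mathrm{round}(\beta
  \cdot n)$ with the user-supplied per-entry totals $n$. This preserves
  the binomial form of the likelihood while accepting array-style
  inputs. Whether the original analysis consumed counts or intensities
  is not documented; this convention is ours.
* **Boundary value of 5-mC.** When 5-hmC is clipped to zero we report
  the *pooled* proportion for 5-mC, not the oxBS proportion. Other
  conventions exist; the flag lets users treat these entries specially.

Missing inputs and zero totals propagate to missing calls rather than
erroring: the pipeline's missingness filter is the designated handler.

## The separate ("traditional") models

The conventional analysis fits, per probe, one beta regression to each
mark:

$$y \sim \mathrm{Beta}(\mu\phi,\ (1-\mu)\phi), \qquad
  \mathrm{logit}(\mu) = \beta_0 + \beta_1\,\mathrm{group} +
  \beta_2\,\mathrm{glial} + \beta_3\,\mathrm{age},$$

with a single precision $\phi$ per probe-model (log link, intercept
only — the mean model carries the science; nothing in the design
suggests regressing dispersion on covariates). `fit_betareg()`
maximizes this likelihood by BFGS with analytic gradients from a
logit-scale least-squares start and a method-of-moments precision;
standard errors come from the inverse observed information. Beta values
of exactly 0 or 1 are undefined under the beta likelihood, so responses
pass through `squeeze(y, 1e-6)` first. The squeeze runs *after* the
low-mean filter (below), which removes most — but not all — boundary
values.

## The paired repeated-measures model

The package's central model treats the two marks at a probe as repeated
measures of one outcome, "DNA modification", with a long data layout of
two rows per sample. Per probe:

$$y_{is} \sim \mathrm{Beta}(\mu_{is}\phi,\ (1-\mu_{is})\phi), \qquad
  \mathrm{logit}(\mu_{is}) = x_{is}^\top\beta + u_s, \qquad
  u_s \sim N(0, \sigma_b^2),$$

where $s$ indexes samples, $i \in \{\text{5mC}, \text{5hmC}\}$, and the
fixed effects expand the full factorial
`group * mod_cat + glial_proportion + age`. The random intercept $u_s$
absorbs the within-sample correlation between the two marks — both the
biological coupling (5-hmC is made from 5-mC) and the statistical
coupling introduced by the shared estimation step. The
group-by-modification interaction is the quantity of interest: it asks
whether the two marks respond *differently* to the condition. Under
treatment coding (reference group, 5-mC as reference level) a positive
interaction means a shift toward a greater proportion of 5-hmC in the
non-reference group; swapping either reference flips the sign.

Two modeling choices were genuinely open:

* **Main effects.** A model with the interaction but no main effects is
  not invariant to coding, so the full factorial is fitted even though
  an interaction-only form is sometimes written down.
* **What the random effect groups.** With exactly two observations per
  sample per probe, a per-sample intercept within each per-probe model
  is the only grouping that pairs the two marks; it is what the
  repeated-measures construction requires. (A global per-probe effect
  across the genome would address a different question entirely.)

### Estimation

The marginal likelihood integrates $u_s$ out per sample. We use
adaptive Gauss–Hermite quadrature with 9 nodes by default: for each
sample the integrand's mode and curvature are found by a safeguarded
Newton search (compiled code, warm-started across likelihood
evaluations), and the nodes are recentered and rescaled there. The
outer optimization is BFGS over $(\beta, \log\phi, \log\sigma_b)$ with
compiled central-difference gradients; $\sigma_b$ is floored at
$10^{-6}$ to avoid boundary pathologies. Standard errors come from the
numerical Hessian at the optimum.

Three properties anchor the implementation (all are tested):

* with $\sigma_b$ fixed at 0 the marginal likelihood reduces *exactly*
  (to $10^{-8}$) to the independent beta-regression likelihood;
* estimates move by less than $10^{-3}$ between 5 and 15 quadrature
  nodes at the default study size;
* fits agree with an independent Laplace-approximation fitter
  (glmmTMB) to high accuracy — that package serves only as a
  cross-check, never as the implementation.

An optional second random intercept per batch is available
(`include_batch_re = TRUE`), integrated by nested quadrature
(non-adaptive outer nodes over the batch effect, adaptive inner
quadrature per sample). It is off by default: in the reference analysis
batch did not survive model selection, and most users will have
batch-corrected upstream.

### Testing the interaction

`interaction_test()` reports a two-sided Wald z-test of the interaction
coefficient by default, with the direction label from the coefficient
sign (exact zeros are "none"). A 1-df likelihood-ratio test is
available via `fit_paired(..., lrt = TRUE)` and
`interaction_test(fit, type = "lrt")`, and as
`model: interaction_test: lrt` in the pipeline configuration.

**Calibration caveat.** At the reference design (13 + 22 samples) Wald
tests on maximum-likelihood fits are mildly liberal: across large
simulations the interaction test's true size at $\alpha = 0.05$ is
about 0.062 ± 0.004, and the separate-model Wald 95% interval covers
about 93.4% of the time. This is inherent small-sample ML behavior, not
an implementation artifact — an independent fitter reproduces the same
p-values to five decimals. The LRT option is somewhat better calibrated
in spot checks; users with small designs who need exact size should
prefer it or use stricter thresholds.

## Filtering pipeline

`run_study()` applies the stages in a fixed order: detection-p
filtering (samples with more than 10% failed probes are excluded first,
then any probe failing in any remaining sample), blacklist removal
(cross-reactive/SNP probes, supplied by the user), MLE estimation, the
low-mean filter, and the missingness filter. Order matters: the
low-mean rule — drop a probe when its across-sample mean *estimated*
5-mC **or** 5-hmC beta is below 0.1 (strict `<`) — operates on
estimated 5-hmC and therefore must follow estimation. This filter is
what removes the zero-inflated bulk of the 5-hmC distribution before
beta-regression modeling; it is a probe-level rule, although it is
occasionally described sample-wise elsewhere. Every stage contributes
to a conserved waterfall: input = final + removals, checked on every
run.

Default significance calling mirrors the reference analysis: separate
models at lenient raw $p < 0.001$ (the regime in which the two
approaches are compared), the paired interaction at FDR < 0.05
(Benjamini–Hochberg, computed per channel with non-converged probes
excluded from $m$). Both are configurable; FDR < 0.10 separate calling
is one config line away.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws, per probe and sample: a shared intercept
$u \sim N(0, \sigma_b^2)$ entering both marks' logit means (drawn
independently per probe×sample, matching the fitted model's assumption
and making probes independent replicates); true proportions from beta
distributions at precision $\phi$; exact 5-hmC zeros with a configured
probability; then BS and oxBS channels as binomial draws at per-entry
coverage. Defaults are fixed once as the reference study conditions:

| parameter | default | rationale |
|---|---|---|
| group sizes | 13 / 22 | entorhinal-cortex case–control design after one sample exclusion |
| coverage | NB, mean 100, size 20, floor 10 | array-scale precision, not sequencing depth |
| 5-mC means | uniform 0.30–0.60 | post-filter CpG methylation range |
| 5-hmC means | uniform 0.12–0.25 | brain-tissue 5-hmC levels above the 0.1 rule |
| $\phi$ | 30 | between-sample beta-value dispersion typical of arrays |
| $\sigma_b$ | 0.5 | moderate within-sample coupling of the marks |
| zero inflation | 0.2 | raw 5-hmC exact-zero rate; a free parameter, no published estimate exists |
| covariates | age 60–95, glial 0.3–0.7; logit effects ±0.01/yr and ±0.5–1.0 | adjusted-for nuisance structure; glial sign reflects neurons being 5-hmC-rich |

Planted effect scenarios follow the two canonical failure modes of
separate-mark analysis: scenario A (a clear 5-mC decrease with a
smaller 5-hmC increase — only 5-mC reaches significance separately)
and scenario B (an equal-and-opposite transfer leaving total
modification constant — *neither* mark reaches significance
separately, only the balance moves). Scenario B's 5-hmC effect is
derived per probe from the constant-total constraint on the proportion
scale and then mapped back to the logit scale; its default 5-mC effect
(−0.25 logits) was chosen so the expected per-mark Wald $|z|$ is near
1 at the reference design, i.e. each mark is individually
nonsignificant by construction. Simplex violations after the
independent beta draws are resolved by proportional rescaling, which
preserves the 5-mC : 5-hmC ratio.

Calibration experiments (type-I error, CI coverage) and the
constant-total power comparison are run on the model scale —
beta-distributed marks with the random intercept, no channel noise —
emulating the *post-filter* regime, since the low-mean filter exists
precisely to remove boundary zeros before modeling, and since the
scenario-B claim concerns the marks themselves. The sensitivity
experiment runs the full loop: generate channels → estimate by MLE →
model.

A channel-noise effect uncovered while validating the power
comparison deserves emphasis: the two estimates at a probe share the
oxBS draw ($\hat\beta_{mC} = p_{ox}$, $\hat\beta_{hmC} = p_{bs} -
p_{ox}$), so their measurement errors are *anti*-correlated, and the
interaction contrast ($\approx p_{bs} - 2p_{ox}$) doubles the oxBS
noise. At array-scale coverage this erodes most of the paired test's
power advantage over the separate 5-hmC test for constant-total
shifts (from roughly 0.93 vs 0.49 on the marks themselves to
near-parity on the estimates; both regimes are reported by
`scripts/acceptance.R`). Higher coverage, or measurement designs that
estimate the marks independently, restore the advantage.

A related subtlety concerns covariates whose effects differ *between
the marks* — glial proportion is the canonical example, since neurons
are 5-hmC-rich relative to glia. The model (matching the reference
formula) adjusts covariates as main effects only, so the part of a
mark-specific covariate effect that differs between marks is not
absorbed; whatever group imbalance the covariate happens to have in a
given study then loads onto the group-by-modification interaction as
a bias shared by *every probe*. In generator experiments with the
default mark-specific glial and age effects this produces
dataset-level power swings of ±0.2 or more between covariate draws.
Analysts worried about this in real data should consider
covariate-by-modification interaction terms (add them via the long
data and a custom design); power experiments in this package's
acceptance script therefore use either per-replicate covariate draws
or the model-scale generator. The generator does *not*
emulate probe-type chemistry, spatial correlation along the genome,
cell-type mixtures, or batch structure; passing tests say nothing
about those features of real data. One consequence of channel noise
worth knowing: a true-zero 5-hmC entry re-estimates as a small
positive value whenever the BS draw exceeds the oxBS draw, so the
estimated zero fraction is *below* the structural zero-inflation rate
(clipping of small positive truths adds some back); zero-enrichment is
preserved qualitatively, not numerically.

## Numerical choices

* Squeeze epsilon $10^{-6}$; applied after filtering. Clipped 5-hmC
  zeros that survive the probe-mean filter become high-leverage
  observations under the beta likelihood (logit ≈ −13.8); at default
  simulation conditions roughly 3% of entries are affected, which
  measurably inflates the interaction test's rejection rate in full
  channel-loop simulations. Real studies with appreciable 5-hmC above
  the filter threshold are less affected; a larger epsilon blunts but
  does not remove the leverage.
* Beta-regression optimization: BFGS, relative tolerance $10^{-8}$,
  200 iterations, analytic gradients. Paired model: BFGS, relative
  tolerance $10^{-9}$, 500 iterations, compiled finite-difference
  gradients (step $10^{-5}$).
* BH adjustment evaluates `m/j * p` in that association order so
  results are bit-identical to `stats::p.adjust(method = "BH")`, which
  serves as an independent oracle in tests alongside the literal
  quadratic-time step-up formula.
* Ties in BH are handled by the cumulative-minimum construction
  (stable); zero coefficients get direction "none" so sign tallies are
  deterministic.
* Problem sizes in the test suite: 500 signal pairs against the grid
  oracle, 1000 replicates for coverage, 2000 for type-I error, 500
  probes for the power comparison — chosen to resolve each property
  within useful Monte-Carlo error on a single CPU.

## Worked example

```{r example, eval = FALSE}
study <- run_study(list(
  simulation = list(n_probes = 60, zero_inflation = 0,
                    effects = list(list(probes = 1:10, scenario = "B"))),
  seed = 7))
study$filter_report
study$comparison
head(study$results)
```

## Known limitations

* Wald inference is mildly liberal at small $n$ (see above); the LRT
  option mitigates this at double the fitting cost.
* The boundary convention for $\beta_{mC}$ under clipping is one of
  several defensible choices.
* Per-probe models are fitted independently; no information is shared
  across probes (no empirical-Bayes shrinkage of $\phi$ or
  $\sigma_b$).
* Region-level (DMR-style) aggregation, zero-inflated beta likelihoods
  and the ratio-of-correlated-gammas alternative are out of scope.
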