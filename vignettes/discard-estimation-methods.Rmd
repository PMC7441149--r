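---
title: "Estimating fisheries discards: models, tiers and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fisheries discards: models, tiers and uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

discardbench estimates the rate and magnitude of fisheries discards — the
portion of the catch returned to the sea whole — from landings statistics,
when direct discard observations exist for only a minority of fisheries.
This vignette is the package's own account of its methods: the model, the
assumptions behind each step, the tunable parameters, and what the
validation studies do and do not demonstrate.

## The unit of analysis and the rate/level identity

A *fishery* is a flag state x gear type x target species group x FAO Major
Fishing Area combination. Retained landings are reported per country,
species item, area and year; an allocation-key table distributes each such
cell over the fisheries of the same flag state and area (fractions summing
to 1 per cell), and the allocated tonnage is averaged over the assessment
period (default 2010–2014) to give each fishery's mean annual landings
$L_i$.

The *discard rate* is defined against total catch: with discards $D$ and
landings $L$, $r = D/(D+L)$. Conversion between the two directions is
therefore nonlinear in $r$:

$$D = L \frac{r}{1-r},$$

the unique solution of the defining equation. A rate of 0.5 means discards
equal landings. Rates are capped at `rate_cap` (default 0.99) so the
conversion stays finite; the cap is far above any empirically plausible
gear-level rate and exists purely as a numerical guard. Landings are
treated as known constants — all interval width on discard totals comes
from discard-rate uncertainty. This mirrors how total-catch intervals are
conventionally reported in global discard assessments: catch bounds equal
fixed landings plus the discard-level bounds.

## Three-tier rate assignment

Every fishery receives its discard rate from the first applicable tier:

1. **observed** — the fishery has its own discard-rate records; the rate is
   their weighted mean (weights default to 1). Multiple records are never
   silently deduplicated upstream; combining happens only here.
2. **policy** — a constant rate attached to a flag state (optionally
   restricted by gear and/or area), for countries whose rates come from
   expert estimates or discard bans. The most specific matching rule wins
   (flag+gear+area over flag+gear over flag); ties of equal specificity are
   an error rather than an arbitrary choice.
3. **gear_model** — a Bayesian zero-inflated Beta model of the gear type's
   discard rate, fitted to all observed rates for that gear, supplies the
   rate for fisheries with neither records nor policy coverage.

Tiers 1 and 2 are deterministic (constant across Monte Carlo draws); tier 3
carries posterior uncertainty.

## The zero-inflated Beta gear model

Observed discard rates are proportions in $[0, 1)$ with a genuine point
mass at zero (some fisheries discard nothing). The model is a mixture:
zero with probability $zi$, otherwise Beta with mean $\mu$ and precision
$\phi$ (shapes $\mu\phi$ and $(1-\mu)\phi$). The expected rate is
$(1-zi)\mu$. Observed rates of exactly 1 are outside the support (the
model is zero- but not one-inflated) and are clamped to $1-10^{-6}$ with a
warning.

Fitting is intercept-only per gear, independent across gears — no partial
pooling, since each gear is modelled as its own population. Sampling runs
on the unconstrained scale ($\mathrm{logit}\,zi$, $\mathrm{logit}\,\mu$,
$\log\phi$) with weakly informative priors: Normal(0, 1.5) on both logits
(near-uniform on the probability scale while discouraging the boundaries)
and Normal($\log 10$, 1) on $\log\phi$, centring the Beta component on
moderate dispersion. A `zi_prior = "flat"` option replaces the logit prior
with a uniform on $[0,1]$; it exists for calibration checks, because with a
flat prior the zero-count marginal posterior is conjugate
(Beta($k+1$, $n-k+1$) for $k$ zeros in $n$), giving an exact external
standard the sampler must reproduce.

The sampler is a self-contained adaptive random-walk Metropolis:
component-wise proposals, per-parameter step sizes adapted in batches of 50
during warmup only (towards the component-wise optimal acceptance rate of
0.44, within the commonly cited 0.3–0.5 band), frozen afterwards so the
post-warmup chain is a valid Markov chain. Defaults are 4 chains of 2,000
iterations with 1,000 warmup. Because the zero-inflated Beta likelihood
factorizes, the weighted log-likelihood reduces to four sufficient
statistics, making each posterior evaluation O(1) in the number of
observations; this is why hundreds of replicate fits are cheap enough for
the simulation studies below. Convergence is declared when every
parameter's split-$\hat R$ is at most 1.01; effective sample sizes use the
paired-lag (Geyer) truncation. With small samples and short chains
split-$\hat R$ hovers around this strict threshold even for healthy chains,
so replicate simulation studies run with `allow_nonconverged = TRUE` and
record diagnostics instead of aborting.

## Propagation and aggregation

With $n$ draws per fishery (default 4,000), draw $j$ of fishery $i$ gives
discards $D_{ij} = L_i r_{ij}/(1-r_{ij})$. For a stratum $s$ (global, or
by area, gear, target group), the level draw is
$\mathrm{level}_{sj} = \sum_{i \in s} D_{ij}$ and the rate draw is
$\mathrm{level}_{sj}/(\mathrm{level}_{sj} + L_s)$ with the stratum's fixed
landings $L_s$ — so the rate/level identity holds exactly per draw, and
per-draw global totals equal the sum over any exhaustive stratification to
machine precision.

Rates are summarized by the mean and a 95% *highest density interval*
(shortest contiguous window over the sorted draws containing
$\lceil 0.95\,n\rceil$ values; among ties, the smallest lower bound);
levels by the mean and a 95% *equal-tailed* interval (type-7 interpolated
quantiles). This split mirrors how rates (skewed, boundary-adjacent) and
tonnages are conventionally reported. Two numerical notes:

* The HDI is never wider than the *discrete* symmetric-tail window whose
  endpoints are order statistics, because that window always contains at
  least $\lceil 0.95\,n\rceil$ draws — this is the width-dominance
  property the tests assert. The *interpolated* equal-tailed interval can
  occasionally be a hair narrower than the HDI on finite draws (it may
  contain one or two fewer draws), so dominance against it is not an exact
  law and is not asserted.
* Published global assessments have printed a rate HDI and a level CI that
  are not images of each other under the rate/level identity. This package
  makes no attempt to reconcile such pairs: its rate and level intervals
  are internally consistent by construction (both summarize the same draw
  set), and both are reported.

Within a gear, tier-3 fisheries share the same posterior parameter draw in
each Monte Carlo draw (comonotone rates). This is the faithful reading of
applying "a global gear-specific rate" to unobserved fisheries, and it is
the conservative choice: perfect between-fishery dependence maximizes the
variance of stratum sums; an independent-draw alternative would narrow
intervals.

### What the tier-3 interval means: two modes

`assign_rates()` offers two imputation modes for gear-model fisheries.

* `"gear_mean"` (default): each draw imputes the gear-level expected rate
  $(1-zi)\mu$ from one posterior draw. Intervals quantify uncertainty
  about the *gear mean* — the estimand used when a single gear-wide rate
  is applied to unobserved fisheries.
* `"posterior_predictive"`: each fishery additionally receives an
  individual zero-inflated Beta draw under the sampled parameters.
  Intervals then include the between-fishery variability of the
  unobserved fisheries, which is the correct uncertainty for the
  *realized total* of a finite set of fisheries, and are accordingly
  wider.

The distinction matters for validation: in a synthetic world whose
tier-3 fisheries have individually drawn true rates, the realized global
rate fluctuates around the gear means, so only the posterior-predictive
intervals can be calibrated against it. The package's end-to-end coverage
study therefore runs in posterior-predictive mode, while `gear_mean`
remains the default analysis setting.

## The synthetic world

`simulate_world()` generates the four input tables with the statistical
structure the estimator assumes, plus embedded ground truth. Default
conditions: 150 fisheries over 12 flag states, 8 gear types, 10 areas and
6 target groups; log-normal mean annual landings
($\log L \sim N(\log 5000, 1.5^2)$, a heavy-tailed magnitude spread);
five period years with mild year-to-year noise (log-sd 0.1, renormalized
so the period mean is exact); target tier catch shares 20% observed /
45% policy / 35% gear-model. A paper-scale run simply raises
`n_fisheries`; the default size keeps replicate studies fast while leaving
tier structure, heavy-tailed weights and gear imbalance intact.

Design choices worth stating explicitly:

* True per-fishery rates are inverse-CDF draws from the gear's
  zero-inflated Beta (all uniforms drawn before the parameter map), so
  raising a gear's true $\mu$ at a fixed seed moves that gear's rates — and
  any stratum level containing it — monotonically.
* Observation noise is logit-Normal (sd 0.15) with exact zeros preserved:
  noisy rates stay in $[0,1)$ and the zero-inflation structure survives
  observation. Real discard records come from heterogeneous studies whose
  error structure is unknown; a single bounded noise model is an idealized
  stand-in.
* Policy countries' fisheries carry their policy rate as truth, i.e. the
  policy tier is treated as accurate by construction. Pipeline error in
  these studies therefore comes from observation noise (tier 1) and
  finite-sample inference (tier 3) only. Real expert estimates and ban
  assumptions carry un-modelled error, so real-data intervals inherit an
  optimism the synthetic study cannot detect.
* Observed fisheries are selected per gear (largest shares first within a
  random order, stopping nearest the target share), guaranteeing every
  gear that appears in tier 3 has at least one observation to fit on.

Consequently, passing recovery tests shows the estimator is internally
correct and calibrated *under its own assumptions*; it does not validate
the allocation keys, the policy rates, or the representativeness of real
observation programmes.

## Validation studies and problem sizes

The test suite includes, at sizes chosen to keep a full run in minutes:

* exact oracle checks (weighted-mean arithmetic, conversion identities,
  brute-force HDI scans over 500 random draw sets of 20–5,000 draws);
* parameter recovery at $n = 500$ observations for three contrasting gear
  regimes (posterior means within 0.05 for $zi$ and $\mu$, 30% for $\phi$);
* simulation-based calibration: 200 replicates with parameters drawn from
  the priors and 40 observations each (4 chains x 1,000 iterations),
  requiring 95% HDI coverage of the true mean rate in $[0.90, 0.99]$;
* end-to-end recovery: 100 replicate default worlds, 500 draws each, with
  the global-rate HDI (posterior-predictive mode) required to cover the
  realized truth in at least 90, and per-draw mass conservation across
  stratifications to $10^{-9}$ relative.

## Known limitations

* Unreported catch is not modelled; estimates condition on reported
  landings.
* Species and size composition of discards is out of scope.
* The rate-to-level conversion assumes discards scale linearly with total
  catch within a fishery.
* Policy-tier rates carry no uncertainty; if expert estimates are biased,
  stratum intervals will not reflect it.
* Independent per-gear fits ignore cross-gear similarity; gears with very
  few observations lean on the priors (visible in wide posteriors and
  recorded effective sample sizes).
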