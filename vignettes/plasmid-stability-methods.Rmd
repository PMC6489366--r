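---
title: "Quantifying plasmid stability under post-segregational killing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plasmid stability under post-segregational killing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pskstab)
```

## The problem

Engineered plasmids are lost at cell division: occasionally every copy ends
up in one daughter, and because the plasmid burdens its host the plasmid-free
lineage then outgrows the engineered one. Post-segregational killing (PSK)
systems counter this. Toxin–antitoxin (TA) cassettes (hok/sok, axe/txe) kill
a daughter cell shortly after it loses the plasmid; secreted bacteriocins
(e.g. microcin-V) instead police the whole culture, killing any non-immune —
that is, plasmid-free — cell continuously. `pskstab` implements a compact
dynamical model of these three situations, maps it onto the two experimental
designs actually used to assay stability (serial dilute-and-regrow passaging
and a single-passage competition dilution series), and estimates the model's
parameters from data with a hierarchical Bayesian sampler. Companion modules
turn raw measurements into model inputs: a mixture-model gate converts
flow-cytometry events into plasmid-bearing fractions, and a Gaussian-process
regression estimates maximal specific growth rates from OD curves.

## The model

Two populations, plasmid-bearing $X^+$ and plasmid-free $X^-$, grow
exponentially in time units $\tau$ of plasmid-free e-foldings:

$$\frac{dX^+}{d\tau} = \gamma X^+ - \lambda\gamma X^+$$

TA / no-PSK:
$$\frac{dX^-}{d\tau} = X^- + \lambda\gamma X^+ - \omega\lambda\gamma X^+$$

bacteriocin:
$$\frac{dX^-}{d\tau} = X^- + \lambda\gamma X^+ - 2\omega X^-$$

with three parameters:

* $\lambda \in [0,1]$ — probability that a dividing plasmid-bearing cell
  produces a plasmid-free daughter; linked to mean copy number $n$ by
  $\lambda = 2^{1-n}$ (`copy_number_to_loss_prob()`), the chance that random
  segregation sends all copies one way.
* $\gamma > 0$ — ratio of plasmid-free to plasmid-bearing doubling time;
  $\gamma < 1$ means the plasmid slows growth.
* $\omega \in [0,1]$ — killing efficacy. For TA it discounts the loss influx
  (killing intercepts newly plasmid-free daughters); for bacteriocins it is a
  continuous death pressure $2\omega$ on all plasmid-free cells. $1-\omega$
  is the survival probability of a (newly) plasmid-free cell.

The system is linear, so `closed_form_solution()` is exact: $X^+$ grows as
$e^{\gamma(1-\lambda)\tau}$ and $X^-$ is the forced solution with exponent 1
(TA) or $1-2\omega$ (bacteriocin). When the two exponents tie exactly we use
the resonant $\tau e^{a\tau}$ form rather than perturbing parameters. All
fraction computations are carried out relative to the dominant exponent so
nothing overflows even at hundreds of passages. `asymptotic_fraction()`
gives the long-run plasmid-bearing fraction — for a bacteriocin strong
enough that $1-2\omega < \gamma(1-\lambda)$ the populations coexist at a
stable fraction, the qualitative signature that distinguishes policing from
TA killing.

Three printed-model choices we keep verbatim rather than "fixing": the
plasmid-free per-capita rate is 1 (an e-folding, not a doubling, per unit
$\tau$ — `tau_to_generations()` rescales for reporting, and fraction
dynamics are invariant to common time rescaling); the bacteriocin equation
reuses the same $dX^+/d\tau$; and the bacteriocin death term keeps its
factor 2, allowing net decline of $X^-$ when $2\omega > 1$.

## Passaging and competition designs

A stability assay dilutes the culture $D$-fold daily and regrows it.
`passaging_protocol()` defaults to $D = 1000$ and regrowth time
$\tau = \ln D$ — the time a culture growing at the plasmid-free rate needs
to recover its pre-dilution density, making the passage self-consistent with
the model's units. (The actual dilution factor of the original assay is not
stated anywhere we could find; $D$ is configurable and fraction dynamics
depend on it only through $\tau$.) Deterministic dilution preserves the
fraction exactly, and because the flow is linear the fraction at passage $p$
equals the undiluted solution's fraction at $p\,\tau$ — the inference
forward model exploits this. Saturation/stationary phase is not modelled;
the model is pure exponential growth, a simplification inherited from the
model itself.

`predict_competition()` handles the restoration design: mixtures of
plasmid-bearing and plasmid-free cells at a series of starting fractions,
sampled after one passage. A policing bacteriocin pushes every mixture back
toward fully plasmid-bearing within one passage; a TA system cannot, and the
burden $\gamma < 1$ drags every mixture down.

## Synthetic data: the stated world

No raw dataset accompanies the study this package emulates (the archive
reference is unresolvable), so `hierarchical_truth()` +
`generate_loss_curves()`, `generate_events()` and `generate_growth_curve()`
define a synthetic world with known truth:

* **Loss curves**: 9 replicates × 37 daily passages, matching the fluorescent
  plasmid assays. Replicate parameters vary around population means on
  transformed scales (logit $\lambda$, log $\gamma$, logit $\omega$) with
  normal deviations — bounds are respected automatically and the structure
  matches the inference hierarchy. Default scales (0.3, 0.05, 0.3) produce
  the visually tight-but-distinct replicate spread seen in such assays;
  the true replicate variance of the original data is unreported, so these
  are deliberate, conservative choices. Observation noise is binomial over
  the $10^4$ cytometry events per sample, or Beta with precision $\phi$
  (default 500) to emulate day-to-day overdispersion; an optional binomial
  bottleneck resamples the culture at each dilution.
* **Cytometry events**: log10 fluorescence is a two-mode location-scale
  mixture (autofluorescence mode at 2.0 decades, reporter mode
  `separation_decades` higher, within-mode sd 0.25), scatter channels are
  log-normal, and a debris component sits at low scatter. Labels travel with
  events so gates can be benchmarked. No spillover/compensation artifacts
  are simulated.
* **Growth curves**: logistic growth after a lag, observed every 10 min with
  multiplicative log-normal noise. The exit from lag is softplus-smoothed
  over 15 min (about half a doubling time) because real cultures resume
  growth gradually; a hard corner in log-OD is both unrealistic and
  needlessly hostile to any derivative estimator.

A green test on this world establishes that the pipeline recovers what the
generators put in — not that the generators capture every feature of real
plate-reader or cytometer data.

## Flow-cytometry gating

`classify_events()` realises the automated pipeline as: debris gate (events
below a scatter quantile on both channels; an optional absolute floor covers
the all-debris corner case) → log10 transform → 1- and 2-component Gaussian
mixture fits by EM → BIC selection. With two components at least 0.2 decades
apart, the higher-mean component is "bearing" and the fraction is its mean
responsibility — a soft count robust to overlap. Closer components are
reported as unresolvable (1 component, flagged). A unimodal sample is
assigned wholly to bearing or free by comparing its mode to a reference
autofluorescence level, a config scalar best derived from a plasmid-free
control (`reference_from_control()`). The estimated fraction is invariant to
global multiplicative rescaling of fluorescence, so detector gain does not
matter for two-population samples.

## Growth rates

`fit_growth_gp()` regresses log OD on time with a squared-exponential-kernel
Gaussian process plus observation noise — the same class of non-parametric
smoother the original growth analysis cites. Hyperparameters maximise the
marginal likelihood from 5 deterministic restarts within data-driven bounds;
a small jitter stabilises the Cholesky factorisation for near-noiseless
curves. The maximal specific growth rate $\mu_{max}$ is the maximum of the
posterior mean derivative of log OD over a 200-point grid, with uncertainty
from the derivative-process variance — both available analytically for this
kernel. The burden ratio is then
$\gamma = \mu_{max}^{bearing}/\mu_{max}^{free}$
(`gamma_from_growth_fits()`), identical to the doubling-time ratio
`gamma_from_doubling_times()` since $\ln 2$ cancels; both routes are
provided because either may be the natural unit in a given lab's records.

## Hierarchical inference

`fit_hierarchical()` estimates $(\lambda, \gamma, \omega)$ from loss curves.
The hierarchy places normal population distributions on logit $\lambda$,
log $\gamma$ and logit $\omega$, with non-centred per-replicate deviations;
observed fractions are scored by a Beta likelihood with mean equal to the
model fraction and inferred precision $\phi$ — fractions from $10^4$ events
are overdispersed relative to binomial, and $\phi$ absorbs both the event
count and day effects. Saturated observations (exactly 0 or 1) are mapped
into $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 1/(2\,n_{events})$,
and the model mean is clamped to the *same* interval: clamping the model
tighter punishes a saturated true model against saturated observations by
~11 nats per point and visibly biases the fit — a numerical trap worth
recording.

Priors (weakly informative defaults, all configurable via `prior_spec()`):
logit $\lambda \sim N(-6, 3)$ (λ centred near $2.5\times10^{-3}$, wide),
log $\gamma \sim N(0, 0.5)$, logit $\omega \sim N(0, 2)$, half-normal
population scales, log-normal $\phi$.

Sampling is an affine-invariant stretch-move ensemble (the natural choice
given the correlated, funnel-shaped posterior and no gradient), run as 4
independent ensembles of $2d+8$ walkers. Ensembles start in a small ball
around a data-informed point: each replicate is fit independently, the
moments of those estimates seed the population level, and the noise
precision is profiled. Convergence is judged by split-$\hat R$ *across
ensembles* (each ensemble's pooled walkers form one chain, split into
iteration halves); per-walker $\hat R$ is meaningless for stretch samplers
because individual walkers are deliberately slow. Fits with any
$\hat R \ge 1.01$ are flagged, not hidden. Identifiability is reported per
parameter as the overlap coefficient between the population-mean prior and
posterior; overlap above 0.35 flags the parameter as data-starved — exactly
what happens to $\lambda$ when no loss is observed (the axe/txe situation:
with all-ones curves, fitting "cannot be applied" meaningfully, and the flag
says so instead of returning a fake interval).

`posterior_predictive()` draws fresh replicates from the fitted hierarchy
and returns the pointwise mean and central 95% band — the envelope usually
overlaid on observed loss curves. `fit_competition()` reuses the machinery
with the competition forward map and a single parameter set, and
additionally flags posterior concentration of $\lambda$ below $10^{-4}$,
i.e. loss indistinguishable from zero at that design's resolution. The
killing efficacy is reported both as $\omega$ and as the survival
probability $1-\omega$, the quantity usually quoted for TA systems.

### What the loss-curve design can and cannot identify

For curves started fully plasmid-bearing the entire TA trajectory is
$f(t) = \left(1 + c\,(e^{rt}-1)/r\right)^{-1}$ with
$r = 1-\gamma(1-\lambda)$ and $c = \lambda\gamma(1-\omega)$: three
parameters enter through exactly two combinations. The data pin $r$ and $c$
sharply; $(\lambda, \gamma, \omega)$ then live on a one-dimensional ridge,
and the *level* of $\lambda$ along that ridge is set by the $\omega$ prior,
not by the data. With the defaults above (ω centred at ½) and a true
$(\lambda = 0.01,\ \omega = 0.95)$, the posterior median of $\lambda$ sits
near $10^{-3}$ — the identified products $\gamma(1-\lambda)$ and
$\lambda\gamma(1-\omega)$ are recovered accurately, while $\lambda$'s
credible interval excludes its true level, systematically. We verified this
with a 10,000-step gold-standard run ($\hat R \approx 1.01$): the package's
acceptance suite asserts full $\lambda$-level recovery anyway and those
assertions fail, deliberately left red, because they are unattainable for
this design under any honestly weak $\omega$ prior. Replicate-to-replicate
variance does not break the degeneracy (the variance components of
$\log c$ are themselves only identified in combination). Practical remedies,
all supported: measure copy number and fix or tightly prior $\lambda$ via
$\lambda = 2^{1-n}$; fit a no-PSK control strain (for which $\omega$ is
absent, so $r$ and $c$ identify $\lambda\gamma$ and $\gamma(1-\lambda)$
jointly); or design assays starting below fraction 1. This mirrors the
original study, which reports only a *bound* on the hok/sok survival
probability rather than a point estimate.

## Numerical choices

* Fraction trajectories: computed relative to the dominant growth exponent
  with `expm1`; the resonant limit is the continuous $g \to 1$ limit of the
  same expression. No overflow for any parameters, times or passage counts.
* Mixture EM: means initialised at the 25/75% quantiles, sds floored at
  $10^{-4}$ decades, 500 iterations, tolerance $10^{-8}$; BIC compares 2 vs
  5 free parameters.
* GP: kernel bounds tie the length scale to the sampling interval and range;
  noise floored near $10^{-4}$ of the signal sd; jitter $10^{-10}\sigma_f^2$.
* Sampler: stretch parameter $a = 1.3$ (gentler than the canonical 2; in
  30+ dimensions the $z^{d-1}$ factor otherwise strands walkers), thinning 4,
  first half of each ensemble discarded as burn-in.
* Degenerate inputs: all-ones curves fit cleanly (and flag λ); a single
  replicate collapses the hierarchy gracefully onto its priors; zero-loss
  parameters produce exactly constant curves.

## Limitations

The model assumes constant copy number and constant growth rates across
passages — plasmid-host coevolution over weeks of passaging violates both,
and the bacteriocin immunity evolution that ends microcin-V stability in
practice is entirely outside the model (in the model's terms it appears as
an effective $\omega$ decaying over time). The simulator has no stationary
phase and no stochastic loss events (deterministic flow plus observation
noise, optionally a dilution bottleneck); at realistic bottleneck sizes
($10^6$ cells) demographic noise is negligible next to measurement noise,
but for very small bottlenecks a birth-death treatment would be needed.
FCS binary ingestion is not included; event tables arrive as CSV.
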