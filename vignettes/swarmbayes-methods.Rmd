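---
title: "Inferring interaction rules in moving animal groups: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring interaction rules in moving animal groups: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmbayes)
```

## The scientific problem

Very different local interaction rules can produce the same collective
patterns — swarms, rotating mills, polarised travelling groups. Group-level
observables therefore cannot identify *which* rules individuals use; that
information lives in the fine-scale movements of individuals reacting to
their neighbours. `swarmbayes` implements both halves of the resulting
inverse problem:

1. a two-dimensional **self-propelled particle (SPP) simulator**, the
   generative model for all synthetic data, and
2. a **fully Bayesian engine** that recovers the interaction parameters
   from recorded trajectories, quantifies the remaining uncertainty with
   Shannon entropy, and compares rule variants (alignment vs no-alignment,
   metric vs topological neighbourhoods) with Bayes factors.

## The generative model

`N` identical particles live in an `L x L` square with periodic boundaries
and move at a common constant speed `v` (one displacement per timestep).
All distances and displacements use the minimum-image convention. At each
timestep every particle synchronously:

1. **Finds its neighbourhood.** Particle `j` is *visible* to particle `i`
   when the bearing of `j` relative to `i`'s heading has magnitude at most
   `pi - beta / 2`, where `beta` is the total width of the rear blind
   sector (`beta = 0` means full vision; anything directly behind is
   invisible for any `beta > 0`). Under the *geometric* (metric) scheme
   the neighbours are all visible particles within the interaction radius
   `r`; under the *topological* scheme they are the `k` nearest visible
   particles, however distant (distance ties broken by particle index for
   reproducibility). The blind angle applies in both schemes. The relation
   is directed: `i` may see `j` while `j` cannot see `i`.
2. **Computes social forces.** The *alignment* vector is the normalised
   sum of the neighbours' heading unit vectors; the *attraction* vector is
   the normalised displacement from the particle to its neighbours' centre
   of mass, computed in minimum-image coordinates relative to the focal
   particle (neighbour clouds are local, so this is unambiguous at mill
   scale). Either vector is undefined (and contributes nothing) when the
   neighbour set is empty or the sum has zero length.
3. **Updates its heading.** The new deterministic direction is the angle
   of `inertia + w_align * A + w_attract * C`, with the inertial term
   fixed at the current heading unit vector — normalisation makes an
   inertial weight of one fully general. If the whole sum vanishes the
   particle keeps its heading: the only continuous completion of the rule.
   With probability `p` (the *update rate*) the particle adopts this
   direction; otherwise it retains its previous heading. In either case a
   wrapped-Gaussian angle with SD `sigma` is then added — noise rotates
   the *final* normalised direction, so `sigma` is exactly the angular SD
   that appears in the likelihood. `sigma` absorbs both behavioural
   variability and observation error; there is no separate position-noise
   channel.
4. **Moves** a distance `v` along the new heading, wrapping at the
   boundary.

All particles read the time-`t` state and write the time-`t+1` state. This
synchronous update is what makes the process Markovian, and hence what
makes the product-form likelihood below exact.

Angles are stored in radians wrapped to `(-pi, pi]`. One seeded generator
drives a simulation; per-particle draws are consumed in fixed index order
(update indicators first, then noise), so a configuration plus a seed
reproduces a trajectory bit for bit.

### The reference parameter set

The package ships a documented reference configuration
(`reference_config()`, stored as YAML under `inst/extdata/`, deliberately
in config rather than code): 25 particles in a 10 x 10 box, speed 0.2 per
step, attraction weight 1, alignment weight 0.25, interaction radius 2,
blind angle pi/2, noise SD 0.15, update probability 1. These values were
chosen once so that, from random initial conditions, the group reliably
converges to the classic *rotating mill* within a few hundred steps —
verified across seeds with the unsigned milling order parameter (mean
`|sin|` of the angle between each heading and its radius vector from the
group centroid; 1 for tangential motion in either sense, about `2/pi` for
random headings). Mills here routinely mix clockwise and anti-clockwise
particles, so an unsigned statistic is the right detector. "Steady state"
is operationalised as milling order above 0.8 sustained for 10 consecutive
steps within a 3000-step horizon; seeds that never reach it are excluded
from steady-state analyses with a warning.

## The likelihood

Speed is constant, so positions are completely determined by headings and
only heading changes need to be scored. Writing `phi_hat_i(t+1)` for the
deterministic predicted direction computed from the state at `t`, each
particle-timestep contributes the wrapped-normal density of the observed
minus predicted heading, and the log-likelihood of a trajectory is the sum
over particles and timesteps. When the update rate `p` is below one the
exact transition density is a two-component mixture,

```
p * WN(phi_obs - phi_hat; sigma) + (1 - p) * WN(phi_obs - phi_old; sigma),
```

because a non-updating particle keeps its old heading but is still noised.
This mixture is derived from the stated generative process (the update
indicator is unobserved and is marginalised out per particle per step); it
degenerates exactly to the pure form at `p = 1`.

The wrapped-normal density sums the Gaussian over `2*pi` translates. The
wrap sum is truncated once the outermost included translate sits about 7.1
SDs out, keeping the neglected mass near 1e-12 for `sigma <= 2*pi`; beyond
`2*pi` the density is numerically uniform and short-circuits to
`1 / (2*pi)`. (A simpler truncation at `ceil(4*sigma/2*pi)` terms is *not*
sufficient — it leaves ~7e-6 of mass at `sigma = 2*pi`, which the
package's quadrature tests would catch.) Likelihood terms that underflow
to zero density are kept as `-Inf` log-mass grid points rather than being
propagated as `NaN` through the mixture.

## The Bayesian engine

Inference runs on an exhaustive regular grid over the free parameters —
the finite set of sample parameter values on which the entropy is defined.
The free parameters are exactly those implied by the model flags: the
active force weights, `r` or `k`, the blind angle, `sigma`, and optionally
`p`. The prior is uniform over broad per-parameter ranges (defaults:
attraction 0–2, alignment 0–1, radius 0.5–4.5, neighbour count 1–13,
blind angle 0–pi, noise SD 0.05–0.85 with the lowest grid value strictly
positive, update rate 0.1–1).

Updating is exact sequential Bayes: each observed transition adds its
grid-wise log-likelihood to the log mass, which is renormalised with
log-sum-exp; the log normalising constants accumulate into the cumulative
log evidence `log p(D | M)`. Because the grid is finite and the dynamics
Markovian, batch and sequential updating agree to accumulation error only
— a property the test suite checks at 1e-10 against a naive per-point
enumeration.

Summaries follow the usual study conventions: mass-weighted marginal means
and SDs per parameter, and the Shannon entropy of the joint distribution
(natural log by default; entropy *comparisons* are base-invariant) as the
single-number measure of remaining uncertainty, falling from
`log(grid size)` at the prior towards 0 as the posterior concentrates.
Model comparison uses the log Bayes factor — the difference of cumulative
log evidences of two models fitted to *identical* observations (enforced
by an assimilated-data-count check). Marginalising parameters inside the
evidence supplies the automatic Occam penalty; in no-alignment candidate
models the alignment axis is removed entirely rather than pinned at zero,
so that penalty is genuinely exercised.

The grid evaluator factorises the model to stay fast: neighbourhoods
depend only on `(r-or-k, beta)`, predicted headings additionally on the
force weights, and the density on `(sigma, p)`, so a full grid evaluation
of one transition costs far less than point-by-point evaluation. The
naive path (`step_loglik` at a single parameter set) is retained as the
reference implementation and the two are cross-checked in the tests.

## Experiment pipelines and their design choices

Four scripted scenarios mirror the classic study designs, each replicated
over 5 seeds by default with seed-averaged records alongside per-seed
ones. Problem sizes are the package defaults throughout: N = 25
particles, 10 assimilated timesteps, 9 grid points per axis (7 plus a
10-point update-rate axis when `p` is freed — 10 points over 0.1–1 put
both 0.5 and 1 exactly on the axis). The reference parameter values were
placed on the default grid axes deliberately: recovery claims are then
statements about information content, not about interpolation error.

- **Convergence** (`run_convergence_scenario()`): assimilate transitions
  one at a time from a random initial configuration, then from the mill
  steady state. Expected behaviour: all parameters recovered within a few
  steps from random configurations; steady-state data converge more
  slowly, and the interaction radius marginal stays close to its prior —
  inside a mill everyone sits within one radius, so the data cannot say
  where interactions would cease. We operationalise "practically
  unchanged from the prior" as the radius marginal retaining at least 80%
  of its prior entropy.
- **Noise sweep** (`run_noise_sweep()`): full 10-step inferences across
  increasing true `sigma`, under a widened noise prior (0.05 to `2*pi`)
  so heavy noise levels remain inside the grid; the default sweep values
  are the first six axis values of that prior. Posterior entropy rises
  with noise and plateaus at the prior entropy once `sigma` is of order
  `pi` — at that point direction changes span the full semicircle by
  chance alone and the data carry no information.
- **Update-rate sweep** (`run_update_rate_sweep()`): data generated with
  `p < 1` but analysed assuming `p = 1` bias the force weights low —
  fewer actual updates per recorded step must be explained by weaker
  forces — and inflate the inferred noise; freeing the `p` axis removes
  the bias and recovers `p`. One methodological choice deserves emphasis:
  joint entropies over grids of different dimensionality are not
  commensurable (adding an axis adds entropy by construction), so when
  the package compares the uncertainty of `p`-fixed and `p`-free fits it
  uses the entropy of the joint marginal over the *shared* structural
  axes (`entropy_shared` in the records, `posterior_entropy(post,
  axes_vector)` in the API). Even on that footing the ordering is the
  least robust of the package's qualitative claims: per-seed values
  overlap substantially and only the seed average leans the expected way.
- **Model selection** (`run_model_selection()`): both candidate models
  assimilate identical data step by step, from data generated by each
  candidate in turn. Correct-model support should grow with data; for
  nested comparisons (no-alignment data under an alignment-capable
  model) only the Occam penalty separates the models, so the Bayes
  factor is correct in sign but much smaller in magnitude — and its
  seed-averaged step-by-step trace is near-flat, where Monte-Carlo
  wiggles of a few tenths of a nat are to be expected.

## Numerical and degenerate-input conventions

- Log-space accumulation with log-sum-exp everywhere; renormalisation
  after every update.
- Zero-length force sums fall back to inertia; empty neighbourhoods are
  legal everywhere.
- Topological ties at the k-th distance break by particle index.
- `update_prob = 0` is accepted by the simulator (frozen-heading limit);
  inference grids keep the axis at or above 0.1.
- Trajectory CSVs serialise floats with 17 significant digits and are
  parsed with base R's correctly-rounded reader, making write/read round
  trips bit-exact; files are ordered t-major, particle-minor so equal
  trajectories produce byte-identical files.

## What the synthetic data do and do not show

The simulator *is* the data-generating process assumed by the likelihood,
so the studies here test the inference machinery under a correctly
specified model (plus the deliberate misspecification of the update-rate
study). Real trajectory data add everything the generator does not
emulate: variable speeds, heterogeneous individuals, boundary effects in
tanks rather than periodic boxes, occlusion and tracking mistakes, and
observation noise on positions rather than a single angular channel.
Passing the package's tests therefore demonstrates that the method
recovers rules *when the model family is right*, and quantifies honestly
when data are uninformative (mills, heavy noise, fast sampling); it does
not validate any particular rule set for any particular species.

## Known limitations

- Two dimensions only; constant speed; no body-contact or hydrodynamic
  interactions.
- Grid inference scales multiplicatively in axes: beyond ~6 axes the
  exhaustive grid is impractical (that regime calls for MCMC/SMC, which
  is out of scope here).
- Entropy values depend on the grid resolution; only comparisons at a
  fixed grid (or over shared axes) are meaningful.
- The blind-angle convention (total rear width `beta`, visibility iff
  `|bearing| <= pi - beta/2`) is one of several in the literature; check
  conventions before comparing fitted values across packages.
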