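---
title: "Sex-specific spatial capture-recapture from unstructured search surveys"
author: "sexscr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific spatial capture-recapture from unstructured search surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexscr)
```

## The estimation problem

Non-invasive genetic sampling surveys identify individual animals from DNA in
field-collected material (here, feces found along search routes) without ever
capturing them. Each genotyped sample is a spatially referenced detection of a
known individual of (usually) known sex. From such data, spatial
capture-recapture (SCR) estimates the number of animals in a region, where
they concentrate, and how detection declines with distance — while accounting
for the individuals that were never found.

`sexscr` implements a sex-specific Bayesian SCR model for this situation,
together with everything around it: terrain covariate engineering on a
discretized habitat, conversion of GPS search tracks into "conceptual traps"
with a search-effort covariate, an rjMCMC sampler with covariate selection,
and the posterior products (density surfaces, abundance, inclusion
probabilities, sex ratios). A seeded synthetic-data generator reproduces the
statistical structure the model assumes, so every stage is testable without
field data.

## The model

**Ecological process.** The habitat is a 250 m grid of $C$ cells (the study
polygon grown by a 1000 m buffer, so activity centers may sit outside the
searched area). Each of $M$ augmented individuals has a latent activity
center (AC) $s_i \in \{1,\dots,C\}$ following an inhomogeneous Bernoulli
point process on the cells,

$$\pi_c \;=\; \frac{\exp\big(\textstyle\sum_k \gamma_k \beta_k x_{kc}\big)}
                   {\sum_{c'} \exp\big(\textstyle\sum_k \gamma_k \beta_k x_{kc'}\big)},$$

with standardized cell covariates $x_{kc}$ — terrain ruggedness (TRI), site
severity (SSI), canopy cover, and barren ground — and per-sex coefficients
$\beta_k$ gated by binary inclusion indicators $\gamma_k$. With all
$\gamma_k = 0$ the process reduces to a uniform (null) point process.

**Observation process.** Search tracks, buffered by 3 m (the approximate
viewshed of the observers), define which 50 m sub-cells of a 100 m detector
grid were searched; unsearched cells are not detectors. An individual can be
recorded at most once per searched sub-cell, so counts at detector $j$ are
$y_{ij} \sim \mathrm{Binomial}(K_j, p_{ij})$ with $K_j \le 4$ searched
sub-cells and

$$p_{ij} \;=\; \mathrm{logit}^{-1}\!\big(\mathrm{logit}(p_{0,\mathrm{sex}_i})
      + \beta_{\mathrm{search}}\, e_j\big)\,
      \exp\!\big(-d_{ij}^2 / 2\sigma^2_{\mathrm{sex}_i}\big),$$

the effort-adjusted half-normal detection function: $d_{ij}$ is the distance
from the AC cell center to the detector center, $\sigma$ scales with
home-range size, $p_0$ is the sex-specific baseline at mean effort, and
$e_j$ is the standardized log searched area of the detector (searched areas
span orders of magnitude, hence the log).

**Data augmentation and latent sex.** The unknown population size is handled
by embedding the data in a super-population of $M = 6\,n$ individuals
($n$ = number detected), each with $z_i \sim \mathrm{Bernoulli}(\psi)$;
abundance is $N = \sum_i z_i$. Sex is a latent Bernoulli variable
(female = 0, male = 1) with $P(\mathrm{male}) = \Psi_{sex}$, fixed where
observed, sampled for unsexed and augmented individuals.

**Priors.** The defaults — all configurable through `scrPriors()` — are
$p_0 \sim \mathrm{Beta}(1,1)$, $\sigma \sim \mathrm{U}(0, 5000\,\mathrm{m})$,
$\beta, \beta_{\mathrm{search}} \sim \mathrm{N}(0, 2)$,
$\psi, \Psi_{sex} \sim \mathrm{U}(0,1)$, and
$\gamma_k \sim \mathrm{Bernoulli}(0.5)$. The coefficient prior is weakly
informative by design. Covariates are standardized, so $\beta = 2$ already
means an $e^2 \approx 7$-fold intensity change per covariate standard
deviation; essentially flat priors (say, sd 10) are not harmless here,
because the augmented model has a degenerate mode in which every detected
individual's activity center pools in the single most extreme habitat cell
while $p_0$ collapses and $\sigma$ inflates to absorb the spatial spread of
the detections. The prior gain of pooling grows with the number of detected
individuals, and only a prior that treats $|\beta| > 5$ as implausible
reliably suppresses the mode. Sex-specific calibration runs made this
concrete: under a flat coefficient prior the ruggedness coefficient drifted
to 7–25 with $p_0$ an order of magnitude low, stably across very long
chains.

## Covariate engineering

TRI is the square root of summed squared elevation differences to the eight
neighbors of a 25 m DEM cell. SSI combines slope and aspect; the literature
describes the index by its behavior (negative on mesic, positive on xeric
sites) rather than by a formula, so the package uses

$$\mathrm{SSI} = \sin(\mathrm{slope})\cdot\cos(\mathrm{aspect} - 180^\circ),$$

with slope and aspect from the Horn eight-neighbor estimator (the GIS
standard). This is zero on flat ground, positive on steep south-facing
(xeric) and negative on steep north-facing (mesic) slopes; the functional
form is a package decision and is exposed as the `fun` argument of
`computeSSI()` should a different composite be preferred.

All covariates are moving-window averaged within a radius matching the local
home-range scale (200 m or 300 m in the reference configurations), mean
aggregated to the 250 m habitat grid (snapped to multiples of the cell
size), and standardized. Candidate covariates with pairwise $|r| > 0.7$ are
screened by iteratively dropping, from the worst pair, the column with the
larger mean absolute correlation to everything else — a deterministic rule;
ties drop the later column, and a pair at exactly the threshold is kept.
Buffering of the study polygon is grid-based (a cell is kept if its center
is within the buffer distance, per axis, of a cell inside the polygon), so
the buffered grid always contains the polygon and the cell count is exactly
reproducible.

## Detector construction and filtering

The searched-corridor geometry is computed by fine rasterization (default
1 m): a sub-cell is searched if any corridor point inside the study polygon
falls in it, and the searched area of a detector is the rasterized
buffer-cell intersection area. Detections are de-duplicated to one encounter
per individual per searched sub-cell, which is what makes the
Binomial($K_j \le 4$) observation model coherent; samples that fall in
unsearched cells or sub-cells are logged and dropped, never silently
counted.

Long spatial recaptures (dispersal or transience, which violate closure) are
removed by pooling all within-individual pairwise detection distances,
setting the cap at the 99th percentile (linear-interpolation empirical
quantile) or at an explicit value, and then removing, per individual, the
detection with the largest mean distance to its other detections until all
pairs fall under the cap. Removal at the detection level retains data, and
the farthest-first rule is deterministic. Re-applying the filter with the
same explicit cap is a no-op.

## Sampler design

`runMCMC()` is a Metropolis-within-Gibbs sampler with a fixed update order:
joint random-walk Metropolis on $(\mathrm{logit}(p_0), \log \sigma)$ per sex
(the two parameters ride a posterior ridge, and a joint move costs one
likelihood scan instead of two) and on $\beta_{\mathrm{search}}$ (updated on
alternate iterations; it mixes fast); a reversible-jump toggle per indicator
(Kuo-Mallick style: on activation the coefficient is proposed from its
prior, so the acceptance ratio reduces to the AC-prior ratio times the prior
inclusion odds); conditional random-walk updates of included coefficients;
Gibbs updates of $z$ and sex; conjugate Beta updates of $\psi$ and
$\Psi_{sex}$; and categorical Gibbs updates of the AC cells, drawn last.
Proposal scales adapt by Robbins-Monro during burn-in toward a 0.37
acceptance rate and are frozen afterwards, preserving detailed balance. Each
indicator toggle is attempted with probability 1/2 per sweep: this lazy
proposal keeps the chain aperiodic in the flat-likelihood limit where every
toggle would be accepted.

**Collapsed updates.** Every parameter update marginalizes the activity
centers of the undetected augmented individuals analytically: a $z = 0$
individual's AC integrates to $\sum_c \pi_c = 1$, and a $z = 1$ undetected
individual's to $w = \sum_c \pi_c e^{\ell_0(c)}$ with $\ell_0(c)$ the
all-zero-history log-likelihood at cell $c$ — a single log-sum-exp per sex.
The ACs are then re-drawn from their full conditionals at the end of the
iteration, so the scheme is a partially collapsed Gibbs sampler with the
same stationary distribution. Without this collapsing, the parameter updates
condition on hundreds of prior-driven augmented ACs that echo the current
parameter values, which multiplies the autocorrelation time of the
point-process coefficients by roughly the square of the augmentation factor;
with it, scaled-down chains mix well enough for calibration studies. The
state updates $z$ and sex use the same marginal quantities, which also makes
them cheaper.

Default run shape: 4 chains of 80,000 iterations, 20,000 burn-in, every 3rd
post-burn-in draw retained for parameters and every 10th for the
memory-heavy AC/inclusion/sex draws.

**Local evaluation.** Detection probabilities are truncated to zero beyond a
radius of $4\sigma$ (per sex, recomputed every iteration from the current
$\sigma$), which makes the per-iteration cost scale with the detectors near
each occupied cell rather than with all cell-detector pairs. The neighbor
structure is precomputed once at a generous radius (by default several times
the apparent detection scale of the data) with per-cell lists sorted by
distance, so kernels stop scanning at the current radius; the effective
truncation radius is capped at that precomputed radius. The truncation error
of an all-zero encounter history is bounded by
$\sum_j K_j\, p_{0}\exp(-r^2/2\sigma^2)$, which the test suite checks
numerically; at $r = 4\sigma$ the bound is below $4 \times 10^{-4}$ per
cell-detector pair even at $p_0 = 1$. A per-sex radius is used rather than a
shared $4\,\max(\sigma_F, \sigma_M)$: it is tighter for the smaller-ranged
sex and keeps each sex's likelihood self-contained, and the same truncation
is applied consistently in every update, so the sampled model is exactly the
truncated likelihood.

**Exactness.** On a tiny instance (4 cells, 2 detectors, $M = 3$) the
sampler's marginal posteriors of $s$, $z$, sex and $\gamma$ are compared
with exhaustive enumeration over all latent configurations; the option
`rj_redraw_beta = FALSE` freezes the coefficients so the MCMC target
coincides with the enumerable finite model. Prior recovery (flattened
likelihood) is checked by Kolmogorov-Smirnov tests against every prior.

## The synthetic-data generator

`scrScenario()` fixes the generative conditions; `simulateLandscape()`,
`simulatePopulation()` and `simulateSurvey()` draw from independent seeded
sub-streams, so re-drawing a survey never changes the landscape or the true
population. The landscape is a sum of seeded Gaussian bumps (DEM in meters,
canopy and barren percentages squashed into $[0, 100]$, forest = canopy
above a threshold): smooth, controllable, and download-free, emulating the
character of real DEM and land-cover products without reproducing any
landscape. ACs are drawn cell-wise from the same softmax point process the
model fits. Because the model treats ACs at cell resolution, the survey
simulator computes detection from the AC's cell center; the uniform
within-cell jitter in the reported coordinates is cosmetic. Unsexed
individuals arise completely at random at a configurable rate (default 5%,
of the order seen in field genotyping); the missingness mechanism in real
data is unknown, and MCAR is a declared stand-in.

What the generator does **not** emulate: genotyping error and allelic
dropout, animal movement along tracks (detections are independent binomial
draws given the AC), anisotropic or non-circular home ranges, and temporal
variation in effort. Passing recovery tests therefore demonstrates that the
estimator inverts its own generative assumptions correctly — not that those
assumptions hold in any particular field system.

## Calibration study design

The recovery suite uses a 5 × 5 km landscape (400 habitat cells of 250 m),
100 females and 100 males with $\beta = (1.2, -0.5, -0.8, 0)$,
$p_0 = 0.02$, $\sigma = 200$ m, $\beta_{\mathrm{search}} = 0.5$, and 150
detectors with $K = 4$ and log-normal searched areas. The detector layout
follows two standard SCR design principles. First, search effort must
concentrate where animals are: at these detection rates a spatially uniform
layout detects so few individuals (expected encounters per individual about
$K p_0 J \cdot 2\pi\sigma^2/A \approx 0.12$) that the $M = 6n$ augmentation
could not contain the true population. Second, the searched cells must span
the covariate gradient and sit within $\sim$1–2$\sigma$ of each other:
placing all detectors in a block of top-ranked cells leaves no covariate
contrast inside the searched area (quasi-separation of the selection
coefficients), while scattering single detectors too widely yields almost no
spatial recaptures, leaving the $(p_0, \sigma)$ ridge multimodal. The suite
therefore uses 75 detector pairs at 250 m spacing whose seed cells span the
top 60% of the suitability ranking. Twenty replicate surveys are fitted with
two chains of 8,000 iterations (2,000 burn-in); the full-scale run shape
stays available through the defaults. These problem sizes are the package's
calibration choices: large enough for interval calibration and selection
behavior to be measurable, small enough to re-run routinely.

## Known limitations

* ACs live on cell centers; density within a cell is not resolved, and
  $\sigma$ near or below the cell size is poorly identified.
* The closed-population assumption is handled only by the long-recapture
  filter; genuine transients inside the cap remain.
* $\beta_{\mathrm{search}}$ is shared across sexes (the reference analyses
  report a single per-area value).
* The collinearity screen and the SSI formula are deterministic package
  decisions where the methodological literature leaves latitude; both are
  configurable and logged.
* With very few detections per sex, coefficient posteriors conditional on
  inclusion shrink toward the prior and inclusion probabilities are weakly
  informative — model selection needs data volume.
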