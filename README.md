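# sexscr

Sex-specific Bayesian spatial capture–recapture (SCR) from non-invasive
genetic sampling along unstructured search tracks.

Wildlife surveys that genotype field-collected DNA (typically feces) yield
spatially referenced detections of identified individuals of known sex —
but no physical traps, no fixed occasions, and no record of the animals that
were never found. `sexscr` turns such data (or fully synthetic equivalents)
into sex-specific density surfaces, abundance estimates, and habitat-
selection inference, for ecologists and wildlife managers working on
mountain ungulates and similar systems.

## The model

The package implements a hierarchical SCR model with Bayesian data
augmentation:

* **Ecological process** — each of `M` augmented individuals has a latent
  activity center (AC) on a 250 m habitat grid, following an inhomogeneous
  Bernoulli point process
  `pi_c ∝ exp(Σ_k γ_k β_k x_kc)` on standardized terrain covariates
  (ruggedness TRI, site severity SSI, canopy cover, barren ground), with
  per-sex coefficients `β` gated by inclusion indicators `γ` sampled by
  reversible-jump MCMC (posterior inclusion and model probabilities).
* **Observation process** — search tracks buffered by 3 m define which 50 m
  sub-cells of a 100 m detector grid were searched; encounter counts are
  `y_ij ~ Binomial(K_j ≤ 4, p_ij)` with the effort-adjusted half-normal
  detection function
  `p_ij = invlogit(logit(p0_sex) + β_search e_j) · exp(−d_ij² / 2σ_sex²)`.
* **Augmentation and latent sex** — `z_i ~ Bernoulli(ψ)` with `N = Σ z_i`
  (`M = 6 ×` the number detected), and sex is a latent Bernoulli
  (`P(male) = Ψ_sex`), sampled for unsexed and undetected individuals.

A seeded synthetic-data generator (`scrScenario()`, `simulateLandscape()`,
`simulatePopulation()`, `simulateSurvey()`, `simulateTracks()`) reproduces
exactly this generative structure, so the whole pipeline is testable without
any field download.

## Worked example

A complete synthetic analysis — landscape, habitat grid, survey, fit,
posterior products:

```r
library(sexscr)

sc <- scrScenario(extent = c(0, 5000, 0, 5000), n_true_per_sex = c(100, 100),
                  beta_true = c(1.2, -0.5, -0.8, 0), p0_true = c(0.02, 0.02),
                  sigma_true = c(200, 200), beta_search_true = 0.5, seed = 1)
land <- simulateLandscape(sc)
poly <- cbind(c(0, 5000, 5000, 0), c(0, 0, 5000, 5000))
hab  <- buildHabitatGrid(poly, land, buffer = 0, cell = 250, radius = 200)
#> <habitat_grid> 400 cells of 250 m (0.0625 km2 each), buffer 0 m
#>   covariates: TRI, SSI, CANOPY, BARREN (standardized)

# survey design: 75 detector pairs spanning the habitat-suitability gradient
eta   <- as.vector(hab$X %*% sc$beta_true[, 1])
seeds <- order(eta, decreasing = TRUE)[round(seq(1, 240, length.out = 75))]
set.seed(42)
det <- detectorGrid(x = as.vector(outer(hab$centers[seeds, 1], c(-125, 125), "+")),
                    y = rep(hab$centers[seeds, 2], 2),
                    K = rep(4, 150),
                    effort_raw = pmin(exp(rnorm(150, 7.5, 0.6)), 1e4))

truth <- simulatePopulation(hab, sc)
enc   <- simulateSurvey(truth, hab, det, sc)
fit   <- runMCMC(enc, hab, det,
                 samplerConfig(n_chains = 2, n_iter = 8000, burn_in = 2000,
                               seed = 7))
posteriorSummary(fit)
computePipPmp(fit)
abundanceDensity(fit)
sexRatio(fit)
gelmanRubin(fit)
```

With this seed the survey detects 50 of the 200 simulated individuals
(`M = 300` after augmentation). The fit recovers the truth within its
credible intervals — posterior means and 95% CIs as printed by the code
above:

```
     parameter     mean       lo       hi
1         p0_F   0.0222 7.75e-03   0.0508
2         p0_M   0.0262 5.61e-03   0.0951
3      sigma_F 205.8196 1.37e+02 276.5236
4      sigma_M 173.0029 1.01e+02 253.5177
5  beta_search   0.6005 2.01e-01   1.0534
15     psi_sex   0.4219 1.84e-01   0.6814
16           N 219.2235 1.29e+02 297.0000

 sex covariate   pip coef_mean coef_lo coef_hi
   F       TRI 1.000   2.54284   1.302   4.229
   F       SSI 0.232   0.00684  -1.403   1.718
   F    CANOPY 0.405  -0.73656  -2.401   1.044
   F    BARREN 0.299  -0.06366  -2.009   1.586
   M       TRI 0.993   2.67292   0.962   5.021
   M       SSI 0.626  -1.86764  -4.952   0.516
   M    CANOPY 0.590  -1.76348  -4.891   0.963
   M    BARREN 0.435  -0.96152  -3.836   1.696

   region     sex N_mean N_lo N_hi density_mean density_lo density_hi area_km2
9 overall overall 218.56  123  297        8.743       4.92       11.9     25.0

male:female ratio = 0.73
```

The abundance interval covers the simulated truth (`N = 200`,
`p0 = 0.02`, `sigma = 200` m, `beta_search = 0.5`), terrain ruggedness is
selected in essentially every draw (PIP ≈ 1) while the null covariate
(barren ground) is not, and split rank-normalized R-hat for all continuous
parameters is below 1.05.

`densitySurface(fit)` returns per-cell posterior mean densities (per cell,
per km² or per ha) that sum exactly to the posterior mean abundance, and
`writeDensitySurface()` exports them as an ESRI ASCII grid.

For real data the entry points are `readTracksGPX()`/`readTracksCSV()` and
`buildDetectors()` (conceptual traps + effort from buffered tracks),
`assignDetections()` (sub-cell de-duplicated encounter histories), and
`filterLongRecaptures()` (99th-percentile closure filter), with
`buildHabitatGrid()` consuming DEM/canopy/barren/forest rasters
(`read_asc()`) and a study polygon (`readPolygon()`).

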