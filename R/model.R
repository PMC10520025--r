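#' Model parameter set
#'
#' All continuous and discrete parameters of the sex-specific SCR model at
#' one state: per-sex baseline detection `p0`, per-sex half-normal scale
#' `sigma` (m), shared effort coefficient `beta_search`, per-sex point-process
#' coefficients `beta` (4 x 2) with inclusion indicators `gamma` (4 x 2,
#' 0/1), the data-augmentation inclusion probability `psi`, and the latent-sex
#' probability `psi_sex` (probability an individual is male).
#'
#' @param p0 length-2 numeric in (0, 1), `c(female, male)`.
#' @param sigma length-2 positive numeric, meters.
#' @param beta_search scalar.
#' @param beta 4 x 2 matrix (rows TRI, SSI, CANOPY, BARREN).
#' @param gamma 4 x 2 matrix of 0/1 indicators.
#' @param psi,psi_sex scalars in (0, 1).
#' @return An object of class `scr_params`.
#' @export
scrParams <- function(p0 = c(0.02, 0.02), sigma = c(200, 200),
                      beta_search = 0, beta = matrix(0, 4, 2),
                      gamma = matrix(1, 4, 2), psi = 0.5, psi_sex = 0.5) {
  p0 <- rep_len(p0, 2L); sigma <- rep_len(sigma, 2L)
  beta <- matrix(beta, 4L, 2L); gamma <- matrix(gamma, 4L, 2L)
  if (any(p0 <= 0 | p0 >= 1)) stopf("p0 must be in (0, 1)")
  if (any(sigma <= 0)) stopf("sigma must be > 0")
  if (!all(gamma %in% c(0, 1))) stopf("gamma entries must be 0 or 1")
  if (psi <= 0 || psi >= 1 || psi_sex <= 0 || psi_sex >= 1)
    stopf("psi and psi_sex must be in (0, 1)")
  structure(list(p0 = p0, sigma = sigma, beta_search = beta_search,
                 beta = beta, gamma = gamma, psi = psi, psi_sex = psi_sex),
            class = "scr_params")
}

#' Effort-adjusted baseline detection probability
#'
#' GLM formulation on the logit scale:
#' `invlogit(logit(p0_sex) + beta_search * effort_std)`. At the mean
#' standardized effort (`effort_std = 0`) this returns `p0_sex` exactly.
#'
#' @param p0_sex baseline detection probability in (0, 1).
#' @param beta_search effort coefficient (logit scale).
#' @param effort_std standardized log searched area of the detector(s).
#' @return Detection probability (vectorized over `effort_std`).
#' @export
baselineP0 <- function(p0_sex, beta_search, effort_std) {
  if (any(p0_sex <= 0 | p0_sex >= 1)) stopf("p0_sex must be in (0, 1)")
  if (any(!is.finite(c(beta_search, effort_std)))) stopf("inputs must be finite")
  plogis(qlogis(p0_sex) + beta_search * effort_std)
}

#' Half-normal detection function
#'
#' `p(d) = p0_eff * exp(-d^2 / (2 * sigma^2))`: detection probability declines
#' with the distance `d` between a detector and the individual's activity
#' center, at rate set by the scale `sigma` (a proxy for home-range radius).
#'
#' @param d distance in meters, non-negative.
#' @param p0_eff effective baseline detection probability at `d = 0`.
#' @param sigma_sex half-normal scale in meters, positive.
#' @return Detection probability.
#' @export
detectionProb <- function(d, p0_eff, sigma_sex) {
  if (any(d < 0)) stopf("distance must be non-negative")
  if (any(sigma_sex <= 0)) stopf("sigma must be > 0")
  p0_eff * exp(-d^2 / (2 * sigma_sex^2))
}

#' Log-prior of activity-center placement
#'
#' The inhomogeneous Bernoulli point process over habitat cells:
#' `pi_c = exp(sum_k gamma_k beta_k x_kc) / sum_c' exp(...)`. With all
#' indicators zero the process reduces to the uniform (null) point process,
#' `pi_c = 1 / C`. The log-sum-exp normalizer is guarded by max subtraction.
#'
#' @param habitat a `habitat_grid`.
#' @param beta_sex length-4 coefficient vector for one sex.
#' @param gamma_sex length-4 0/1 inclusion vector.
#' @return Length-`nCells(habitat)` vector of log cell probabilities.
#' @export
acLogPrior <- function(habitat, beta_sex, gamma_sex) {
  stopifnot(length(beta_sex) == 4L, length(gamma_sex) == 4L)
  if (any(!is.finite(habitat$X))) stopf("non-finite habitat covariates")
  ac_logprior_fast(habitat$X, beta_sex, gamma_sex)
}

# validation-free path for the sampler's inner loops
ac_logprior_fast <- function(X, beta_sex, gamma_sex) {
  eta <- as.vector(X %*% (beta_sex * gamma_sex))
  m <- max(eta)
  eta - m - log(sum(exp(eta - m)))
}

#' Binomial encounter log-likelihood of one individual
#'
#' For a population member (`z = 1`) with activity center in habitat cell
#' `cell`, sums `log Binomial(y_j; K_j, p_j)` over detectors within
#' `local_radius` of the cell center, with
#' `p_j = baselineP0(p0_sex, beta_search, e_j) * exp(-d_j^2 / (2 sigma^2))`.
#' Detectors beyond the radius are treated as having zero detection
#' probability (so a detection there makes the state impossible). For a
#' non-member (`z = 0`) the contribution is 0 for an all-zero history and
#' `-Inf` otherwise.
#'
#' @param y_i integer detection counts over detectors.
#' @param cell habitat cell index of the activity center.
#' @param z,sex_i inclusion indicator and sex (0 female / 1 male).
#' @param params an [scrParams()].
#' @param habitat a `habitat_grid`.
#' @param detectors a [detectorGrid()].
#' @param local_radius evaluation radius in meters (default `Inf`, i.e. full
#'   evaluation; the sampler uses `4 * max(sigma)`).
#' @return Scalar log-likelihood.
#' @export
encounterLogLik <- function(y_i, cell, z, sex_i, params, habitat, detectors,
                            local_radius = Inf) {
  if (any(y_i > detectors$K)) stopf("y exceeds the binomial trial count K")
  if (z == 0) return(if (all(y_i == 0)) 0 else -Inf)
  d <- sqrt((habitat$centers[cell, 1] - detectors$x)^2 +
              (habitat$centers[cell, 2] - detectors$y)^2)
  p0e <- baselineP0(params$p0[sex_i + 1L], params$beta_search,
                    detectors$effort_std)
  p <- detectionProb(d, p0e, params$sigma[sex_i + 1L])
  p[d > local_radius] <- 0
  ll <- numeric(length(p))
  pos <- p > 0
  ll[pos] <- dbinom(y_i[pos], detectors$K[pos], p[pos], log = TRUE)
  ll[!pos] <- ifelse(y_i[!pos] == 0, 0, -Inf)
  sum(ll)
}

#' Prior specification
#'
#' Default priors: `p0 ~ Beta(1, 1)`, `sigma ~ Uniform(0, 5000)` m,
#' `beta`, `beta_search ~ Normal(0, 2)`, `psi, psi_sex ~ Uniform(0, 1)`
#' (i.e. Beta(1, 1), updated conjugately), `gamma ~ Bernoulli(0.5)`. The
#' coefficient prior is weakly informative on purpose: with standardized
#' covariates, a coefficient of 2 already means an e^2-fold intensity change
#' per covariate standard deviation, and a much flatter prior admits a
#' degenerate mode of the augmented model in which all activity centers pool
#' in the single most extreme habitat cell while `p0` collapses and `sigma`
#' inflates to compensate (see the methods vignette).
#'
#' @param p0_shape1,p0_shape2 Beta prior shapes for both sexes' `p0`.
#' @param sigma_max upper bound (m) of the uniform prior on `sigma`.
#' @param beta_sd standard deviation of the normal prior on `beta` and
#'   `beta_search`.
#' @param psi_shape1,psi_shape2 Beta prior shapes for `psi`.
#' @param psi_sex_shape1,psi_sex_shape2 Beta prior shapes for `psi_sex`.
#' @param gamma_prob prior inclusion probability of each covariate.
#' @return An object of class `scr_priors`.
#' @export
scrPriors <- function(p0_shape1 = 1, p0_shape2 = 1, sigma_max = 5000,
                      beta_sd = 2, psi_shape1 = 1, psi_shape2 = 1,
                      psi_sex_shape1 = 1, psi_sex_shape2 = 1,
                      gamma_prob = 0.5) {
  structure(list(p0_shape1 = p0_shape1, p0_shape2 = p0_shape2,
                 sigma_max = sigma_max, beta_sd = beta_sd,
                 psi_shape1 = psi_shape1, psi_shape2 = psi_shape2,
                 psi_sex_shape1 = psi_sex_shape1,
                 psi_sex_shape2 = psi_sex_shape2, gamma_prob = gamma_prob),
            class = "scr_priors")
}

# log prior density of the continuous parameters (psi / psi_sex / gamma are
# handled conjugately or by toggle moves, but enter joint_logposterior)
param_logprior <- function(params, priors) {
  if (any(params$sigma >= priors$sigma_max)) return(-Inf)
  sum(stats::dbeta(params$p0, priors$p0_shape1, priors$p0_shape2, log = TRUE)) +
    sum(-log(priors$sigma_max)) +
    sum(dnorm(params$beta[params$gamma == 1], 0, priors$beta_sd, log = TRUE)) +
    dnorm(params$beta_search, 0, priors$beta_sd, log = TRUE) +
    stats::dbeta(params$psi, priors$psi_shape1, priors$psi_shape2, log = TRUE) +
    stats::dbeta(params$psi_sex, priors$psi_sex_shape1, priors$psi_sex_shape2,
                 log = TRUE) +
    sum(ifelse(params$gamma == 1, log(priors$gamma_prob),
               log(1 - priors$gamma_prob)))
}

#' Joint log-posterior of a model state
#'
#' Sum of the activity-center log-priors of all augmented individuals, the
#' Bernoulli terms of the inclusion indicators (`psi`) and latent sexes
#' (`psi_sex`), the binomial encounter log-likelihoods, and the parameter
#' log-priors. `-Inf` (an impossible state) is propagated, never `NaN`.
#'
#' @param state list with `params` ([scrParams()]), `s` (cell index per
#'   augmented individual), `z` (0/1), `sex` (0/1), and `M`.
#' @param y count matrix for the detected individuals (rows must come first
#'   among the `M` augmented individuals).
#' @param habitat a `habitat_grid`.
#' @param detectors a [detectorGrid()].
#' @param priors an [scrPriors()].
#' @param local_radius evaluation radius in meters (default `Inf`).
#' @return Scalar log-posterior (unnormalized).
#' @export
jointLogPosterior <- function(state, y, habitat, detectors, priors,
                              local_radius = Inf) {
  p <- state$params
  M <- state$M
  n_det <- nrow(y)
  lp <- param_logprior(p, priors)
  if (!is.finite(lp)) return(-Inf)
  logpi <- cbind(acLogPrior(habitat, p$beta[, 1], p$gamma[, 1]),
                 acLogPrior(habitat, p$beta[, 2], p$gamma[, 2]))
  for (i in seq_len(M)) {
    g <- state$sex[i] + 1L
    lp <- lp + logpi[state$s[i], g] +
      (if (state$z[i] == 1) log(p$psi) else log(1 - p$psi)) +
      (if (state$sex[i] == 1) log(p$psi_sex) else log(1 - p$psi_sex))
    y_i <- if (i <= n_det) y[i, ] else rep(0L, ncol(y))
    lp <- lp + encounterLogLik(y_i, state$s[i], state$z[i], state$sex[i],
                               p, habitat, detectors, local_radius)
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}
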