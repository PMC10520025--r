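test_that("effort GLM returns p0 at mean effort and is monotone", {
  expect_equal(baselineP0(0.3, 1.2, 0), 0.3)
  e <- seq(-2, 2, by = 0.5)
  p <- baselineP0(0.05, 0.7, e)
  expect_true(all(diff(p) > 0))
  # published parameter combination as a numeric spot check
  expect_equal(baselineP0(0.013, 0.579, 1), plogis(qlogis(0.013) + 0.579))
  expect_equal(round(baselineP0(0.013, 0.579, 1), 5), 0.02296)
  expect_error(baselineP0(1.2, 0, 0), "p0")
})

test_that("half-normal detection declines as the closed form prescribes", {
  expect_equal(detectionProb(0, 0.4, 150), 0.4)
  expect_equal(detectionProb(150, 0.4, 150) / 0.4, exp(-0.5))
  expect_equal(round(detectionProb(150, 1, 150), 5), 0.60653)
  d <- seq(0, 1000, by = 50)
  expect_true(all(diff(detectionProb(d, 0.2, 200)) < 0))
  expect_equal(detectionProb(600, 1, 200) / detectionProb(0, 1, 200),
               exp(-4.5))
  expect_equal(round(exp(-4.5), 6), 0.011109)
  expect_error(detectionProb(-1, 0.5, 100), "non-negative")
})

test_that("the AC prior is a softmax over cells and reduces to uniform", {
  hab <- toy_habitat(5, 5, seed = 40)
  lp0 <- acLogPrior(hab, c(1, -2, 0.5, 0), rep(0, 4))
  expect_equal(lp0, rep(log(1 / 25), 25))
  for (rep in 1:10) {
    beta <- rnorm(4, 0, 3)
    lp <- acLogPrior(hab, beta, rep(1, 4))
    expect_equal(sum(exp(lp)), 1, tolerance = 1e-12)
    expect_equal(exp(lp), softmax_oracle(as.vector(hab$X %*% beta)),
                 tolerance = 1e-12)
  }
  # five-cell single-covariate instance against the hand softmax
  hab5 <- toy_habitat(5, 1, seed = 1)
  hab5$X[, 1] <- c(-2, -1, 0, 1, 2); hab5$X[, 2:4] <- 0
  lp <- acLogPrior(hab5, c(1, 0, 0, 0), c(1, 0, 0, 0))
  expect_equal(exp(lp)[5], exp(2) / sum(exp(c(-2, -1, 0, 1, 2))),
               tolerance = 1e-12)
  expect_equal(round(exp(lp)[5], 5), 0.63641)
})

test_that("encounter log-likelihood matches hand binomial computations", {
  hab <- toy_habitat(3, 3, cell = 100, seed = 41)
  det <- detectorGrid(hab$centers[5, 1], hab$centers[5, 2], K = 4,
                      effort_raw = 2500)
  par <- scrParams(p0 = c(0.5, 0.5), sigma = c(1e6, 1e6))  # p ~ p0 at any d
  # z = 0: all-zero history contributes 0, any detection is impossible
  expect_equal(encounterLogLik(0L, 1, 0, 0, par, hab, det), 0)
  expect_equal(encounterLogLik(1L, 1, 0, 0, par, hab, det), -Inf)
  # K = 4, p = 0.5, y = 2 -> log C(4,2) 0.5^4 = log(0.375)
  expect_equal(encounterLogLik(2L, 5, 1, 0, par, hab, det),
               log(0.375), tolerance = 1e-9)
  expect_equal(round(log(0.375), 5), -0.98083)
  expect_error(encounterLogLik(5L, 5, 1, 0, par, hab, det), "K")
})

test_that("local evaluation converges to the full likelihood", {
  set.seed(42)
  hab <- toy_habitat(6, 6, seed = 42)
  det <- toy_detectors(hab, cells = c(1, 8, 15, 22, 29, 36))
  par <- scrParams(p0 = c(0.3, 0.2), sigma = c(200, 250), beta_search = 0.4)
  y_i <- integer(6); y_i[2] <- 1L
  cell <- 8
  full <- encounterLogLik(y_i, cell, 1, 0, par, hab, det, local_radius = Inf)
  expect_equal(encounterLogLik(y_i, cell, 1, 0, par, hab, det,
                               local_radius = 1e9), full)
  local <- encounterLogLik(y_i, cell, 1, 0, par, hab, det,
                           local_radius = 4 * 200)
  expect_lt(abs(local - full), 1e-6)
  # truncation bound on all-zero histories
  for (rep in 1:20) {
    cell <- sample(36, 1)
    r <- runif(1, 300, 1500)
    d <- sqrt((hab$centers[cell, 1] - det$x)^2 + (hab$centers[cell, 2] - det$y)^2)
    bound <- sum(det$K * baselineP0(par$p0[1], par$beta_search, det$effort_std) *
                   exp(-r^2 / (2 * par$sigma[1]^2)))
    fullz <- encounterLogLik(integer(6), cell, 1, 0, par, hab, det)
    locz <- encounterLogLik(integer(6), cell, 1, 0, par, hab, det,
                            local_radius = r)
    expect_lte(abs(fullz - locz), bound + 1e-12)
  }
})

test_that("the joint posterior decomposes exactly as the enumeration oracle", {
  hab <- toy_habitat(2, 2, cell = 250, seed = 44)
  det <- toy_detectors(hab, cells = c(1, 4), effort_raw = c(2000, 5000))
  y <- matrix(c(2L, 1L), 1, 2)
  obs_sex <- NA_real_
  p0 <- c(0.3, 0.4); sigma <- c(300, 250); bs <- 0.5
  beta_fix <- matrix(c(0.8, -0.4, 0.2, 0, -0.5, 0.3, 0.1, 0.6), 4, 2)
  psi <- 0.6; psi_sex <- 0.45
  par <- scrParams(p0 = p0, sigma = sigma, beta_search = bs, beta = beta_fix,
                   gamma = matrix(1, 4, 2), psi = psi, psi_sex = psi_sex)
  priors <- scrPriors()
  # log-posterior differences between configurations must match the oracle's
  # log-weight differences (shared parameter priors cancel)
  oracle_logw <- function(s, z, sex) {
    pi_ <- cbind(exp(acLogPrior(hab, beta_fix[, 1], rep(1, 4))),
                 exp(acLogPrior(hab, beta_fix[, 2], rep(1, 4))))
    lw <- 0
    for (i in seq_along(s)) {
      g <- sex[i] + 1
      p0e <- plogis(qlogis(p0[g]) + bs * det$effort_std)
      p <- p0e * exp(-((hab$centers[s[i], 1] - det$x)^2 +
                         (hab$centers[s[i], 2] - det$y)^2) / (2 * sigma[g]^2))
      yi <- if (i == 1) y[1, ] else c(0L, 0L)
      li <- if (z[i] == 1) sum(dbinom(yi, det$K, p, log = TRUE)) else
        (if (i == 1) -Inf else 0)
      lw <- lw + log(pi_[s[i], g]) + log(if (z[i] == 1) psi else 1 - psi) +
        log(if (sex[i] == 1) psi_sex else 1 - psi_sex) + li
    }
    lw
  }
  set.seed(1)
  states <- replicate(12, list(s = sample(4, 3, replace = TRUE),
                               z = c(1L, rbinom(2, 1, 0.5)),
                               sex = rbinom(3, 1, 0.5)), simplify = FALSE)
  jp <- vapply(states, function(st)
    jointLogPosterior(list(params = par, s = st$s, z = st$z, sex = st$sex,
                           M = 3), y, hab, det, priors), numeric(1))
  ow <- vapply(states, function(st) oracle_logw(st$s, st$z, st$sex), numeric(1))
  fin <- is.finite(ow)
  expect_true(any(fin))
  expect_equal(jp[fin] - jp[fin][1], ow[fin] - ow[fin][1], tolerance = 1e-10)
  expect_true(all(jp[!fin] == -Inf))

  # flat data (no detector searched): posterior over s is the AC prior
  par0 <- par
  st <- list(params = par0, s = c(1L, 2L, 3L), z = c(1L, 1L, 0L),
             sex = c(0L, 1L, 0L), M = 3)
  y0 <- matrix(integer(0), 1, 0)
  base <- jointLogPosterior(st, y0[, 0, drop = FALSE], hab,
                            structure(data.frame(detector_id = integer(),
                                                 x = numeric(), y = numeric(),
                                                 K = integer(),
                                                 effort_raw = numeric(),
                                                 effort_std = numeric()),
                                      class = c("detector_grid", "data.frame"),
                                      cell_size = 100),
                            priors)
  st2 <- st; st2$s[1] <- 4L
  base2 <- jointLogPosterior(st2, y0[, 0, drop = FALSE], hab,
                             structure(data.frame(detector_id = integer(),
                                                  x = numeric(), y = numeric(),
                                                  K = integer(),
                                                  effort_raw = numeric(),
                                                  effort_std = numeric()),
                                       class = c("detector_grid", "data.frame"),
                                       cell_size = 100),
                             priors)
  lpF <- acLogPrior(hab, beta_fix[, 1], rep(1, 4))
  expect_equal(base2 - base, lpF[4] - lpF[1], tolerance = 1e-12)

  # psi -> 1 forces z = 1 in the mode
  parP <- par; parP$psi <- 1 - 1e-12
  best <- which.max(vapply(states, function(st)
    jointLogPosterior(list(params = parP, s = st$s, z = st$z, sex = st$sex,
                           M = 3), y, hab, det, priors), numeric(1)))
  expect_true(all(states[[best]]$z == 1L))
})

test_that("the likelihood separates over individuals", {
  hab <- toy_habitat(4, 4, seed = 45)
  det <- toy_detectors(hab, cells = c(2, 9))
  y <- rbind(c(1L, 0L), c(0L, 2L))
  par <- scrParams(p0 = c(0.3, 0.3), sigma = c(300, 300))
  st <- list(params = par, s = c(2L, 9L, 5L, 12L), z = c(1L, 1L, 1L, 0L),
             sex = c(0L, 1L, 0L, 1L), M = 4)
  base <- jointLogPosterior(st, y, hab, det, scrPriors())
  # perturbing one individual's cell changes the total by exactly that
  # individual's term difference
  st2 <- st; st2$s[3] <- 6L
  d_tot <- jointLogPosterior(st2, y, hab, det, scrPriors()) - base
  lpF <- acLogPrior(hab, par$beta[, 1], par$gamma[, 1])
  d_ind <- (lpF[6] + encounterLogLik(c(0L, 0L), 6, 1, 0, par, hab, det)) -
    (lpF[5] + encounterLogLik(c(0L, 0L), 5, 1, 0, par, hab, det))
  expect_equal(d_tot, d_ind, tolerance = 1e-10)
})

test_that("parameter containers validate their invariants", {
  expect_error(scrParams(p0 = c(0, 0.5)), "p0")
  expect_error(scrParams(sigma = c(-1, 100)), "sigma")
  expect_error(scrParams(gamma = matrix(2, 4, 2)), "gamma")
  expect_error(scrParams(psi = 1.5), "psi")
  p <- scrParams()
  expect_s3_class(p, "scr_params")
})
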