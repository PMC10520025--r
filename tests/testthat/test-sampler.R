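test_that("configuration validates and defaults reproduce the reference run shape", {
  cfg <- samplerConfig()
  expect_equal(cfg$n_chains, 4)
  expect_equal(cfg$n_iter, 80000)
  expect_equal(cfg$burn_in, 20000)
  expect_equal(cfg$thin, 3)
  expect_equal(cfg$ac_thin, 10)
  expect_equal(cfg$M_multiplier, 6)
  expect_error(samplerConfig(n_iter = 100, burn_in = 100), "burn_in")
  expect_error(samplerConfig(thin = 0), "thin")
})

test_that("identical configuration and seed give bit-identical samples", {
  sh <- shared_small_fit()
  cfg <- samplerConfig(n_chains = 1, n_iter = 400, burn_in = 100, seed = 77)
  f1 <- runMCMC(sh$enc, sh$hab, sh$det, cfg)
  f2 <- runMCMC(sh$enc, sh$hab, sh$det, cfg)
  expect_identical(f1$chains[[1]]$params, f2$chains[[1]]$params)
  expect_identical(f1$chains[[1]]$ac, f2$chains[[1]]$ac)
})

test_that("draw bookkeeping respects thinning, bounds, and fixed z", {
  sh <- shared_small_fit()
  fit <- sh$fit
  cfg <- fit$config
  n_save <- (cfg$n_iter - cfg$burn_in) / cfg$thin
  for (ch in fit$chains) {
    expect_equal(nrow(ch$params), n_save)
    expect_true(all(ch$gamma %in% 0:1))
    expect_true(all(ch$params[, "N"] <= fit$M))
    expect_true(all(ch$params[, "N"] >= fit$n_detected))
    expect_true(all(ch$ac$z[, seq_len(fit$n_detected)] == 1L))
    expect_equal(ch$params[, "N"], ch$params[, "N_F"] + ch$params[, "N_M"])
  }
})

test_that("with the likelihood switched off, sampled marginals match the priors", {
  hab <- toy_habitat(4, 4, seed = 50)
  cfg <- samplerConfig(n_chains = 1, n_iter = 22000, burn_in = 2000, thin = 20,
                       M = 0, seed = 13)
  fit <- runMCMC(NULL, hab, NULL, cfg)
  P <- fit$chains[[1]]$params
  expect_gt(suppressWarnings(ks.test(P[, "p0_F"], "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(P[, "sigma_M"], "punif", 0, 5000))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(P[, "beta_search"], "pnorm", 0, 2))$p.value, 0.01)
  bF <- P[fit$chains[[1]]$gamma[, "gamma_TRI_F"] == 1, "beta_TRI_F"]
  expect_gt(suppressWarnings(ks.test(bF, "pnorm", 0, 2))$p.value, 0.01)
  # indicators recover their Bernoulli(0.5) prior
  expect_lt(abs(mean(fit$chains[[1]]$gamma) - 0.5), 0.03)
})

test_that("indicator toggles hold the prior with flat likelihood and find strong effects", {
  hab <- toy_habitat(10, 10, seed = 51)
  # flat likelihood: stationary P(gamma = 1) equals the prior
  set.seed(3)
  par <- list(beta = matrix(0, 4, 2), gamma = matrix(1, 4, 2))
  hits <- 0; nsweep <- 3000
  for (t in seq_len(nsweep)) {
    sw <- updateIndicators(par, hab)
    par <- sw$params
    hits <- hits + sum(par$gamma)
  }
  expect_lt(abs(hits / (8 * nsweep) - 0.5), 0.03)

  # 300 ACs simulated with beta = (1.5, 0, 0, 0): strong covariate selected,
  # pure-noise covariate mostly not
  pip_strong <- pip_null <- numeric(10)
  for (sd in 1:10) {
    set.seed(sd)
    pr <- softmax_oracle(as.vector(hab$X %*% c(1.5, 0, 0, 0)))
    cells <- sample.int(100, 300, replace = TRUE, prob = pr)
    cnt <- cbind(tabulate(cells[1:150], 100), tabulate(cells[151:300], 100))
    par <- list(beta = matrix(0, 4, 2), gamma = matrix(0, 4, 2))
    g_acc <- matrix(0, 4, 2)
    for (t in 1:2000) {
      sw <- updateIndicators(par, hab, counts = cnt)
      par <- sw$params
      # conditional refresh of included coefficients (simple random walk)
      for (g in 1:2) for (k in 1:4) {
        if (par$gamma[k, g] == 0) next
        bp <- par$beta[, g]; bp[k] <- bp[k] + rnorm(1, 0, 0.2)
        lr <- sum(cnt[, g] * (acLogPrior(hab, bp, par$gamma[, g]) -
                                acLogPrior(hab, par$beta[, g], par$gamma[, g]))) +
          dnorm(bp[k], 0, 2, log = TRUE) - dnorm(par$beta[k, g], 0, 2, log = TRUE)
        if (log(runif(1)) < lr) par$beta[, g] <- bp
      }
      if (t > 500) g_acc <- g_acc + par$gamma
    }
    pip <- g_acc / 1500
    pip_strong[sd] <- mean(pip[1, ])
    pip_null[sd] <- mean(pip[4, ])
  }
  expect_gt(mean(pip_strong), 0.95)
  expect_lt(mean(pip_null), 0.5)
})

test_that("split rank-normalized R-hat flags divergence and passes convergence", {
  set.seed(60)
  conv <- matrix(rnorm(4000), 1000, 4)
  expect_lt(gelmanRubin(conv)$rhat, 1.01)
  div <- cbind(rnorm(500, 0, 0.1), rnorm(500, 50, 0.1))
  expect_gt(gelmanRubin(div)$rhat, 1.1)
  const <- matrix(1, 100, 3)
  expect_warning(r <- gelmanRubin(const)$rhat, "variance")
  expect_true(is.na(r))
  sep <- cbind(rep(1, 100), rep(2, 100))
  expect_gt(gelmanRubin(sep)$rhat, 1.1)
})

test_that("R-hat on a fit covers continuous parameters and flags indicator-governed ones", {
  sh <- shared_small_fit()
  gr <- suppressWarnings(gelmanRubin(sh$fit))
  expect_true(all(c("p0_F", "sigma_M", "N", "psi_sex") %in% gr$parameter))
  expect_true(all(gr$visual_check[grepl("^beta_TRI", gr$parameter)]))
  expect_true(all(is.finite(gr$rhat[!gr$visual_check])))
})

test_that("abundance is insensitive to the augmentation ceiling when identified", {
  sh <- shared_small_fit()
  cfg6 <- samplerConfig(n_chains = 1, n_iter = 4000, burn_in = 1000,
                        M_multiplier = 6, seed = 21)
  cfg10 <- samplerConfig(n_chains = 1, n_iter = 4000, burn_in = 1000,
                         M_multiplier = 10, seed = 21)
  f6 <- runMCMC(sh$enc, sh$hab, sh$det, cfg6)
  f10 <- runMCMC(sh$enc, sh$hab, sh$det, cfg10)
  n6 <- f6$chains[[1]]$params[, "N"]; n10 <- f10$chains[[1]]$params[, "N"]
  expect_true(all(n6 <= f6$M))
  expect_lt(abs(mean(n6) - mean(n10)), sd(n6))
})
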