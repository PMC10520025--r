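test_that("PIP and PMP match the literal tabulation oracle", {
  set.seed(70)
  hab <- toy_habitat(3, 3, seed = 70)
  ndr <- 10
  gdraws <- matrix(rbinom(ndr * 8, 1, 0.5), ndr, 8)
  colnames(gdraws) <- paste0("gamma_", rep(c("TRI", "SSI", "CANOPY", "BARREN"), 2),
                             "_", rep(c("F", "M"), each = 4))
  s <- matrix(1L, 2, 4); z <- matrix(1L, 2, 4); sx <- matrix(0L, 2, 4)
  fit <- fake_fit(hab, s, z, sx, gamma = gdraws)
  fit$chains[[1]]$params <- cbind(fit$chains[[1]]$params[rep(1, ndr), ])
  fit$chains[[1]]$params[, 6:13] <- matrix(rnorm(ndr * 8), ndr)
  sel <- computePipPmp(fit)
  orF <- pip_pmp_oracle(gdraws[, 1:4])
  expect_equal(sel$pip$pip[sel$pip$sex == "F"], orF$pip)
  pmpF <- sel$pmp$pmp[sel$pmp$sex == "F"]
  names(pmpF) <- sel$pmp$configuration[sel$pmp$sex == "F"]
  expect_equal(pmpF, orF$pmp[names(pmpF)])
  expect_equal(sum(pmpF), 1, tolerance = 1e-12)

  # partition identity: PIP_k = sum of PMPs of configurations containing k
  for (k in 1:4) {
    inc <- substr(names(pmpF), k, k) == "1"
    expect_equal(sum(pmpF[inc]), orF$pip[k], tolerance = 1e-12)
  }
})

test_that("constant and never-included indicators are summarized correctly", {
  hab <- toy_habitat(3, 3, seed = 71)
  g <- matrix(rep(c(1L, 0L), c(4, 4)), 20, 8, byrow = TRUE)
  colnames(g) <- paste0("gamma_", rep(c("TRI", "SSI", "CANOPY", "BARREN"), 2),
                        "_", rep(c("F", "M"), each = 4))
  fit <- fake_fit(hab, matrix(1L, 20, 2), matrix(1L, 20, 2),
                  matrix(0L, 20, 2), gamma = g)
  sel <- computePipPmp(fit)
  expect_equal(sel$pip$pip[sel$pip$sex == "F"], rep(1, 4))
  expect_equal(sel$pip$pip[sel$pip$sex == "M"], rep(0, 4))
  expect_true(all(is.na(sel$pip$coef_mean[sel$pip$sex == "M"])))
})

test_that("abundance, density and surfaces satisfy the partition identities", {
  hab <- toy_habitat(4, 4, seed = 72)
  # single draw, 3 individuals: 2 in forest cells, sexes M, F, F
  fcells <- which(hab$forest); ocells <- which(!hab$forest)
  s <- matrix(c(fcells[1], fcells[2], ocells[1]), 1, 3)
  z <- matrix(1L, 1, 3)
  sx <- matrix(c(1L, 0L, 0L), 1, 3)
  fit <- fake_fit(hab, s, z, sx)
  ad <- abundanceDensity(fit)
  get <- function(r, sxx) ad[ad$region == r & ad$sex == sxx, "N_mean"]
  expect_equal(get("forest", "overall"), 2)
  expect_equal(get("overall", "M"), 1)
  expect_equal(get("overall", "overall"), 3)
  expect_equal(get("forest", "overall") + get("open", "overall"),
               get("overall", "overall"))
  expect_equal(ad$density_mean, ad$N_mean / ad$area_km2)

  # identities hold per draw on a sampled fit
  sh <- shared_small_fit()
  ad2 <- abundanceDensity(sh$fit, within_study = TRUE)
  dr <- attr(ad2, "draws")
  expect_equal(dr[["forest.overall"]] + dr[["open.overall"]],
               dr[["overall.overall"]])
  expect_equal(dr[["overall.F"]] + dr[["overall.M"]], dr[["overall.overall"]])

  # surface mass conservation
  surf <- densitySurface(sh$fit)
  expect_equal(sum(surf$all), mean(dr[["overall.overall"]]), tolerance = 1e-9)
  expect_equal(surf$all, surf$F + surf$M, tolerance = 1e-12)

  expect_error(abundanceDensity(sh$fit, regions = list(a = sh$hab$forest,
                                                       b = sh$hab$forest)),
               "partition")
})

test_that("a null point process yields a flat density surface", {
  hab <- toy_habitat(5, 5, seed = 73)
  cfg <- samplerConfig(n_chains = 1, n_iter = 6000, burn_in = 1000,
                       ac_thin = 5, M = 400, seed = 31,
                       update = list(indicators = FALSE, beta = FALSE),
                       init = list(gamma = matrix(0, 4, 2)))
  fit <- runMCMC(NULL, hab, NULL, cfg)
  surf <- densitySurface(fit)
  expect_gt(min(surf$all) / max(surf$all), 0.75)
})

test_that("a strong ruggedness effect shows up in the density surface", {
  sh <- shared_small_fit()
  hab2 <- sh$hab
  sc <- scrScenario(extent = c(0, 2000, 0, 2000), n_true_per_sex = c(150, 150),
                    beta_true = c(1.5, 0, 0, 0), p0_true = c(0.25, 0.25),
                    sigma_true = c(250, 250), beta_search_true = 0, seed = 41)
  truth <- simulatePopulation(hab2, sc)
  enc <- simulateSurvey(truth, hab2, sh$det, sc)
  cfg <- samplerConfig(n_chains = 1, n_iter = 3000, burn_in = 1000, seed = 33)
  fit <- runMCMC(enc, hab2, sh$det, cfg)
  surf <- densitySurface(fit)
  ct <- cor.test(hab2$X[, "TRI"], surf$all, method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("sex ratios reproduce the ratio arithmetic", {
  hab <- toy_habitat(4, 4, seed = 74)
  ndr <- 50
  # constant draws: 134 males and 186 females present in every draw
  M <- 134 + 186
  s <- matrix(sample(nCells(hab), ndr * M, replace = TRUE), ndr, M)
  z <- matrix(1L, ndr, M)
  sx <- matrix(rep(rep(c(1L, 0L), c(134, 186)), each = ndr), ndr, M)
  fit <- fake_fit(hab, s, z, sx)
  sr <- sexRatio(fit)
  expect_equal(round(sr$ratio_of_means, 2), 0.72)
  expect_equal(sr$ratio_of_means, 134 / 186, tolerance = 1e-12)

  sx2 <- matrix(rep(rep(c(1L, 0L), c(510, 506)), each = ndr), ndr, 1016)
  fit2 <- fake_fit(hab, matrix(sample(nCells(hab), ndr * 1016, replace = TRUE),
                               ndr, 1016), matrix(1L, ndr, 1016), sx2)
  expect_equal(round(sexRatio(fit2)$ratio_of_means, 2), 1.01)

  # equal counts every draw: ratio exactly one, no missing draws
  sx3 <- matrix(rep(c(1L, 0L), each = 5)[rep(1:10, each = 1)], ndr, 10,
                byrow = TRUE)
  fit3 <- fake_fit(hab, matrix(sample(nCells(hab), ndr * 10, replace = TRUE),
                               ndr, 10), matrix(1L, ndr, 10), sx3)
  sr3 <- sexRatio(fit3)
  expect_equal(sr3$ratio_mean, 1)
  expect_equal(sr3$n_ratio_missing, 0)
})

test_that("posterior summaries pool chains", {
  sh <- shared_small_fit()
  ps <- posteriorSummary(sh$fit)
  expect_true(all(c("p0_F", "sigma_M", "N", "psi_sex") %in% ps$parameter))
  expect_true(all(ps$lo <= ps$mean & ps$mean <= ps$hi))
})
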