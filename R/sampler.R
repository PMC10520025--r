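#' Sampler configuration
#'
#' Defaults reproduce the reference run shape: four independent chains of
#' 80,000 iterations with 20,000 burn-in, every third post-burn-in sample
#' retained for parameters and every tenth iteration retained for activity
#' centers, and data augmentation to `M = 6 x` the number of detected
#' individuals.
#'
#' @param n_chains number of independent chains (default 4).
#' @param n_iter iterations per chain (default 80000).
#' @param burn_in discarded initial iterations (default 20000); must be
#'   smaller than `n_iter`.
#' @param thin parameter thinning (default 3).
#' @param ac_thin thinning of the stored activity-center / inclusion / sex
#'   draws (default 10).
#' @param seed integer seed; chain `k` uses `seed + k`.
#' @param M explicit augmented population size, overriding `M_multiplier`.
#' @param M_multiplier data-augmentation factor (default 6: `M = 6 x n`).
#' @param proposal initial random-walk proposal standard deviations (on the
#'   transformed scales) for blocks `p0`, `sigma`, `beta_search`, `beta`.
#' @param adapt adapt proposal scales during burn-in (Robbins-Monro, frozen
#'   afterwards)?
#' @param target_accept target acceptance rate of the adaptation
#'   (default 0.37).
#' @param local_radius_mult local-evaluation radius as a multiple of the
#'   current sigma of each sex (default 4).
#' @param neighbor_radius radius (m) of the precomputed cell-detector
#'   neighbor structure; the effective truncation radius is
#'   `min(local_radius_mult * sigma, neighbor_radius)`. Defaults to a
#'   data-driven multiple of the apparent detection scale.
#' @param rj_redraw_beta draw `beta_k` afresh from its prior when an
#'   indicator toggles on (the reversible-jump move; default `TRUE`). With
#'   `FALSE` the indicator toggles around fixed coefficient values, which is
#'   the exact finite model used by the enumeration cross-checks.
#' @param update named list of logicals switching parameter blocks on or off
#'   (`detection`, `indicators`, `beta`, `s`, `z`, `sex`, `psi`); blocks
#'   switched off keep their initial values.
#' @param init optional named list of fixed initial values (any of `p0`,
#'   `sigma`, `beta_search`, `beta`, `gamma`, `psi`, `psi_sex`, `s`, `z`,
#'   `sex`).
#' @return An object of class `sampler_config`.
#' @export
samplerConfig <- function(n_chains = 4, n_iter = 80000, burn_in = 20000,
                          thin = 3, ac_thin = 10, seed = 1L, M = NULL,
                          M_multiplier = 6,
                          proposal = list(p0 = 0.4, sigma = 0.15,
                                          beta_search = 0.15, beta = 0.3),
                          adapt = TRUE, target_accept = 0.37,
                          local_radius_mult = 4, neighbor_radius = NULL,
                          rj_redraw_beta = TRUE,
                          update = list(), init = NULL) {
  if (burn_in >= n_iter) stopf("burn_in must be smaller than n_iter")
  if (thin < 1 || ac_thin < 1) stopf("thin and ac_thin must be >= 1")
  upd <- list(detection = TRUE, indicators = TRUE, beta = TRUE, s = TRUE,
              z = TRUE, sex = TRUE, psi = TRUE)
  upd[names(update)] <- update
  structure(list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, ac_thin = ac_thin, seed = as.integer(seed),
                 M = M, M_multiplier = M_multiplier, proposal = proposal,
                 adapt = adapt, target_accept = target_accept,
                 local_radius_mult = local_radius_mult,
                 neighbor_radius = neighbor_radius,
                 rj_redraw_beta = rj_redraw_beta, update = upd, init = init),
            class = "sampler_config")
}

# ---------------------------------------------------------------------------

#' Fit the sex-specific SCR model by Metropolis-within-Gibbs sampling
#'
#' Runs the full sampler: joint random-walk Metropolis on
#' `(logit(p0), log(sigma))` per sex and on `beta_search`; reversible-jump
#' indicator toggles and conditional Metropolis updates of the point-process
#' coefficients; Gibbs updates of the inclusion indicators `z` and latent
#' sexes; conjugate Beta updates of `psi` and `psi_sex`; and categorical
#' Gibbs updates of the activity-center cells (with local evaluation of the
#' state space), drawn last. All parameter updates marginalize the activity
#' centers of undetected augmented individuals analytically and the centers
#' are re-drawn from their full conditionals each iteration (a partially
#' collapsed Gibbs scheme; see the methods vignette). Chains run sequentially
#' with independent seeded streams; identical configuration and seed give
#' bit-identical output.
#'
#' @param enc an `encounter_data` (or `NULL` for a data-free prior run, in
#'   which case `config$M` must be given, possibly 0).
#' @param habitat a `habitat_grid`.
#' @param detectors a [detectorGrid()] (or `NULL` to switch the likelihood
#'   off).
#' @param config a [samplerConfig()].
#' @param priors an [scrPriors()].
#' @return An object of class `scr_fit`: per-chain parameter and indicator
#'   draw matrices, retained activity-center / inclusion / sex draws,
#'   acceptance rates, and the inputs needed by the posterior-product
#'   functions.
#' @export
runMCMC <- function(enc, habitat, detectors, config = samplerConfig(),
                    priors = scrPriors()) {
  C <- nCells(habitat)
  J <- if (is.null(detectors)) 0L else nrow(detectors)
  y <- if (is.null(enc)) matrix(0L, 0L, J) else enc$y
  n_det <- nrow(y)
  if (J > 0L && n_det > 0L && any(sweep(y, 2L, detectors$K, ">") > 0))
    stopf("encounter counts exceed the binomial trial counts K")
  obs_sex <- if (is.null(enc)) numeric(0) else enc$sex
  M <- config$M %||% (config$M_multiplier * n_det)
  if (M < n_det) stopf("M (%d) must be at least the number detected (%d)", M, n_det)

  d2 <- if (J > 0L)
    outer(habitat$centers[, 1], detectors$x, "-")^2 +
      outer(habitat$centers[, 2], detectors$y, "-")^2
  else matrix(0, C, 0L)
  d2t <- t(d2)

  # detection triplets in CSR by individual (0-based for the kernels)
  trip_j <- integer(0); trip_y <- numeric(0)
  trip_start <- integer(n_det); trip_count <- integer(n_det)
  for (i in seq_len(n_det)) {
    js <- which(y[i, ] > 0L)
    trip_start[i] <- length(trip_j) + 1L
    trip_count[i] <- length(js)
    trip_j <- c(trip_j, js - 1L)
    trip_y <- c(trip_y, as.numeric(y[i, js]))
  }

  # apparent detection scale, used only for initialization and the neighbor
  # structure
  spread <- rep(0, n_det)
  rms <- habitat$cell_size
  if (n_det > 0L && J > 0L) {
    cent <- matrix(0, n_det, 2)
    for (i in seq_len(n_det)) {
      ks <- seq.int(trip_start[i], length.out = trip_count[i])
      js <- trip_j[ks] + 1L
      w <- trip_y[ks]
      cent[i, ] <- c(sum(w * detectors$x[js]), sum(w * detectors$y[js])) / sum(w)
      spread[i] <- sqrt(max((detectors$x[js] - cent[i, 1])^2 +
                              (detectors$y[js] - cent[i, 2])^2))
    }
    rms <- max(habitat$cell_size,
               sqrt(mean(spread^2)) / sqrt(2) + habitat$cell_size / 2)
  }
  R_nb <- config$neighbor_radius %||%
    max(6 * rms, max(c(spread, 0)) + 2 * habitat$cell_size)

  # CSR neighbor structure: detectors within R_nb of each cell (0-based)
  nb_idx <- integer(0); nb_ptr <- integer(C + 1L); nb_d2 <- numeric(0)
  if (J > 0L) {
    # per cell, detectors within R_nb sorted by distance, so the kernels can
    # stop scanning at the current truncation radius
    nbl <- apply(d2, 1L, function(r) {
      w <- which(r <= R_nb^2)
      w[order(r[w])] - 1L
    }, simplify = FALSE)
    nb_ptr <- c(0L, cumsum(lengths(nbl)))
    nb_idx <- unlist(nbl, use.names = FALSE)
    nb_d2 <- unlist(lapply(seq_len(C), function(c) d2[c, nbl[[c]] + 1L]),
                    use.names = FALSE)
  }
  # candidate AC cells per detected individual: all cells within R_nb of the
  # detection centroid (a superset of the local-evaluation support), sorted
  # by centroid distance so the sampler can stop at the truncation radius
  cand <- vector("list", n_det)
  cand_d <- vector("list", n_det)
  for (i in seq_len(n_det)) {
    dd <- (habitat$centers[, 1] - cent[i, 1])^2 +
      (habitat$centers[, 2] - cent[i, 2])^2
    ci <- which(dd <= R_nb^2)
    if (!length(ci)) stopf("no habitat cell within %g m of individual %d", R_nb, i)
    o <- order(dd[ci])
    cand[[i]] <- ci[o]
    cand_d[[i]] <- dd[ci][o]
  }
  cand_ptr <- c(0L, cumsum(lengths(cand)))
  cand_idx <- as.integer(unlist(cand, use.names = FALSE))
  cand_d2 <- as.numeric(unlist(cand_d, use.names = FALSE))

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    chains[[ch]] <- run_one_chain(ch, y, obs_sex, habitat, detectors, d2t,
                                  nb_ptr, nb_idx, nb_d2, cand_ptr, cand_idx,
                                  cand_d2,
                                  trip_start, trip_count, trip_j, trip_y,
                                  if (n_det > 0L) cent else matrix(0, 0, 2),
                                  rms, R_nb, M, config, priors)
  }
  structure(list(chains = chains, config = config, priors = priors,
                 n_detected = n_det, M = M, habitat = habitat,
                 detectors = detectors, neighbor_radius = R_nb),
            class = "scr_fit")
}

#' @export
print.scr_fit <- function(x, ...) {
  ns <- nrow(x$chains[[1]]$params)
  cat(sprintf("<scr_fit> %d chains x %d retained draws; %d detected, M = %d\n",
              length(x$chains), ns, x$n_detected, x$M))
  pm <- colMeans(do.call(rbind, lapply(x$chains, `[[`, "params")))
  cat(sprintf("  N = %.1f, p0 = (%.4f, %.4f), sigma = (%.0f, %.0f) m\n",
              pm["N"], pm["p0_F"], pm["p0_M"], pm["sigma_F"], pm["sigma_M"]))
  invisible(x)
}

# one chain; RNG is already seeded by the caller
run_one_chain <- function(ch, y, obs_sex, habitat, detectors, d2t,
                          nb_ptr, nb_idx, nb_d2, cand_ptr, cand_idx, cand_d2,
                          trip_start, trip_count, trip_j, trip_y,
                          cent, rms, R_nb, M, config, priors) {
  C <- nCells(habitat)
  J <- nrow(d2t)
  n_det <- nrow(y)
  upd <- config$update
  lrm <- config$local_radius_mult
  eff <- if (J > 0L) detectors$effort_std else numeric(0)
  K <- if (J > 0L) detectors$K else integer(0)

  init <- config$init %||% list()
  # --- initialization (bounded re-tries to reach a finite posterior) ------
  for (attempt in 1:20) {
    p0 <- init[["p0"]] %||% rbeta(2, priors$p0_shape1, priors$p0_shape2)
    p0 <- pmin(pmax(p0, 1e-6), 1 - 1e-6)
    sigma <- init[["sigma"]] %||%
      (if (n_det > 0L) runif(2, max(habitat$cell_size / 2, rms * 0.7), rms * 1.5) *
         attempt^0.5
       else runif(2, 0, priors$sigma_max))
    sigma <- pmin(sigma, priors$sigma_max * 0.999)
    beta_search <- init[["beta_search"]] %||% rnorm(1, 0, min(priors$beta_sd, 1))
    beta <- init[["beta"]] %||% matrix(rnorm(8, 0, min(priors$beta_sd, 1)), 4, 2)
    beta <- matrix(beta, 4, 2)
    gamma <- matrix(init[["gamma"]] %||% rbinom(8, 1, priors$gamma_prob), 4, 2)
    psi <- init[["psi"]] %||% rbeta(1, priors$psi_shape1, priors$psi_shape2)
    psi <- min(max(psi, 0.02), 0.98)
    psi_sex <- init[["psi_sex"]] %||%
      rbeta(1, priors$psi_sex_shape1, priors$psi_sex_shape2)
    psi_sex <- min(max(psi_sex, 0.02), 0.98)

    s <- integer(M); zvec <- integer(M); sexvec <- integer(M)
    if (n_det > 0L) {
      for (i in seq_len(n_det))
        s[i] <- which.min((habitat$centers[, 1] - cent[i, 1])^2 +
                            (habitat$centers[, 2] - cent[i, 2])^2)
    }
    if (M > n_det) s[(n_det + 1):M] <- sample.int(C, M - n_det, replace = TRUE)
    if (!is.null(init[["s"]])) s <- init[["s"]]
    zvec[seq_len(n_det)] <- 1L
    if (M > n_det) zvec[(n_det + 1):M] <- rbinom(M - n_det, 1L, 0.5)
    if (!is.null(init[["z"]])) { zvec <- init[["z"]]; zvec[seq_len(n_det)] <- 1L }
    sexvec <- rbinom(M, 1L, psi_sex)
    known <- which(!is.na(obs_sex))
    sexvec[known] <- obs_sex[known]
    if (!is.null(init[["sex"]])) { sexvec <- init[["sex"]]; sexvec[known] <- obs_sex[known] }

    ll <- vapply(1:2, function(g) {
      di <- which(sexvec[seq_len(n_det)] == (g - 1L))
      ks <- sequence(trip_count[di], from = trip_start[di])
      p0e <- if (J > 0L) plogis(qlogis(p0[g]) + beta_search * eff) else numeric(0)
      r2g <- min(config$local_radius_mult * sigma[g], R_nb)^2
      hng <- cpp_halfnormal(nb_ptr, nb_d2, sigma[g], r2g)
      cpp_ll_det(d2t, nb_ptr, nb_idx, hng, p0e, sigma[g], r2g, K, s[di],
                 c(0L, cumsum(trip_count[di])), trip_j[ks], trip_y[ks])
    }, numeric(1))
    if (all(is.finite(ll))) break
    if (attempt == 20) stopf("could not initialize a finite posterior in 20 attempts")
  }
  logpi <- cbind(acLogPrior(habitat, beta[, 1], gamma[, 1]),
                 acLogPrior(habitat, beta[, 2], gamma[, 2]))

  # adaptation state: log proposal sds
  lsc <- c(p0_F = log(config$proposal$p0), p0_M = log(config$proposal$p0),
           sigma_F = log(config$proposal$sigma), sigma_M = log(config$proposal$sigma),
           beta_search = log(config$proposal$beta_search))
  lsc_beta <- matrix(log(config$proposal$beta), 4, 2)
  acc_n <- acc_k <- setNames(numeric(7), c(names(lsc), "gamma", "beta"))

  n_save <- floor((config$n_iter - config$burn_in) / config$thin)
  n_save_ac <- floor((config$n_iter - config$burn_in) / config$ac_thin)
  par_names <- c("p0_F", "p0_M", "sigma_F", "sigma_M", "beta_search",
                 paste0("beta_", rep(c("TRI", "SSI", "CANOPY", "BARREN"), 2),
                        "_", rep(c("F", "M"), each = 4)),
                 "psi", "psi_sex", "N", "N_F", "N_M")
  P <- matrix(NA_real_, n_save, length(par_names),
              dimnames = list(NULL, par_names))
  G <- matrix(NA_integer_, n_save, 8,
              dimnames = list(NULL, paste0("gamma_",
                rep(c("TRI", "SSI", "CANOPY", "BARREN"), 2), "_",
                rep(c("F", "M"), each = 4))))
  Sdr <- matrix(NA_integer_, n_save_ac, M)
  Zdr <- matrix(NA_integer_, n_save_ac, M)
  Xdr <- matrix(NA_integer_, n_save_ac, M)
  isave <- 0L; isave_ac <- 0L

  # detection CSR of the detected individuals of sex g. All parameter
  # updates marginalize the activity centers of the *undetected* augmented
  # individuals analytically (their per-individual marginal likelihood is
  # sum_c pi_c for z = 0, i.e. 1, and sum_c pi_c exp(zerolik_c) for z = 1),
  # which removes the feedback of prior-driven activity centers on the
  # parameter updates; the centers are re-drawn from their full conditionals
  # at the end of each iteration (a partially collapsed Gibbs scheme).
  prep_det <- function(g) {
    di <- which(sexvec[seq_len(n_det)] == (g - 1L))
    ks <- sequence(trip_count[di], from = trip_start[di])
    list(cells = s[di], ptr = c(0L, cumsum(trip_count[di])),
         j = trip_j[ks], y = trip_y[ks])
  }
  p0eff <- function(p0g, bs) if (J > 0L) plogis(qlogis(p0g) + bs * eff) else numeric(0)
  r2 <- function(sg) min(lrm * sg, R_nb)^2
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

  # per-sex cache of the half-normal CSR factor for the current sigma
  hn <- list(cpp_halfnormal(nb_ptr, nb_d2, sigma[1], r2(sigma[1])),
             cpp_halfnormal(nb_ptr, nb_d2, sigma[2], r2(sigma[2])))
  zl_of <- function(g, p0e, hng) {
    if (J == 0L) numeric(C) else cpp_zerolik_all(nb_ptr, nb_idx, hng, p0e, K, C)
  }
  zl <- cbind(zl_of(1, p0eff(p0[1], beta_search), hn[[1]]),
              zl_of(2, p0eff(p0[2], beta_search), hn[[2]]))
  lw <- c(lse(logpi[, 1] + zl[, 1]), lse(logpi[, 2] + zl[, 2]))

  for (t in seq_len(config$n_iter)) {
    adapting <- config$adapt && t <= config$burn_in
    astep <- min(0.25, 3 / sqrt(t))
    aug <- if (M > n_det) (n_det + 1L):M else integer(0)
    n1u <- c(sum(zvec[aug] == 1L & sexvec[aug] == 0L),
             sum(zvec[aug] == 1L & sexvec[aug] == 1L))
    det_g <- list(prep_det(1L), prep_det(2L))

    # (1) detection parameters ------------------------------------------
    if (upd$detection) {
      ll_det_of <- function(g, p0e, sg, hng) {
        dg <- det_g[[g]]
        cpp_ll_det(d2t, nb_ptr, nb_idx, hng, p0e, sg, r2(sg), K,
                   dg$cells, dg$ptr, dg$j, dg$y)
      }
      p0e_cur <- list(p0eff(p0[1], beta_search), p0eff(p0[2], beta_search))
      ll_det <- c(ll_det_of(1, p0e_cur[[1]], sigma[1], hn[[1]]),
                  ll_det_of(2, p0e_cur[[2]], sigma[2], hn[[2]]))
      # joint (p0, sigma) proposal per sex: the two ride a posterior ridge,
      # and a joint move needs one likelihood scan instead of two
      for (g in 1:2) {
        nmp <- c("p0_F", "p0_M")[g]; nms <- c("sigma_F", "sigma_M")[g]
        p0p <- plogis(qlogis(p0[g]) + rnorm(1, 0, exp(lsc[nmp])))
        sp <- sigma[g] * exp(rnorm(1, 0, exp(lsc[nms])))
        if (sp < priors$sigma_max) {
          p0ep <- p0eff(p0p, beta_search)
          hnp <- cpp_halfnormal(nb_ptr, nb_d2, sp, r2(sp))
          zlp <- zl_of(g, p0ep, hnp)
          lwp <- lse(logpi[, g] + zlp)
          lldp <- ll_det_of(g, p0ep, sp, hnp)
          logr <- (lldp + n1u[g] * lwp) - (ll_det[g] + n1u[g] * lw[g]) +
            stats::dbeta(p0p, priors$p0_shape1, priors$p0_shape2, log = TRUE) -
            stats::dbeta(p0[g], priors$p0_shape1, priors$p0_shape2, log = TRUE) +
            log(p0p * (1 - p0p)) - log(p0[g] * (1 - p0[g])) +
            log(sp) - log(sigma[g])
          a <- is.finite(logr) && log(runif(1)) < logr
          if (a) {
            p0[g] <- p0p; sigma[g] <- sp
            p0e_cur[[g]] <- p0ep; hn[[g]] <- hnp
            zl[, g] <- zlp; lw[g] <- lwp; ll_det[g] <- lldp
          }
        } else { logr <- -Inf; a <- FALSE }
        if (adapting) {
          d <- astep * (min(1, exp(min(logr, 0, na.rm = TRUE))) - config$target_accept)
          lsc[nmp] <- lsc[nmp] + d
          lsc[nms] <- lsc[nms] + d
        }
        if (t > config$burn_in) {
          acc_n[nmp] <- acc_n[nmp] + a; acc_k[nmp] <- acc_k[nmp] + 1
          acc_n[nms] <- acc_n[nms] + a; acc_k[nms] <- acc_k[nms] + 1
        }
      }
      if (t %% 2L == 0L || J == 0L) {
      bsp <- beta_search + rnorm(1, 0, exp(lsc["beta_search"]))
      p0epF <- p0eff(p0[1], bsp); p0epM <- p0eff(p0[2], bsp)
      zlpF <- zl_of(1, p0epF, hn[[1]]); zlpM <- zl_of(2, p0epM, hn[[2]])
      lwp <- c(lse(logpi[, 1] + zlpF), lse(logpi[, 2] + zlpM))
      lldp <- c(ll_det_of(1, p0epF, sigma[1], hn[[1]]),
                ll_det_of(2, p0epM, sigma[2], hn[[2]]))
      logr <- sum(lldp + n1u * lwp) - sum(ll_det + n1u * lw) +
        dnorm(bsp, 0, priors$beta_sd, log = TRUE) -
        dnorm(beta_search, 0, priors$beta_sd, log = TRUE)
      a <- is.finite(logr) && log(runif(1)) < logr
      if (a) {
        beta_search <- bsp; zl <- cbind(zlpF, zlpM); lw <- lwp; ll_det <- lldp
      }
      if (adapting) lsc["beta_search"] <- lsc["beta_search"] +
          astep * (min(1, exp(min(logr, 0, na.rm = TRUE))) - config$target_accept)
      if (t > config$burn_in) {
        acc_n["beta_search"] <- acc_n["beta_search"] + a
        acc_k["beta_search"] <- acc_k["beta_search"] + 1
      }
      }
    }

    # (2)-(3) point-process coefficients and indicators ------------------
    # counts cover the detected individuals only; the undetected enter
    # through the marginal terms n1u * logsumexp(logpi + zerolik)
    cnt <- cbind(tabulate(det_g[[1]]$cells, nbins = C),
                 tabulate(det_g[[2]]$cells, nbins = C))
    if (upd$indicators) {
      sw <- updateIndicators(list(beta = beta, gamma = gamma), habitat,
                             counts = cnt, priors = priors,
                             rj_redraw_beta = config$rj_redraw_beta,
                             logpi = logpi, zl = zl, n_undetected = n1u)
      beta <- sw$params$beta; gamma <- sw$params$gamma; logpi <- sw$logpi
      if (t > config$burn_in) {
        acc_n["gamma"] <- acc_n["gamma"] + sw$n_accept
        acc_k["gamma"] <- acc_k["gamma"] + 8
      }
    }
    if (upd$beta) {
      for (g in 1:2) for (k in 1:4) {
        if (gamma[k, g] == 0L) next
        bet_p <- beta[k, g] + rnorm(1, 0, exp(lsc_beta[k, g]))
        beta_try <- beta[, g]; beta_try[k] <- bet_p
        logpi_p <- ac_logprior_fast(habitat$X, beta_try, gamma[, g])
        logr <- sum(cnt[, g] * (logpi_p - logpi[, g])) +
          n1u[g] * (lse(logpi_p + zl[, g]) - lse(logpi[, g] + zl[, g])) +
          dnorm(bet_p, 0, priors$beta_sd, log = TRUE) -
          dnorm(beta[k, g], 0, priors$beta_sd, log = TRUE)
        a <- is.finite(logr) && log(runif(1)) < logr
        if (a) { beta[k, g] <- bet_p; logpi[, g] <- logpi_p }
        if (adapting) lsc_beta[k, g] <- lsc_beta[k, g] +
            astep * (min(1, exp(min(logr, 0, na.rm = TRUE))) - config$target_accept)
        if (t > config$burn_in) {
          acc_n["beta"] <- acc_n["beta"] + a; acc_k["beta"] <- acc_k["beta"] + 1
        }
      }
    }
    lw <- c(lse(logpi[, 1] + zl[, 1]), lse(logpi[, 2] + zl[, 2]))

    # (4) inclusion indicators z (marginal over the activity center) -----
    if (upd$z && length(aug)) {
      pz <- plogis(qlogis(psi) + lw[sexvec[aug] + 1L])
      zvec[aug] <- rbinom(length(aug), 1L, pz)
    }

    # (5) latent sex -----------------------------------------------------
    if (upd$sex && M > 0L) {
      unk_det <- which(is.na(obs_sex))
      if (length(unk_det)) {
        llb <- cpp_ll_det_bysex(d2t, zl[, 1], zl[, 2],
                                p0eff(p0[1], beta_search),
                                p0eff(p0[2], beta_search),
                                sigma[1], sigma[2],
                                r2(sigma[1]), r2(sigma[2]),
                                s[seq_len(n_det)], c(0L, cumsum(trip_count)),
                                trip_j, trip_y)
        lo <- qlogis(psi_sex) +
          (llb[unk_det, 2] + logpi[s[unk_det], 2]) -
          (llb[unk_det, 1] + logpi[s[unk_det], 1])
        sexvec[unk_det] <- rbinom(length(unk_det), 1L, plogis(lo))
      }
      if (length(aug)) {
        lo <- qlogis(psi_sex) + ifelse(zvec[aug] == 1L, lw[2] - lw[1], 0)
        sexvec[aug] <- rbinom(length(aug), 1L, plogis(lo))
      }
    }

    # (6) conjugate psi and psi_sex --------------------------------------
    if (upd$psi) {
      psi <- rbeta(1, priors$psi_shape1 + sum(zvec),
                   priors$psi_shape2 + M - sum(zvec))
      psi_sex <- rbeta(1, priors$psi_sex_shape1 + sum(sexvec),
                       priors$psi_sex_shape2 + M - sum(sexvec))
      psi <- min(max(psi, 1e-12), 1 - 1e-12)
      psi_sex <- min(max(psi_sex, 1e-12), 1 - 1e-12)
    }

    # (7) activity centers, drawn last from their full conditionals ------
    if (upd$s && M > 0L) {
      p0e_F <- p0eff(p0[1], beta_search); p0e_M <- p0eff(p0[2], beta_search)
      if (n_det > 0L) {
        news <- cpp_sample_s_detected(d2t, zl[, 1], zl[, 2], logpi[, 1], logpi[, 2],
                                      p0e_F, p0e_M, sigma[1], sigma[2],
                                      r2(sigma[1]), r2(sigma[2]),
                                      sexvec[seq_len(n_det)],
                                      cand_ptr, cand_idx, cand_d2,
                                      c(0L, cumsum(trip_count)), trip_j, trip_y,
                                      runif(n_det))
        if (any(news < 0L))
          stopf("activity-center update found no feasible cell (iteration %d)", t)
        s[seq_len(n_det)] <- news
      }
      if (length(aug)) {
        for (g in 1:2) {
          lp_z1 <- logpi[, g] + zl[, g]
          w1 <- exp(lp_z1 - max(lp_z1)); cw1 <- cumsum(w1)
          w0 <- exp(logpi[, g] - max(logpi[, g])); cw0 <- cumsum(w0)
          a1 <- aug[sexvec[aug] == (g - 1L) & zvec[aug] == 1L]
          a0 <- aug[sexvec[aug] == (g - 1L) & zvec[aug] == 0L]
          if (length(a1))
            s[a1] <- findInterval(runif(length(a1)) * cw1[C], cw1) + 1L
          if (length(a0))
            s[a0] <- findInterval(runif(length(a0)) * cw0[C], cw0) + 1L
        }
      }
    }

    # store ---------------------------------------------------------------
    if (t > config$burn_in) {
      tp <- t - config$burn_in
      if (tp %% config$thin == 0L && isave < n_save) {
        isave <- isave + 1L
        P[isave, ] <- c(p0, sigma, beta_search, beta[, 1], beta[, 2],
                        psi, psi_sex, sum(zvec),
                        sum(zvec == 1L & sexvec == 0L),
                        sum(zvec == 1L & sexvec == 1L))
        G[isave, ] <- c(gamma[, 1], gamma[, 2])
      }
      if (tp %% config$ac_thin == 0L && isave_ac < n_save_ac) {
        isave_ac <- isave_ac + 1L
        Sdr[isave_ac, ] <- s; Zdr[isave_ac, ] <- zvec; Xdr[isave_ac, ] <- sexvec
      }
    }
  }
  list(params = P, gamma = G, ac = list(s = Sdr, z = Zdr, sex = Xdr),
       acceptance = ifelse(acc_k > 0, acc_n / acc_k, NA),
       proposal_sd = exp(lsc), seed = config$seed + ch)
}

#' One reversible-jump sweep over the inclusion indicators
#'
#' For each sex and covariate, proposes toggling the inclusion indicator
#' `gamma[k, g]`; on activation the coefficient is drawn from its prior
#' (Kuo-Mallick prior-proposal move), so the prior density cancels from the
#' acceptance ratio, which reduces to the activity-center prior ratio times
#' the prior inclusion odds. With a flat likelihood (`counts = 0`) every
#' toggle is accepted and the stationary inclusion probability equals the
#' prior `gamma_prob`. With `rj_redraw_beta = FALSE` the indicators toggle
#' around the current fixed coefficient values (a plain Metropolis move on
#' the finite model with known coefficients).
#'
#' @param params list with elements `beta` (4 x 2) and `gamma` (4 x 2), e.g.
#'   an [scrParams()].
#' @param habitat a `habitat_grid`.
#' @param counts `nCells(habitat)` x 2 matrix of activity-center counts per
#'   cell and sex for the anchored (detected) individuals (default all zero:
#'   flat likelihood).
#' @param priors an [scrPriors()].
#' @param rj_redraw_beta draw the coefficient from its prior on activation?
#' @param logpi optional cached `nCells x 2` matrix of current log cell
#'   probabilities ([acLogPrior()] per sex).
#' @param zl optional `nCells x 2` matrix of all-zero-history log-likelihoods
#'   per cell and sex, for the collapsed marginal term of undetected
#'   population members.
#' @param n_undetected per-sex count of undetected `z = 1` individuals whose
#'   activity centers are marginalized out (see [runMCMC()]).
#' @return List with updated `params`, the updated `logpi` cache, and the
#'   number of accepted toggles `n_accept`.
#' @export
updateIndicators <- function(params, habitat, counts = NULL,
                             priors = scrPriors(), rj_redraw_beta = TRUE,
                             logpi = NULL, zl = NULL, n_undetected = c(0, 0)) {
  C <- nCells(habitat)
  counts <- counts %||% matrix(0, C, 2)
  zl <- zl %||% matrix(0, C, 2)
  logpi <- logpi %||% cbind(acLogPrior(habitat, params$beta[, 1], params$gamma[, 1]),
                            acLogPrior(habitat, params$beta[, 2], params$gamma[, 2]))
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  pri_on <- log(priors$gamma_prob) - log(1 - priors$gamma_prob)
  nacc <- 0L
  for (g in 1:2) for (k in 1:4) {
    # lazy proposal: attempt each toggle with probability 1/2, so the chain
    # is aperiodic even when every toggle would be accepted (flat likelihood)
    if (runif(1) < 0.5) next
    gam_p <- 1L - params$gamma[k, g]
    bet_p <- params$beta[k, g]
    if (gam_p == 1L && rj_redraw_beta) bet_p <- rnorm(1, 0, priors$beta_sd)
    beta_try <- params$beta[, g]; beta_try[k] <- bet_p
    gamma_try <- params$gamma[, g]; gamma_try[k] <- gam_p
    logpi_p <- ac_logprior_fast(habitat$X, beta_try, gamma_try)
    logr <- sum(counts[, g] * (logpi_p - logpi[, g])) +
      (if (n_undetected[g] > 0)
         n_undetected[g] * (lse(logpi_p + zl[, g]) - lse(logpi[, g] + zl[, g]))
       else 0) +
      (if (gam_p == 1L) pri_on else -pri_on)
    if (is.finite(logr) && log(runif(1)) < logr) {
      params$gamma[k, g] <- gam_p
      if (gam_p == 1L) params$beta[k, g] <- bet_p
      logpi[, g] <- logpi_p
      nacc <- nacc + 1L
    }
  }
  list(params = params, logpi = logpi, n_accept = nacc)
}
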