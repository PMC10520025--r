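# independent brute-force oracles, deliberately written as literal loops

tri_oracle <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      acc <- acc + (z[ii, jj] - z[i, j])^2
    }
    out[i, j] <- sqrt(acc)
  }
  out
}

winavg_oracle <- function(z, radius, res) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (ii in seq_len(nr)) for (jj in seq_len(nc)) {
      if (((ii - i)^2 + (jj - j)^2) * res^2 <= radius^2 + 1e-9)
        vals <- c(vals, z[ii, jj])
    }
    out[i, j] <- mean(vals, na.rm = TRUE)
  }
  out
}

softmax_oracle <- function(x) exp(x) / sum(exp(x))

# literal tabulation of PIP and PMP from an indicator draw matrix (draws x 4)
pip_pmp_oracle <- function(G) {
  pip <- numeric(4)
  for (k in 1:4) pip[k] <- sum(G[, k]) / nrow(G)
  labs <- character(nrow(G))
  for (r in seq_len(nrow(G))) labs[r] <- paste(G[r, ], collapse = "")
  all_cfg <- apply(expand.grid(rep(list(0:1), 4))[, 4:1], 1, paste, collapse = "")
  pmp <- sapply(sort(all_cfg), function(cf) mean(labs == cf))
  list(pip = pip, pmp = pmp)
}

# Exhaustive enumeration of the joint posterior of a tiny SCR instance with
# fixed continuous parameters. Detected individuals (rows of y) have z = 1;
# observed sexes (non-NA) are fixed. Returns the gamma posterior and the
# per-individual marginals of s, z, sex.
enum_posterior <- function(habitat, detectors, y, obs_sex, M, p0, sigma,
                           beta_search, beta_fix, psi, psi_sex,
                           gamma_prob = 0.5) {
  C <- nCells(habitat)
  J <- nrow(detectors)
  n_det <- nrow(y)
  d <- sqrt(outer(habitat$centers[, 1], detectors$x, "-")^2 +
              outer(habitat$centers[, 2], detectors$y, "-")^2)
  # likelihood of individual i at cell c, included (z=1), for each sex
  lik1 <- function(i, c, sex) {
    p0e <- plogis(qlogis(p0[sex + 1]) + beta_search * detectors$effort_std)
    p <- p0e * exp(-d[c, ]^2 / (2 * sigma[sex + 1]^2))
    yi <- if (i <= n_det) y[i, ] else rep(0, J)
    prod(dbinom(yi, detectors$K, p))
  }
  gamma_cfgs <- as.matrix(expand.grid(rep(list(0:1), 4)))
  ng <- nrow(gamma_cfgs)
  # per (gamma config, sex): cell probabilities
  pi_of <- function(gcfg, sex)
    softmax_oracle(as.vector(habitat$X %*% (beta_fix[, sex + 1] * gcfg)))
  # weights over joint gamma configs (female x male)
  Wg <- matrix(0, ng, ng)
  s_marg <- array(0, c(M, C)); z_marg <- numeric(M); sex_marg <- numeric(M)
  # per-individual table of w(s, z, sex) for a given (piF, piM)
  ind_table <- function(i, piF, piM) {
    w <- array(0, c(C, 2, 2))       # s, z+1, sex+1
    for (c in seq_len(C)) for (zi in 0:1) for (sx in 0:1) {
      if (i <= n_det && zi == 0) next
      if (i <= n_det && !is.na(obs_sex[i]) && obs_sex[i] != sx) next
      pri <- (if (sx == 1) psi_sex else 1 - psi_sex) *
        (if (zi == 1) psi else 1 - psi) *
        (if (sx == 1) piM[c] else piF[c])
      li <- if (zi == 1) lik1(i, c, sx) else
        (if (i <= n_det) 0 else 1)    # z=0 detected: impossible
      w[c, zi + 1, sx + 1] <- pri * li
    }
    w
  }
  gp <- function(gcfg) prod(ifelse(gcfg == 1, gamma_prob, 1 - gamma_prob))
  tabs <- vector("list", M)
  for (gf in seq_len(ng)) for (gm in seq_len(ng)) {
    piF <- pi_of(gamma_cfgs[gf, ], 0); piM <- pi_of(gamma_cfgs[gm, ], 1)
    m_i <- numeric(M)
    for (i in seq_len(M)) {
      tabs[[i]] <- ind_table(i, piF, piM)
      m_i[i] <- sum(tabs[[i]])
    }
    wt <- gp(gamma_cfgs[gf, ]) * gp(gamma_cfgs[gm, ]) * prod(m_i)
    Wg[gf, gm] <- wt
    if (wt > 0) {
      for (i in seq_len(M)) {
        cond <- tabs[[i]] / m_i[i]
        s_marg[i, ] <- s_marg[i, ] + wt * apply(cond, 1, sum)
        z_marg[i] <- z_marg[i] + wt * sum(cond[, 2, ])
        sex_marg[i] <- sex_marg[i] + wt * sum(cond[, , 2])
      }
    }
  }
  tot <- sum(Wg)
  pipF <- colSums(gamma_cfgs * rowSums(Wg)) / tot
  pipM <- colSums(gamma_cfgs * colSums(Wg)) / tot
  list(s = s_marg / tot, z = z_marg / tot, sex = sex_marg / tot,
       pip = cbind(F = pipF, M = pipM), Wg = Wg / tot)
}
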