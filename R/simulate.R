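#' Simulate terrain and land-cover rasters
#'
#' Generates a smooth seeded landscape: the DEM is a sum of random Gaussian
#' bumps, canopy and barren cover are independent smooth fields squashed into
#' `[0, 100]` percent, and the forest layer is the canopy field thresholded at
#' the scenario's `canopy_threshold`. The fields emulate the statistical
#' character (smoothness, bounded cover percentages, binary land cover) of
#' real DEM / canopy / land-cover products without reproducing any particular
#' landscape.
#'
#' @param scenario an [scrScenario()].
#' @return Named list of [scr_raster]s: `dem` (m), `canopy` (percent),
#'   `barren` (percent), `forest` (0/1).
#' @export
simulateLandscape <- function(scenario) {
  ext <- scenario$extent; res <- scenario$raster_resolution
  nx <- round((ext[2] - ext[1]) / res); ny <- round((ext[4] - ext[3]) / res)
  xs <- ext[1] + (seq_len(nx) - 0.5) * res
  ys <- ext[3] + (seq_len(ny) - 0.5) * res
  bump_field <- function(n, amp, scl) {
    f <- matrix(0, ny, nx)
    for (b in seq_len(n)) {
      cx <- runif(1, ext[1], ext[2]); cy <- runif(1, ext[3], ext[4])
      a <- amp * runif(1, 0.5, 1) * sample(c(-1, 1), 1)
      s <- scl * runif(1, 0.5, 1.5)
      f <- f + a * exp(-(outer(ys, xs, function(y, x)
        ((x - cx)^2 + (y - cy)^2))) / (2 * s^2))
    }
    f
  }
  with_rng(scenario$seed + 1L, {
    dem <- 1000 + bump_field(scenario$n_bumps, scenario$bump_amplitude,
                             scenario$bump_scale)
    g_can <- bump_field(scenario$n_bumps, 1, scenario$bump_scale)
    g_bar <- bump_field(scenario$n_bumps, 1, scenario$bump_scale)
    squash <- function(g, shift = 0) {
      s <- sd(g)
      if (s == 0) matrix(100 * plogis(shift), nrow(g), ncol(g))
      else 100 * plogis((g - mean(g)) / s + shift)
    }
    canopy <- squash(g_can)
    barren <- squash(g_bar, shift = -1)
    forest <- (canopy > scenario$canopy_threshold) + 0
    lapply(list(dem = dem, canopy = canopy, barren = barren, forest = forest),
           scr_raster, xll = ext[1], yll = ext[3], res = res)
  })
}

#' Simulate the true population
#'
#' Places activity centers (ACs) on the habitat grid by the inhomogeneous
#' point process the model assumes: each AC's cell is drawn with probability
#' proportional to `exp(X %*% beta_true[, sex])`, and sexes are assigned in
#' the requested counts. The model treats ACs at cell resolution, so detection
#' in [simulateSurvey()] is computed from the AC's cell center; the reported
#' `ac` coordinates add a uniform within-cell jitter for map realism only.
#'
#' @param habitat a `habitat_grid` (standardized covariates).
#' @param scenario an [scrScenario()].
#' @return An object of class `simulated_truth`: list with `ac` (n x 2
#'   jittered coordinates), `cell` (habitat cell index per individual), `sex`
#'   (0 female / 1 male), and `cell_counts` (ACs per habitat cell).
#' @export
simulatePopulation <- function(habitat, scenario) {
  C <- nCells(habitat)
  if (C == 0L) stopf("habitat grid has zero cells")
  stopifnot(ncol(habitat$X) == 4L)
  with_rng(scenario$seed + 2L, {
    cells <- integer(0); sexes <- integer(0)
    for (g in 1:2) {
      n <- scenario$n_true_per_sex[g]
      if (n == 0L) next
      eta <- as.vector(habitat$X %*% scenario$beta_true[, g])
      pr <- exp(eta - max(eta)); pr <- pr / sum(pr)
      cells <- c(cells, sample.int(C, n, replace = TRUE, prob = pr))
      sexes <- c(sexes, rep(g - 1L, n))
    }
    half <- habitat$cell_size / 2
    ac <- habitat$centers[cells, , drop = FALSE] +
      matrix(runif(2 * length(cells), -half, half), ncol = 2)
    structure(list(ac = ac, cell = cells, sex = sexes,
                   cell_counts = tabulate(cells, nbins = C)),
              class = "simulated_truth")
  })
}

#' @export
print.simulated_truth <- function(x, ...) {
  cat(sprintf("<simulated_truth> %d individuals (%d F, %d M) on %d occupied cells\n",
              length(x$cell), sum(x$sex == 0), sum(x$sex == 1),
              sum(x$cell_counts > 0)))
  invisible(x)
}

#' Simulate a non-invasive genetic sampling survey
#'
#' Draws encounter counts `y[i, j] ~ Binomial(K[j], p[i, j])` with
#' `p[i, j] = invlogit(logit(p0_sex) + beta_search * effort_std[j]) *
#' exp(-d[i, j]^2 / (2 * sigma_sex^2))`, where `d` is the distance from the
#' individual's AC cell center to the detector center. Each encounter is
#' placed in a distinct searched sub-cell of the detector. Individuals never
#' detected are dropped from the returned encounter data (mimicking field
#' data) but reported in the `undetected` element; a fraction of detected
#' individuals has its sex label removed completely at random.
#'
#' @param truth a `simulated_truth` from [simulatePopulation()].
#' @param habitat the `habitat_grid` the truth was simulated on.
#' @param detectors a [detectorGrid()].
#' @param scenario an [scrScenario()].
#' @param survey_seed optional seed for the survey sub-stream only (defaults
#'   to `scenario$seed + 3`); varying it re-draws the survey while leaving the
#'   landscape and population untouched.
#' @return An `encounter_data` with extra elements `undetected` (indices into
#'   `truth`), and `truth_index` (row of `truth` for each detected
#'   individual).
#' @export
simulateSurvey <- function(truth, habitat, detectors, scenario,
                           survey_seed = NULL) {
  if (nrow(detectors) == 0L) stopf("detector grid is empty")
  with_rng(survey_seed %||% (scenario$seed + 3L), {
    n <- length(truth$cell)
    acx <- habitat$centers[truth$cell, 1]; acy <- habitat$centers[truth$cell, 2]
    d2 <- outer(acx, detectors$x, "-")^2 + outer(acy, detectors$y, "-")^2
    p0eff <- matrix(vapply(1:2, function(g)
      plogis(qlogis(scenario$p0_true[g]) +
               scenario$beta_search_true * detectors$effort_std),
      numeric(nrow(detectors))),
      nrow = nrow(detectors))                # J x 2; qlogis(0) = -Inf -> p = 0
    p <- t(p0eff)[truth$sex + 1L, , drop = FALSE] *
      exp(-d2 / (2 * scenario$sigma_true[truth$sex + 1L]^2))
    y <- matrix(rbinom(length(p), size = rep(detectors$K, each = n), prob = p),
                nrow = n)
    detected <- which(rowSums(y) > 0L)
    undetected <- setdiff(seq_len(n), detected)

    ids <- sprintf("ind%03d", detected)
    sex <- truth$sex[detected]
    if (length(detected) && scenario$unknown_sex_rate > 0) {
      hide <- runif(length(detected)) < scenario$unknown_sex_rate
      sex[hide] <- NA
    }
    subs <- attr(detectors, "sub_cells")
    yk <- y[detected, , drop = FALSE]
    nz <- which(yk > 0L, arr.ind = TRUE)
    detections <- if (nrow(nz)) {
      nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
      cnt <- yk[nz]
      picked <- lapply(seq_len(nrow(nz)), function(r) {
        js <- subs[[nz[r, 2]]]
        if (length(js) == 1L) js else sample(js, cnt[r])
      })
      ii <- rep(nz[, 1], lengths(picked)); jj <- rep(nz[, 2], lengths(picked))
      pk <- unlist(picked, use.names = FALSE)
      q <- attr(detectors, "cell_size") / 4
      data.frame(individual_id = ids[ii],
                 detector_id = detectors$detector_id[jj], sub_cell = pk,
                 x = detectors$x[jj] + c(-q, q, -q, q)[pk],
                 y = detectors$y[jj] + c(-q, -q, q, q)[pk])
    } else {
      data.frame(individual_id = character(), detector_id = integer(),
                 sub_cell = integer(), x = numeric(), y = numeric())
    }
    out <- encounterData(yk, ids, sex, detections)
    dimnames(out$y) <- list(ids, detectors$detector_id)
    out$undetected <- undetected
    out$truth_index <- detected
    out
  })
}

#' Simulate unstructured search tracks
#'
#' Correlated random walks inside the scenario extent, emulating GPS search
#' tracks from which detectors and effort are derived.
#'
#' @param scenario an [scrScenario()].
#' @param n_tracks number of tracks.
#' @param n_steps steps per track.
#' @param step_length mean step length in meters.
#' @return Data frame with columns `track_id`, `x`, `y`.
#' @export
simulateTracks <- function(scenario, n_tracks = 5, n_steps = 200,
                           step_length = 30) {
  ext <- scenario$extent
  with_rng(scenario$seed + 4L, {
    out <- lapply(seq_len(n_tracks), function(t) {
      x <- runif(1, ext[1] + 0.1 * diff(ext[1:2]), ext[2] - 0.1 * diff(ext[1:2]))
      y <- runif(1, ext[3] + 0.1 * diff(ext[3:4]), ext[4] - 0.1 * diff(ext[3:4]))
      ang <- runif(1, 0, 2 * pi)
      xs <- numeric(n_steps); ys <- numeric(n_steps)
      for (s in seq_len(n_steps)) {
        ang <- ang + rnorm(1, 0, 0.4)
        x <- min(max(x + step_length * cos(ang), ext[1]), ext[2])
        y <- min(max(y + step_length * sin(ang), ext[3]), ext[4])
        xs[s] <- x; ys[s] <- y
      }
      data.frame(track_id = t, x = xs, y = ys)
    })
    do.call(rbind, out)
  })
}
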