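# shared fixture builders; everything is generated in code

square_poly <- function(w, x0 = 0, y0 = 0) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + w, y0 + w))
}

# a habitat grid with standardized random covariates, built directly
toy_habitat <- function(nx = 5, ny = 5, cell = 250, seed = 1,
                        forest_frac = 0.4) {
  set.seed(seed)
  n <- nx * ny
  centers <- cbind(x = rep((seq_len(nx) - 0.5) * cell, each = ny),
                   y = rep((seq_len(ny) - 0.5) * cell, times = nx))
  X <- matrix(rnorm(4 * n), n, 4)
  X <- matrix(as.numeric(scale(X)), n, 4,
              dimnames = list(NULL, c("TRI", "SSI", "CANOPY", "BARREN")))
  structure(list(centers = centers, cell_size = cell,
                 cell_area_km2 = (cell / 1000)^2, X = X,
                 forest = runif(n) < forest_frac,
                 in_study = rep(TRUE, n), buffer = 0,
                 standardization = list(mean = rep(0, 4), sd = rep(1, 4))),
            class = "habitat_grid")
}

# detector grid covering given cells of a habitat (K = 4, unit effort)
toy_detectors <- function(habitat, cells, K = 4, effort_raw = NULL,
                          cell_size = 100) {
  n <- length(cells)
  detectorGrid(habitat$centers[cells, 1], habitat$centers[cells, 2],
               K = rep(K, n),
               effort_raw = effort_raw %||% rep(2500, n),
               cell_size = cell_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal encounter_data built from a detections table
enc_from_detections <- function(det, detector_ids = NULL, sex = NULL) {
  ids <- sort(unique(det$individual_id))
  dids <- detector_ids %||% sort(unique(det$detector_id))
  y <- matrix(0L, length(ids), length(dids), dimnames = list(ids, dids))
  u <- unique(det[, c("individual_id", "detector_id", "sub_cell")])
  for (r in seq_len(nrow(u))) {
    i <- match(u$individual_id[r], ids)
    j <- match(as.character(u$detector_id[r]), as.character(dids))
    y[i, j] <- y[i, j] + 1L
  }
  sexscr:::encounterData(y, ids, sex %||% rep(0, length(ids)), det)
}

# a fake one-chain fit with prescribed activity-center draws, for testing the
# posterior products without running the sampler
fake_fit <- function(habitat, s, z, sex, params = NULL, gamma = NULL) {
  ndr <- nrow(s)
  if (is.null(params)) {
    params <- matrix(0.5, ndr, 18)
    colnames(params) <- c("p0_F", "p0_M", "sigma_F", "sigma_M", "beta_search",
                          paste0("beta_", rep(c("TRI", "SSI", "CANOPY", "BARREN"), 2),
                                 "_", rep(c("F", "M"), each = 4)),
                          "psi", "psi_sex", "N", "N_F", "N_M")
    params[, "N"] <- rowSums(z)
    params[, "N_F"] <- rowSums(z == 1L & sex == 0L)
    params[, "N_M"] <- rowSums(z == 1L & sex == 1L)
  }
  if (is.null(gamma)) {
    gamma <- matrix(1L, ndr, 8)
    colnames(gamma) <- paste0("gamma_", rep(c("TRI", "SSI", "CANOPY", "BARREN"), 2),
                              "_", rep(c("F", "M"), each = 4))
  }
  structure(list(chains = list(list(params = params, gamma = gamma,
                                    ac = list(s = s, z = z, sex = sex))),
                 config = samplerConfig(n_chains = 1, n_iter = 20, burn_in = 10),
                 priors = scrPriors(), n_detected = 0, M = ncol(s),
                 habitat = habitat, detectors = NULL),
            class = "scr_fit")
}

# one shared small synthetic dataset + fit, memoized across tests in a file
shared_env <- new.env()
shared_small_fit <- function() {
  if (!is.null(shared_env$fit)) return(shared_env)
  hab <- toy_habitat(8, 8, seed = 42)
  set.seed(7)
  det <- toy_detectors(hab, sample(nCells(hab), 30))
  sc <- scrScenario(extent = c(0, 2000, 0, 2000), n_true_per_sex = c(40, 40),
                    p0_true = c(0.15, 0.15), sigma_true = c(250, 250),
                    beta_search_true = 0, seed = 5)
  truth <- simulatePopulation(hab, sc)
  enc <- simulateSurvey(truth, hab, det, sc)
  cfg <- samplerConfig(n_chains = 2, n_iter = 1500, burn_in = 500, thin = 2,
                       ac_thin = 5, seed = 9)
  shared_env$hab <- hab; shared_env$det <- det; shared_env$truth <- truth
  shared_env$enc <- enc
  shared_env$fit <- runMCMC(enc, hab, det, cfg)
  shared_env
}
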