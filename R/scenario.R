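#' Define a synthetic survey scenario
#'
#' Bundles every knob of the synthetic-data generator: landscape extent and
#' resolution, true population sizes per sex, the true point-process
#' coefficients, detection parameters, and the seed. The same scenario always
#' regenerates bit-identical data; landscape, population, and survey draw from
#' independent sub-streams derived from `seed`, so changing only the survey
#' seed leaves the simulated truth unchanged.
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in meters.
#' @param raster_resolution fine-raster resolution in meters (default 25).
#' @param n_true_per_sex integer vector `c(female, male)` of true population
#'   sizes.
#' @param beta_true 4 x 2 matrix of point-process coefficients on the
#'   standardized covariates (rows TRI, SSI, CANOPY, BARREN; columns female,
#'   male). A single vector is recycled to both sexes.
#' @param p0_true baseline detection probability per sex `c(female, male)`,
#'   each in `[0, 1]` (0 and 1 give degenerate never/always detection).
#' @param sigma_true half-normal scale per sex in meters, positive.
#' @param beta_search_true effort coefficient on the logit scale.
#' @param unknown_sex_rate fraction of detected individuals whose sex label is
#'   removed completely at random (default 0.05).
#' @param n_bumps,bump_amplitude,bump_scale Gaussian-bump landscape controls:
#'   number of bumps, elevation amplitude in meters, and spatial scale in
#'   meters.
#' @param canopy_threshold canopy percentage above which a cell counts as
#'   forest (default 50).
#' @param seed integer seed.
#' @return An object of class `scr_scenario`.
#' @export
scrScenario <- function(extent = c(0, 5000, 0, 5000),
                        raster_resolution = 25,
                        n_true_per_sex = c(100, 100),
                        beta_true = c(1.2, -0.5, -0.8, 0),
                        p0_true = c(0.02, 0.02),
                        sigma_true = c(200, 200),
                        beta_search_true = 0.5,
                        unknown_sex_rate = 0.05,
                        n_bumps = 25, bump_amplitude = 300, bump_scale = 800,
                        canopy_threshold = 50,
                        seed = 1L) {
  if (length(extent) != 4L || extent[2] <= extent[1] || extent[4] <= extent[3])
    stopf("extent must be c(xmin, xmax, ymin, ymax) with positive width and height")
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  if (abs(w %% raster_resolution) > 1e-9 || abs(h %% raster_resolution) > 1e-9)
    stopf("extent must be divisible by raster_resolution")
  if (any(n_true_per_sex < 0)) stopf("n_true_per_sex must be >= 0")
  beta_true <- matrix(beta_true, nrow = 4L, ncol = 2L,
                      dimnames = list(c("TRI", "SSI", "CANOPY", "BARREN"),
                                      c("F", "M")))
  p0_true <- rep_len(p0_true, 2L)
  sigma_true <- rep_len(sigma_true, 2L)
  if (any(p0_true < 0 | p0_true > 1)) stopf("p0_true must be in [0, 1]")
  if (any(sigma_true <= 0)) stopf("sigma_true must be > 0")
  if (unknown_sex_rate < 0 || unknown_sex_rate > 1)
    stopf("unknown_sex_rate must be in [0, 1]")
  structure(list(extent = extent, raster_resolution = raster_resolution,
                 n_true_per_sex = as.integer(rep_len(n_true_per_sex, 2L)),
                 beta_true = beta_true, p0_true = p0_true,
                 sigma_true = sigma_true, beta_search_true = beta_search_true,
                 unknown_sex_rate = unknown_sex_rate,
                 n_bumps = n_bumps, bump_amplitude = bump_amplitude,
                 bump_scale = bump_scale, canopy_threshold = canopy_threshold,
                 seed = as.integer(seed)),
            class = "scr_scenario")
}

#' @export
print.scr_scenario <- function(x, ...) {
  cat(sprintf("<scr_scenario> %g x %g km, %d F + %d M, seed %d\n",
              diff(x$extent[1:2]) / 1000, diff(x$extent[3:4]) / 1000,
              x$n_true_per_sex[1], x$n_true_per_sex[2], x$seed))
  cat(sprintf("  p0 = (%g, %g), sigma = (%g, %g) m, beta_search = %g\n",
              x$p0_true[1], x$p0_true[2], x$sigma_true[1], x$sigma_true[2],
              x$beta_search_true))
  invisible(x)
}

#' Read or write a scenario as YAML
#'
#' @param scenario an [scrScenario()].
#' @param path file path.
#' @export
writeScenario <- function(scenario, path) {
  obj <- unclass(scenario)
  obj$beta_true <- as.vector(obj$beta_true)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writeScenario
#' @export
readScenario <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(scrScenario, obj)
}
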