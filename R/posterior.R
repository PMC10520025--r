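#' Posterior inclusion and model probabilities
#'
#' Tabulates the indicator draws pooled over chains. The posterior inclusion
#' probability (PIP) of a covariate is the proportion of draws in which it
#' was in the model; the posterior model probability (PMP) of each of the 16
#' covariate configurations (including the null model) is the proportion of
#' draws with exactly that configuration. Coefficient summaries use only
#' draws with `gamma = 1` (model-averaged coefficients); a covariate never
#' included gets PIP 0 and missing coefficient summaries.
#'
#' @param fit an `scr_fit`.
#' @return An object of class `selection_summary`: list with `pip` (data
#'   frame: sex, covariate, pip, coef_mean, coef_lo, coef_hi) and `pmp`
#'   (data frame: sex, configuration label, pmp; sums to 1 per sex).
#' @export
computePipPmp <- function(fit) {
  G <- do.call(rbind, lapply(fit$chains, `[[`, "gamma"))
  P <- do.call(rbind, lapply(fit$chains, `[[`, "params"))
  covs <- c("TRI", "SSI", "CANOPY", "BARREN")
  pip <- do.call(rbind, lapply(c("F", "M"), function(sx) {
    do.call(rbind, lapply(covs, function(cv) {
      g <- G[, paste0("gamma_", cv, "_", sx)]
      b <- P[g == 1L, paste0("beta_", cv, "_", sx)]
      data.frame(sex = sx, covariate = cv, pip = mean(g),
                 coef_mean = if (length(b)) mean(b) else NA_real_,
                 coef_lo = if (length(b)) unname(quantile(b, 0.025)) else NA_real_,
                 coef_hi = if (length(b)) unname(quantile(b, 0.975)) else NA_real_)
    }))
  }))
  pmp <- do.call(rbind, lapply(c("F", "M"), function(sx) {
    gm <- G[, paste0("gamma_", covs, "_", sx), drop = FALSE]
    lab <- apply(gm, 1L, paste, collapse = "")
    all_cfg <- apply(expand.grid(rep(list(0:1), 4))[, 4:1], 1L, paste, collapse = "")
    tab <- table(factor(lab, levels = sort(all_cfg)))
    data.frame(sex = sx, configuration = names(tab),
               pmp = as.numeric(tab) / length(lab))
  }))
  structure(list(pip = pip, pmp = pmp), class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat("Posterior inclusion probabilities and model-averaged coefficients\n")
  print(x$pip, row.names = FALSE, digits = 3)
  invisible(x)
}

# pooled activity-center draws as a list of matrices
pool_ac <- function(fit) {
  list(s = do.call(rbind, lapply(fit$chains, function(ch) ch$ac$s)),
       z = do.call(rbind, lapply(fit$chains, function(ch) ch$ac$z)),
       sex = do.call(rbind, lapply(fit$chains, function(ch) ch$ac$sex)))
}

#' Sex- and region-specific abundance and density
#'
#' For every retained activity-center draw, counts the population members
#' (`z = 1`) whose activity center falls in each region and sex class, then
#' summarizes across draws (posterior mean and central 95% credible
#' interval). Densities divide by the region's area in km^2. By default only
#' habitat cells inside the unbuffered study area are counted (the buffer
#' exists to let activity centers fall outside the searched region, not to be
#' part of the reported area); set `within_study = FALSE` to use the whole
#' buffered habitat. Default regions are the forest/open partition of the
#' habitat grid.
#'
#' @param fit an `scr_fit`.
#' @param regions named list of logical cell masks partitioning the habitat
#'   (default `list(forest = , open = )` from the grid's forest mask).
#' @param within_study restrict counting and area to cells inside the study
#'   polygon (default `TRUE`).
#' @return An object of class `density_summary`: data frame with columns
#'   `region`, `sex`, `N_mean`, `N_lo`, `N_hi`, `density_mean`, `density_lo`,
#'   `density_hi`, `area_km2`, plus attribute `draws` holding the per-draw
#'   counts.
#' @export
abundanceDensity <- function(fit, regions = NULL, within_study = TRUE) {
  habitat <- fit$habitat
  C <- nCells(habitat)
  regions <- regions %||% list(forest = habitat$forest, open = !habitat$forest)
  cover <- Reduce(`+`, regions)
  if (any(cover != 1L))
    stopf("region masks must partition the habitat (every cell in exactly one region)")
  scope <- if (within_study) habitat$in_study else rep(TRUE, C)
  ac <- pool_ac(fit)
  ndr <- nrow(ac$s)
  sexes <- list(F = 0L, M = 1L, overall = c(0L, 1L))
  regs <- c(regions, list(overall = rep(TRUE, C)))
  out <- list(); draws_out <- list()
  for (rn in names(regs)) {
    in_reg <- regs[[rn]] & scope
    area <- sum(in_reg) * habitat$cell_area_km2
    member <- matrix(in_reg[ac$s], nrow = ndr) & ac$z == 1L
    for (sn in names(sexes)) {
      cnt <- rowSums(member & matrix(ac$sex %in% sexes[[sn]], nrow = ndr))
      qs <- quantile(cnt, c(0.025, 0.975))
      out[[length(out) + 1L]] <- data.frame(
        region = rn, sex = sn, N_mean = mean(cnt), N_lo = unname(qs[1]),
        N_hi = unname(qs[2]), density_mean = mean(cnt) / area,
        density_lo = unname(qs[1]) / area, density_hi = unname(qs[2]) / area,
        area_km2 = area)
      draws_out[[paste(rn, sn, sep = ".")]] <- cnt
    }
  }
  structure(do.call(rbind, out), class = c("density_summary", "data.frame"),
            draws = draws_out)
}

#' Posterior mean density surface
#'
#' Per habitat cell, the mean over retained draws of the number of population
#' members (`z = 1`) with their activity center in the cell, per sex and
#' pooled. The surface sums exactly to the corresponding posterior-mean
#' abundance over the same draws.
#'
#' @param fit an `scr_fit`.
#' @param per one of `"cell"`, `"km2"`, `"ha"`: units of the returned values.
#' @return Data frame with cell coordinates and columns `all`, `F`, `M`;
#'   attribute `habitat` carries the grid for plotting/export.
#' @export
densitySurface <- function(fit, per = c("cell", "km2", "ha")) {
  per <- match.arg(per)
  habitat <- fit$habitat
  C <- nCells(habitat)
  ac <- pool_ac(fit)
  ndr <- nrow(ac$s)
  acc <- function(mask) {
    sel <- ac$z == 1L & mask
    tabulate(ac$s[sel], nbins = C) / ndr
  }
  div <- switch(per, cell = 1, km2 = habitat$cell_area_km2,
                ha = habitat$cell_area_km2 * 100)
  out <- data.frame(x = habitat$centers[, 1], y = habitat$centers[, 2],
                    all = acc(TRUE) / div, F = acc(ac$sex == 0L) / div,
                    M = acc(ac$sex == 1L) / div, check.names = FALSE)
  attr(out, "habitat") <- habitat
  out
}

#' Export a density surface column as an ESRI ASCII grid
#'
#' @param surface output of [densitySurface()].
#' @param column which column to rasterize (`"all"`, `"F"`, `"M"`).
#' @param path output file path.
#' @export
writeDensitySurface <- function(surface, column = "all", path) {
  habitat <- attr(surface, "habitat")
  cs <- habitat$cell_size
  xs <- sort(unique(surface$x)); ys <- sort(unique(surface$y))
  m <- matrix(NA_real_, length(ys), length(xs))
  m[cbind(match(surface$y, ys), match(surface$x, xs))] <- surface[[column]]
  write_asc(scr_raster(m, xll = min(xs) - cs / 2, yll = min(ys) - cs / 2,
                       res = cs), path)
}

#' Posterior sex ratio
#'
#' Summaries of the male:female abundance ratio and of the latent-sex
#' probability `psi_sex`. The headline ratio is the ratio of posterior mean
#' abundances; per-draw ratios are also summarized (draws with zero females
#' are recorded as missing).
#'
#' @param fit an `scr_fit`.
#' @param within_study count only activity centers inside the study polygon
#'   (default `TRUE`, matching [abundanceDensity()]).
#' @return List with `ratio_of_means`, `ratio_mean`, `ratio_lo`, `ratio_hi`,
#'   `n_ratio_missing`, and `psi_sex` (mean and 95% CI).
#' @export
sexRatio <- function(fit, within_study = TRUE) {
  habitat <- fit$habitat
  scope <- if (within_study) habitat$in_study else rep(TRUE, nCells(habitat))
  ac <- pool_ac(fit)
  ndr <- nrow(ac$s)
  member <- matrix(scope[ac$s], nrow = ndr) & ac$z == 1L
  nM <- rowSums(member & ac$sex == 1L)
  nF <- rowSums(member & ac$sex == 0L)
  ratio <- ifelse(nF > 0, nM / nF, NA_real_)
  P <- do.call(rbind, lapply(fit$chains, `[[`, "params"))
  qs <- quantile(ratio, c(0.025, 0.975), na.rm = TRUE)
  pq <- quantile(P[, "psi_sex"], c(0.025, 0.975))
  list(ratio_of_means = mean(nM) / mean(nF),
       ratio_mean = mean(ratio, na.rm = TRUE),
       ratio_lo = unname(qs[1]), ratio_hi = unname(qs[2]),
       n_ratio_missing = sum(is.na(ratio)),
       psi_sex = c(mean = mean(P[, "psi_sex"]),
                   lo = unname(pq[1]), hi = unname(pq[2])))
}

#' Pooled posterior parameter summary
#'
#' Posterior means and central 95% credible intervals of all stored scalar
#' parameters, pooled over chains.
#'
#' @param fit an `scr_fit`.
#' @return Data frame with columns `parameter`, `mean`, `lo`, `hi`.
#' @export
posteriorSummary <- function(fit) {
  P <- do.call(rbind, lapply(fit$chains, `[[`, "params"))
  data.frame(parameter = colnames(P), mean = colMeans(P),
             lo = apply(P, 2L, quantile, 0.025),
             hi = apply(P, 2L, quantile, 0.975), row.names = NULL)
}
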