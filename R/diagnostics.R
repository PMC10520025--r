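#' Gelman-Rubin convergence diagnostic
#'
#' Split, rank-normalized R-hat per continuous parameter: each chain is split
#' in half, draws are rank-normalized across all half-chains, and the usual
#' between/within variance ratio is computed. Point-process coefficients are
#' governed by inclusion indicators, so their R-hat is computed on draws with
#' `gamma = 1` only and flagged (`visual_check = TRUE`): visual inspection is
#' advised for them. Zero-variance parameters yield `NA` with a warning.
#'
#' @param fit an `scr_fit`, or a list/matrix interface: a numeric matrix of
#'   draws (rows) by chains (columns) for a single parameter.
#' @param params parameter names to diagnose; default all continuous ones.
#' @return Data frame with columns `parameter`, `rhat`, `visual_check`.
#' @export
gelmanRubin <- function(fit, params = NULL) {
  if (is.matrix(fit)) {
    return(data.frame(parameter = "x", rhat = split_rhat(fit),
                      visual_check = FALSE))
  }
  stopifnot(inherits(fit, "scr_fit"))
  if (length(fit$chains) < 2L) stopf("need at least 2 chains")
  if (nrow(fit$chains[[1]]$params) < 10L) stopf("need at least 10 retained draws")
  cont <- c("p0_F", "p0_M", "sigma_F", "sigma_M", "beta_search", "psi",
            "psi_sex", "N")
  beta_cols <- grep("^beta_(TRI|SSI|CANOPY|BARREN)_", colnames(fit$chains[[1]]$params),
                    value = TRUE)
  params <- params %||% c(cont, beta_cols)
  out <- lapply(params, function(pn) {
    flag <- pn %in% beta_cols
    if (flag) {
      gcol <- sub("^beta_", "gamma_", pn)
      draws <- lapply(fit$chains, function(ch) ch$params[ch$gamma[, gcol] == 1L, pn])
      nmin <- min(lengths(draws))
      if (nmin < 10L) {
        warning(sprintf("parameter %s: too few included draws for R-hat", pn))
        return(data.frame(parameter = pn, rhat = NA_real_, visual_check = TRUE))
      }
      m <- vapply(draws, function(d) d[seq_len(nmin)], numeric(nmin))
    } else {
      m <- vapply(fit$chains, function(ch) ch$params[, pn],
                  numeric(nrow(fit$chains[[1]]$params)))
    }
    data.frame(parameter = pn, rhat = split_rhat(m), visual_check = flag)
  })
  do.call(rbind, out)
}

# split, rank-normalized R-hat of a draws x chains matrix
split_rhat <- function(m) {
  n <- nrow(m)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(m)), function(ch)
    cbind(m[seq_len(half), ch], m[(n - half + 1):n, ch])))
  if (var(as.vector(halves)) == 0) {
    warning("zero total variance; R-hat undefined")
    return(NA_real_)
  }
  r <- matrix(rank(halves, ties.method = "average"), nrow(halves))
  zmat <- qnorm((r - 3 / 8) / (length(halves) + 1 / 4))
  W <- mean(apply(zmat, 2L, var))
  if (W == 0) return(Inf)  # chains stuck at distinct constants: diverged
  B <- half * var(colMeans(zmat))
  sqrt(((half - 1) / half * W + B / half) / W)
}
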