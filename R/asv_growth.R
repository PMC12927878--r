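#' Select ASVs for phylotype-level growth analysis
#'
#' Retains ASVs passing all three filters: a minimum ratio between maximum
#' and minimum relative abundance (default 100), a minimal maximum relative
#' abundance (default 1%) in at least one sample, and a minimal prevalence
#' (default 20 samples). A zero minimum counts as passing the ratio filter
#' (ratio -> infinity; these are exactly the phylotypes blooming from zero);
#' alternatively a pseudocount of `1/pseudo_depth` can stand in for zero
#' minima.
#'
#' @param rel Relative-abundance matrix (ASVs x samples; columns sum to 1).
#' @param min_ratio Max/min relative-abundance ratio threshold (default 100).
#' @param min_max_abund Minimal maximum relative abundance (default 0.01).
#' @param min_prevalence Minimal number of samples with presence (default 20).
#' @param zero_handling `"pass"` (zero minima satisfy the ratio criterion) or
#'   `"pseudocount"` (substitute `1/pseudo_depth`).
#' @param pseudo_depth Depth used for the pseudocount option.
#' @return Character vector of retained ASV ids (may be empty, with a
#'   warning).
#' @export
select_asvs <- function(rel, min_ratio = 100, min_max_abund = 0.01,
                        min_prevalence = 20L,
                        zero_handling = c("pass", "pseudocount"),
                        pseudo_depth = 3155) {
  zero_handling <- match.arg(zero_handling)
  rel <- as.matrix(rel)
  if (any(abs(colSums(rel) - 1) > 1e-6))
    stop("`rel` columns must sum to 1", call. = FALSE)
  maxab <- apply(rel, 1L, max)
  minab <- apply(rel, 1L, min)
  if (zero_handling == "pseudocount") minab[minab == 0] <- 1 / pseudo_depth
  ratio <- ifelse(minab == 0, Inf, maxab / minab)
  prevalence <- rowSums(rel > 0)
  keep <- ratio >= min_ratio & maxab >= min_max_abund &
    prevalence >= min_prevalence
  ids <- rownames(rel)[keep]
  if (length(ids) == 0L) warning("no ASV passes all selection filters")
  ids
}

#' Absolute phylotype abundance from relative abundance and TCC
#'
#' @param rel Relative abundance in `[0, 1]`.
#' @param tcc Total cell count, cells/l (> 0).
#' @return Absolute abundance, cells/l.
#' @export
absolute_abundance <- function(rel, tcc) {
  if (any(!is.finite(rel)) || any(rel < 0) || any(rel > 1))
    stop("`rel` must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(tcc)) || any(tcc <= 0))
    stop("`tcc` must be positive", call. = FALSE)
  rel * tcc
}

#' Penalized-spline smoother of abundance over travel time
#'
#' Fits a penalized cubic regression spline of abundance on cumulative
#' travel time with [mgcv::gam()], the smoothing parameter chosen by
#' generalized cross-validation (default) or fixed at a given effective
#' degrees of freedom. Replicate observations at identical travel times are
#' averaged before fitting. Fitted values and a pointwise +/- 2 SE envelope
#' (an approximate Bayesian credible band from the smoother's posterior
#' covariance) are evaluated on a regular grid.
#'
#' @param tt Travel times, hours.
#' @param abundance Abundance, cells/l (same length).
#' @param basis_dim Spline basis dimension (default 10).
#' @param smooth_selection `"gcv"` or `"fixed_df"`.
#' @param fixed_df Effective df when `smooth_selection = "fixed_df"`.
#' @param sp Optional fixed smoothing parameter, overriding GCV (useful for
#'   probing the interpolation and straight-line limits of the penalty).
#' @param grid_n Number of grid points (default 200).
#' @param asv_id Optional label carried into the result.
#' @return A `smooth_fit`: list with `asv_id`, `grid`, `fitted`, `se`,
#'   `band_low`, `band_high`, `effective_df`, `gam` (the fitted model) and
#'   `data` (the averaged input).
#' @export
fit_smoother <- function(tt, abundance, basis_dim = 10L,
                         smooth_selection = c("gcv", "fixed_df"),
                         fixed_df = 5, grid_n = 200L, asv_id = NA_character_,
                         sp = NULL) {
  smooth_selection <- match.arg(smooth_selection)
  ok <- is.finite(tt) & is.finite(abundance)
  tt <- tt[ok]; abundance <- abundance[ok]
  if (anyDuplicated(tt)) {
    agg <- tapply(abundance, tt, mean)
    tt <- as.numeric(names(agg)); abundance <- as.numeric(agg)
  }
  o <- order(tt)
  tt <- tt[o]; abundance <- abundance[o]
  if (length(tt) < 8L)
    stop("need at least 8 observations at distinct travel times", call. = FALSE)
  dat <- data.frame(tt = tt, y = abundance)
  if (smooth_selection == "gcv") {
    g <- mgcv::gam(y ~ s(tt, k = basis_dim, bs = "cr"), data = dat,
                   method = "GCV.Cp", sp = sp)
  } else {
    k_fx <- max(3L, as.integer(ceiling(fixed_df)) + 1L)
    g <- mgcv::gam(y ~ s(tt, k = k_fx, fx = TRUE, bs = "cr"), data = dat)
  }
  grid <- seq(min(tt), max(tt), length.out = grid_n)
  pr <- mgcv::predict.gam(g, newdata = data.frame(tt = grid), se.fit = TRUE)
  structure(list(asv_id = asv_id, grid = grid,
                 fitted = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
                 band_low = as.numeric(pr$fit - 2 * pr$se.fit),
                 band_high = as.numeric(pr$fit + 2 * pr$se.fit),
                 effective_df = sum(g$edf), gam = g, data = dat),
            class = "smooth_fit")
}

#' Derivative of a fitted smoother with uncertainty envelope
#'
#' Differentiates the fitted spline on its grid via finite differences of
#' the prediction (basis) matrix — equivalent to the analytic basis
#' derivative at the step used — and propagates the smoother's Bayesian
#' covariance into a pointwise +/- 2 SE envelope for the derivative: the
#' net rate of change of the phylotype's abundance per travel-hour.
#'
#' @param fit A `smooth_fit`.
#' @param eps Finite-difference half-step (default 1e-5 of the grid range).
#' @return List with `asv_id`, `grid`, `derivative` (cells/l per hour),
#'   `se`, `band_low`, `band_high`.
#' @export
derivative_series <- function(fit, eps = NULL) {
  stopifnot(inherits(fit, "smooth_fit"))
  rng <- range(fit$grid)
  if (is.null(eps)) eps <- diff(rng) * 1e-5
  g <- fit$gam
  X1 <- mgcv::predict.gam(g, newdata = data.frame(tt = fit$grid - eps),
                          type = "lpmatrix")
  X2 <- mgcv::predict.gam(g, newdata = data.frame(tt = fit$grid + eps),
                          type = "lpmatrix")
  Xd <- (X2 - X1) / (2 * eps)
  deriv <- as.numeric(Xd %*% stats::coef(g))
  se <- sqrt(pmax(0, rowSums((Xd %*% g$Vp) * Xd)))
  list(asv_id = fit$asv_id, grid = fit$grid, derivative = deriv, se = se,
       band_low = deriv - 2 * se, band_high = deriv + 2 * se)
}

#' Extreme rates of change of a fitted phylotype trajectory
#'
#' Signed extrema of the derivative series over the grid: the maximum
#' increase and the maximum decrease of abundance per travel-hour. For a
#' monotone trajectory one of the two does not change sign; the
#' corresponding extremum is still the signed extreme value, flagged.
#'
#' @param deriv Output of [derivative_series()].
#' @return List with `max_increase`, `max_decrease`, their grid positions
#'   `tt_increase`, `tt_decrease`, and flags `no_increase`, `no_decrease`
#'   (TRUE when the derivative never takes the corresponding sign).
#' @export
max_change <- function(deriv) {
  d <- deriv$derivative
  if (length(d) == 0L) stop("empty derivative series", call. = FALSE)
  i_max <- which.max(d); i_min <- which.min(d)
  list(max_increase = d[i_max], max_decrease = d[i_min],
       tt_increase = deriv$grid[i_max], tt_decrease = deriv$grid[i_min],
       no_increase = d[i_max] <= 0, no_decrease = d[i_min] >= 0)
}

#' Per-capita rate of change between two sites
#'
#' Natural-log per-capita rate from the abundances at two consecutive sites
#' and the travel time between them, scaled to per day:
#' `24 * ln(n_down / n_up) / tt`. Division by `ln 2` converts to doublings
#' per day for comparison with bulk division rates.
#'
#' @param n_up Upstream abundance, cells/l (> 0).
#' @param n_down Downstream abundance, cells/l (>= 0).
#' @param tt Segment travel time, hours (> 0).
#' @param bulk_cd_daily Optional bulk daily division rate for the ratio
#'   report.
#' @return List with `rate_daily` (1/d; `-Inf` with `extinct = TRUE` when
#'   `n_down` is zero), `doublings_daily`, and `ratio_to_bulk` when a bulk
#'   rate is supplied.
#' @export
sitewise_rate <- function(n_up, n_down, tt, bulk_cd_daily = NULL) {
  if (!is.finite(n_up) || n_up <= 0)
    stop("undefined rate: `n_up` must be positive", call. = FALSE)
  if (!is.finite(tt) || tt <= 0) stop("`tt` must be positive", call. = FALSE)
  if (n_down < 0) stop("`n_down` must be non-negative", call. = FALSE)
  extinct <- n_down == 0
  rate <- if (extinct) -Inf else 24 * log(n_down / n_up) / tt
  out <- list(rate_daily = rate, doublings_daily = rate / log(2),
              extinct = extinct)
  if (!is.null(bulk_cd_daily)) out$ratio_to_bulk <- rate / bulk_cd_daily
  out
}
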