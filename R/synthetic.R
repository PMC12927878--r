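#' Ground-truth parameters for a synthetic river transect
#'
#' Bundles every planted parameter of the synthetic generator. Two presets
#' mirror the magnitudes of the two whole-river surveys the package is
#' built around: `"jds3like"` (54 sites over ~2582 km, velocities
#' 0.9--5.4 km/h, ~50-day total travel time, strongly increasing cell
#' counts) and `"jds2like"` (75 sites, velocities 0.6--11.2 km/h, ~34-day
#' travel time). Any field can be overridden by name.
#'
#' Community structure: a headwater community of `richness_start` ASVs with
#' lognormal abundances; along each segment every non-persistent ASV is
#' replaced by a fresh one with probability `replacement_rate` while a
#' persistent core is never replaced; realized richness follows
#' `richness_start + richness_slope * tt_cum`; `n_bloomers` phylotypes grow
#' along logistic trajectories with per-capita rate
#' `bloomer_rate_multiplier` times the bulk division rate. The persistent
#' core is sized so that `persistent_fraction` equals the expected fraction
#' of the three-site headwater pool that persists downstream (the quantity
#' the persistence analysis measures).
#'
#' @param preset `"jds3like"` or `"jds2like"`.
#' @param ... Named overrides of any parameter.
#' @param seed Master seed; all generator randomness derives from it.
#' @return A `synthetic_truth` (named list).
#' @export
synthetic_truth <- function(preset = c("jds3like", "jds2like"), ..., seed = 1L) {
  preset <- match.arg(preset)
  base <- switch(preset,
    jds3like = list(
      n_sites = 54L, total_length = 2582, rkm_start = 2600,
      velocity_min = 0.9, velocity_max = 5.4, tt_target_days = 49.7,
      tcc_intercept = 6e9, tcc_slope = 9.5e6,
      bsp_intercept = 1.7, bsp_slope = -7.9e-4,
      volume_start = 0.11, volume_end = 0.030,
      richness_start = 400L, richness_slope = -0.13, richness_noise_sd = 8,
      replacement_rate = 0.30, persistent_fraction = 0.10,
      n_bloomers = 5L, bloomer_rate_multiplier = 100,
      noise_sd = 0.10, abund_sdlog = 1.2, depth = 10000L),
    jds2like = list(
      n_sites = 75L, total_length = 2582, rkm_start = 2600,
      velocity_min = 0.6, velocity_max = 11.2, tt_target_days = 33.7,
      tcc_intercept = 1.2e9, tcc_slope = 0.93e6,
      bsp_intercept = 0.55, bsp_slope = -4.5e-4,
      volume_start = 0.16, volume_end = 0.05,
      richness_start = 450L, richness_slope = -0.145, richness_noise_sd = 8,
      replacement_rate = 0.30, persistent_fraction = 0.10,
      n_bloomers = 5L, bloomer_rate_multiplier = 100,
      noise_sd = 0.10, abund_sdlog = 1.2, depth = 10000L))
  overrides <- list(...)
  unknown <- setdiff(names(overrides), c(names(base), "seed"))
  if (length(unknown))
    stop("unknown truth parameters: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base[names(overrides)] <- overrides
  base$seed <- as.integer(seed)
  base$preset <- preset
  tt_h <- base$tt_target_days * 24
  if (base$replacement_rate < 0 || base$replacement_rate > 1 ||
      base$persistent_fraction < 0 || base$persistent_fraction > 1)
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (base$richness_start <= abs(base$richness_slope) * tt_h)
    stop("infeasible parameters: richness declines below zero", call. = FALSE)
  if (base$tcc_intercept + base$tcc_slope * tt_h <= 0 ||
      base$tcc_intercept <= 0)
    stop("infeasible parameters: non-positive TCC implied", call. = FALSE)
  if (base$bsp_intercept + base$bsp_slope * tt_h <= 0 ||
      base$bsp_intercept <= 0)
    stop("infeasible parameters: non-positive BSP implied", call. = FALSE)
  structure(base, class = "synthetic_truth")
}

# bulk hourly division rate implied by the truth's trend lines at travel time tt
.bulk_cd_hourly <- function(truth, tt) {
  tcc <- truth$tcc_intercept + truth$tcc_slope * tt
  bsp <- truth$bsp_intercept + truth$bsp_slope * tt
  vol <- truth$volume_start +
    (truth$volume_end - truth$volume_start) * tt / (truth$tt_target_days * 24)
  (bsp * 1e9 / tcc) / (310 * vol)
}

# persistent count (core + bloomers, all present at every site) such that
# persistent / E[3-site pool] = persistent_fraction; returns the core size
.core_size <- function(truth) {
  p <- truth$persistent_fraction
  r <- truth$replacement_rate
  tt <- .expected_tt(truth)
  s_exp <- truth$richness_start + truth$richness_slope * tt
  s1 <- s_exp[1L]
  sbar <- mean(s_exp[2:3])
  persistent <- round_half_up(p * (s1 + 2 * r * sbar) / (1 + 2 * r * p))
  max(0L, persistent - truth$n_bloomers)
}

# expected tt_cum (hours) at the sites, from the deterministic velocity profile
.expected_tt <- function(truth) {
  generate_transect(truth, .skip_noise = TRUE)$tt_cum
}

#' Generate a synthetic river transect
#'
#' Builds `n_sites` equidistant sites spanning `total_length` km with a
#' deterministic, downstream-decelerating velocity profile bounded by
#' `velocity_min`/`velocity_max`; the profile's shape exponent is solved so
#' the whole-river travel time hits `tt_target_days` exactly. Cell counts
#' increase and bulk production decreases linearly in cumulative travel
#' time, cell volumes shrink downstream; each carries multiplicative
#' lognormal noise of standard deviation `noise_sd` (log scale), mean-
#' corrected so `noise_sd = 0` returns the exact trend lines. Fully
#' deterministic under the truth's seed.
#'
#' @param truth A `synthetic_truth`.
#' @param .skip_noise Internal: return noiseless trend lines.
#' @return A `transect` with `tcc`, `bsp`, `mean_cell_volume`,
#'   `temperature` site columns.
#' @export
generate_transect <- function(truth, .skip_noise = FALSE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- truth$n_sites
  rkm <- seq(truth$rkm_start, truth$rkm_start - truth$total_length,
             length.out = n)
  u <- seq(0.97, 0.03, length.out = n)
  target_h <- truth$tt_target_days * 24
  tt_for <- function(gamma) {
    v <- truth$velocity_min +
      (truth$velocity_max - truth$velocity_min) * u^gamma
    seg_v <- (v[-n] + v[-1L]) / 2
    sum(-diff(rkm) / seg_v)
  }
  lo <- 0.02; hi <- 50
  if (tt_for(lo) > target_h || tt_for(hi) < target_h)
    stop("infeasible parameters: travel-time target outside velocity bounds",
         call. = FALSE)
  gamma <- stats::uniroot(function(g) tt_for(g) - target_h, c(lo, hi),
                          tol = 1e-10)$root
  velocity <- truth$velocity_min +
    (truth$velocity_max - truth$velocity_min) * u^gamma

  sites <- data.frame(site_id = sprintf("st_%02d", seq_len(n)),
                      rkm = rkm, velocity = velocity,
                      stringsAsFactors = FALSE)
  tr0 <- build_transect(sites)
  tt <- tr0$tt_cum

  tcc_line <- truth$tcc_intercept + truth$tcc_slope * tt
  bsp_line <- truth$bsp_intercept + truth$bsp_slope * tt
  vol_line <- truth$volume_start +
    (truth$volume_end - truth$volume_start) * tt / max(tt)
  # centred lognormal-shaped noise at a constant absolute scale (set by the
  # mid-river level), so trend-recovery standard errors stay calibrated;
  # noise_sd = 0 returns the exact lines
  if (.skip_noise || truth$noise_sd == 0) {
    noise <- function(line, sd) line
  } else {
    noise <- function(line, sd) {
      eps <- exp(stats::rnorm(n, 0, sd) - sd^2 / 2) - 1
      pmax(line + mean(line) * eps, 0.05 * line)
    }
  }
  set.seed(derive_seed(truth$seed, "transect"))
  sites$tcc <- noise(tcc_line, truth$noise_sd)
  sites$bsp <- noise(bsp_line, truth$noise_sd)
  sites$mean_cell_volume <- noise(vol_line, truth$noise_sd / 2)
  sites$temperature <- 21 + stats::rnorm(n, 0, if (.skip_noise) 0 else 1)
  build_transect(sites)
}

#' Generate a synthetic ASV count table along a transect
#'
#' Implements the community process described in [synthetic_truth()]:
#' persistent core, per-segment Bernoulli replacement of non-core
#' phylotypes, a richness trajectory following the planted slope, and
#' logistic bloomers. At each site every member phylotype receives one
#' guaranteed read and the remaining depth is drawn multinomially from the
#' members' lognormal weights (plus the bloomers' logistic weights), so the
#' realized column sums equal `depth` exactly and the realized richness
#' matches the planted trajectory. Deterministic under the truth's seed.
#'
#' @param truth A `synthetic_truth`.
#' @param transect The matching `transect` from [generate_transect()].
#' @return An `asv_table` (samples `smp_01..`, one per site).
#' @export
generate_asv_table <- function(truth, transect) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(transect, "transect"))
  n <- truth$n_sites
  stopifnot(nrow(transect$sites) == n)
  tt <- transect$tt_cum
  set.seed(derive_seed(truth$seed, "asv"))

  core_n <- .core_size(truth)
  blo_n <- truth$n_bloomers
  s_target <- round_half_up(truth$richness_start + truth$richness_slope * tt +
                              stats::rnorm(n, 0, truth$richness_noise_sd))
  s_target <- pmax(s_target, core_n + blo_n + 5L)
  if (truth$depth <= max(s_target) * 2)
    stop("depth too small to realize the target richness", call. = FALSE)

  counter <- 0L
  new_ids <- function(k) {
    ids <- sprintf("ASV_%05d", counter + seq_len(k))
    counter <<- counter + k
    ids
  }
  new_weights <- function(k) stats::rlnorm(k, 0, truth$abund_sdlog)

  core_ids <- new_ids(core_n)
  core_w <- new_weights(core_n)

  # bloomers: permanent members (present at ~zero abundance upstream) whose
  # weights follow logistic trajectories with per-capita rate = multiplier x
  # the bulk hourly division rate implied by the truth's trend lines
  blo_ids <- if (blo_n > 0) new_ids(blo_n) else character(0)
  blo_t0 <- stats::runif(blo_n, 0.25, 0.75) * max(tt)
  blo_frac <- stats::runif(blo_n, 0.03, 0.15)
  blo_rate <- truth$bloomer_rate_multiplier * .bulk_cd_hourly(truth, blo_t0)

  nc_n <- s_target[1L] - core_n - blo_n
  nc_ids <- new_ids(nc_n)
  nc_w <- new_weights(nc_n)

  members <- vector("list", n)
  nc_weights <- vector("list", n)
  members[[1L]] <- c(core_ids, blo_ids, nc_ids)
  nc_weights[[1L]] <- nc_w
  for (s in 2:n) {
    replaced <- stats::runif(length(nc_ids)) < truth$replacement_rate
    k <- sum(replaced)
    if (k > 0) {
      nc_ids[replaced] <- new_ids(k)
      nc_w[replaced] <- new_weights(k)
    }
    want <- max(0L, s_target[s] - core_n - blo_n)
    if (length(nc_ids) > want) {
      keep <- order(nc_w, decreasing = TRUE)[seq_len(want)]
      nc_ids <- nc_ids[keep]; nc_w <- nc_w[keep]
    } else if (length(nc_ids) < want) {
      add <- want - length(nc_ids)
      nc_ids <- c(nc_ids, new_ids(add))
      nc_w <- c(nc_w, new_weights(add))
    }
    members[[s]] <- c(core_ids, blo_ids, nc_ids)
    nc_weights[[s]] <- nc_w
  }

  all_ids <- unique(unlist(members))
  counts <- matrix(0L, length(all_ids), n,
                   dimnames = list(all_ids, sprintf("smp_%02d", seq_len(n))))
  for (s in seq_len(n)) {
    mem <- members[[s]]
    w_base <- c(core_w, nc_weights[[s]])
    wb <- if (blo_n > 0) {
      (blo_frac / (1 - blo_frac)) * sum(w_base) /
        (1 + exp(-blo_rate * (tt[s] - blo_t0)))
    } else numeric(0)
    w <- c(core_w, wb, nc_weights[[s]])
    extra <- stats::rmultinom(1L, truth$depth - length(mem), prob = w)[, 1L]
    counts[mem, s] <- 1L + extra   # one guaranteed read per member
  }

  map <- data.frame(sample_id = colnames(counts),
                    site_id = transect$sites$site_id,
                    fraction = "bulk", stringsAsFactors = FALSE)
  tab <- asv_table(counts, map, fraction = "bulk")
  attr(tab, "core_ids") <- core_ids
  attr(tab, "bloomer_ids") <- blo_ids
  tab
}

#' Machine-readable ground-truth report
#'
#' Returns every planted parameter plus the derived expectations used for
#' recovery assertions: expected per-site richness, the persistent-core
#' size, the expected headwater-pool size and persistence fraction, and the
#' expected per-segment turnover under the replacement process
#' (`replacement_rate * (1 - core / S)` at the downstream site's expected
#' richness).
#'
#' @param truth A `synthetic_truth`.
#' @param path Optional path; when given, the report is written as JSON.
#' @return List with `parameters` and `expected`.
#' @export
truth_report <- function(truth, path = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  tt <- .expected_tt(truth)
  s_exp <- truth$richness_start + truth$richness_slope * tt
  core_n <- .core_size(truth)
  persistent_n <- core_n + truth$n_bloomers
  r <- truth$replacement_rate
  pool <- s_exp[1L] + 2 * r * (mean(s_exp[2:3]) - persistent_n)
  rep_out <- list(
    parameters = unclass(truth),
    expected = list(
      tt_cum_hours = tt,
      richness_per_site = s_exp,
      core_size = core_n,
      persistent_count = persistent_n,
      headwater_pool = pool,
      persistence_fraction = persistent_n / pool,
      segment_turnover = r * (1 - persistent_n / s_exp[-1L]),
      bulk_cd_daily_mid = 24 * .bulk_cd_hourly(truth, max(tt) / 2)
    )
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep_out, path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep_out))
  }
  rep_out
}
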