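#' Water travel time for a river segment
#'
#' Travel time is the duration a parcel of water needs to traverse a segment,
#' computed as distance over flow velocity. It is the central predictor for
#' downstream trends in cell counts, production and diversity.
#'
#' @param distance Segment length in km; must be positive.
#' @param velocity Flow velocity in km/h; must be positive.
#' @return Travel time in hours.
#' @examples
#' travel_time(10, 5)   # 2 h
#' @export
travel_time <- function(distance, velocity) {
  if (any(!is.finite(distance)) || any(distance <= 0))
    stop("`distance` must be positive and finite", call. = FALSE)
  if (any(!is.finite(velocity)) || any(velocity <= 0))
    stop("`velocity` must be positive and finite", call. = FALSE)
  distance / velocity
}

#' Build a downstream-ordered river transect
#'
#' Assembles sites into a transect object carrying per-segment travel times
#' and cumulative travel time (`tt_cum`, hours; 0 at the headwater site).
#' Sites must be ordered downstream, i.e. by strictly decreasing river
#' kilometre (`rkm`, measured from the river mouth).
#'
#' @param sites data.frame with at least `site_id`, `rkm` and `velocity`
#'   (km/h) columns, ordered headwater first (strictly decreasing `rkm`).
#'   Additional covariate columns (e.g. `tcc`, `bsp`, `mean_cell_volume`,
#'   `temperature`) are kept as-is.
#' @param distances Optional numeric vector of inter-site distances (km), one
#'   per adjacent pair. Defaults to successive `rkm` differences.
#' @param velocity_rule Convention for a segment's velocity: `"mean"`
#'   (arithmetic mean of the two endpoint velocities, the default — least
#'   biased for monotone velocity changes) or `"upstream"` (the upstream
#'   site's velocity).
#' @return An object of class `transect`: a list with `sites` (the input
#'   data.frame plus a `tt_cum` column), `segments` (one row per adjacent
#'   pair: upstream/downstream ids, `distance`, `mean_velocity`, `tt`) and
#'   `tt_cum`.
#' @export
build_transect <- function(sites, distances = NULL,
                           velocity_rule = c("mean", "upstream")) {
  velocity_rule <- match.arg(velocity_rule)
  stopifnot(is.data.frame(sites))
  for (col in c("site_id", "rkm", "velocity")) {
    if (!col %in% names(sites))
      stop("`sites` must contain a `", col, "` column", call. = FALSE)
  }
  n <- nrow(sites)
  if (n < 2L) stop("a transect needs at least two sites", call. = FALSE)
  if (any(!is.finite(sites$rkm)) || any(sites$rkm < 0))
    stop("`rkm` must be non-negative and finite", call. = FALSE)
  if (any(diff(sites$rkm) >= 0))
    stop("sites must be ordered downstream: `rkm` strictly decreasing",
         call. = FALSE)
  if (is.null(distances)) distances <- -diff(sites$rkm)
  if (length(distances) != n - 1L)
    stop("need one distance per adjacent site pair", call. = FALSE)
  if (any(!is.finite(distances)) || any(distances <= 0))
    stop("distances must be positive", call. = FALSE)
  if (any(!is.finite(sites$velocity)) || any(sites$velocity <= 0))
    stop("site velocities must be positive for travel-time computation",
         call. = FALSE)

  v_up <- sites$velocity[-n]
  v_dn <- sites$velocity[-1L]
  mean_velocity <- switch(velocity_rule,
                          mean = (v_up + v_dn) / 2,
                          upstream = v_up)
  tt <- travel_time(distances, mean_velocity)
  segments <- data.frame(
    upstream_site_id = sites$site_id[-n],
    downstream_site_id = sites$site_id[-1L],
    distance = distances,
    mean_velocity = mean_velocity,
    tt = tt,
    stringsAsFactors = FALSE
  )
  tt_cum <- c(0, cumsum(tt))
  sites$tt_cum <- tt_cum
  structure(list(sites = sites, segments = segments, tt_cum = tt_cum,
                 velocity_rule = velocity_rule),
            class = "transect")
}

#' @export
print.transect <- function(x, ...) {
  cat(sprintf("River transect: %d sites, %d segments\n",
              nrow(x$sites), nrow(x$segments)))
  cat(sprintf("  rkm %.1f -> %.1f, total travel time %.1f h (%.1f days)\n",
              x$sites$rkm[1], x$sites$rkm[nrow(x$sites)],
              max(x$tt_cum), max(x$tt_cum) / 24))
  invisible(x)
}

#' Discharge ratio relative to the series minimum
#'
#' Normalizes a discharge measurement to the minimum discharge observed at
#' the same location, yielding a dimensionless ratio >= 1 used as the
#' predictor in the discharge-richness model.
#'
#' @param q Discharge, m^3/s.
#' @param q_min Minimum discharge of the series at this location, m^3/s.
#' @return `q / q_min`.
#' @export
discharge_ratio <- function(q, q_min) {
  if (any(!is.finite(q_min)) || any(q_min <= 0))
    stop("`q_min` must be positive", call. = FALSE)
  if (any(q < q_min))
    stop("`q` below `q_min`: the minimum must be the series minimum",
         call. = FALSE)
  q / q_min
}

#' Read / write a site-metadata CSV
#'
#' The transect CSV has one row per site, downstream-ordered, with columns
#' `site_id, rkm, velocity_kmh, distance_km, discharge_m3s,
#' tcc_cells_per_l, bsp_ugc_per_l_h, mean_cell_volume_um3` plus optional
#' covariates; UTF-8, "." decimal separator. `distance_km` is the distance
#' to the next downstream site (NA on the last row).
#'
#' @param path File path.
#' @return `read_transect_csv()` returns a `transect`; `write_transect_csv()`
#'   invisibly returns `path`.
#' @export
read_transect_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sites <- data.frame(site_id = as.character(df$site_id),
                      rkm = df$rkm,
                      velocity = df$velocity_kmh,
                      stringsAsFactors = FALSE)
  rename <- c(discharge_m3s = "discharge", tcc_cells_per_l = "tcc",
              bsp_ugc_per_l_h = "bsp", mean_cell_volume_um3 = "mean_cell_volume")
  for (nm in names(rename))
    if (nm %in% names(df)) sites[[rename[[nm]]]] <- df[[nm]]
  extra <- setdiff(names(df), c("site_id", "rkm", "velocity_kmh",
                                "distance_km", names(rename)))
  for (nm in extra) sites[[nm]] <- df[[nm]]
  distances <- NULL
  if ("distance_km" %in% names(df)) {
    d <- df$distance_km[-nrow(df)]
    if (all(is.finite(d))) distances <- d
  }
  build_transect(sites, distances = distances)
}

#' @rdname read_transect_csv
#' @param transect A `transect` object.
#' @export
write_transect_csv <- function(transect, path) {
  stopifnot(inherits(transect, "transect"))
  s <- transect$sites
  out <- data.frame(site_id = s$site_id, rkm = s$rkm,
                    velocity_kmh = s$velocity,
                    distance_km = c(transect$segments$distance, NA),
                    stringsAsFactors = FALSE)
  back <- c(discharge = "discharge_m3s", tcc = "tcc_cells_per_l",
            bsp = "bsp_ugc_per_l_h", mean_cell_volume = "mean_cell_volume_um3")
  for (nm in names(back)) if (nm %in% names(s)) out[[back[[nm]]]] <- s[[nm]]
  extra <- setdiff(names(s), c("site_id", "rkm", "velocity", "tt_cum",
                               names(back)))
  for (nm in extra) out[[nm]] <- s[[nm]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
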