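#' ASV count table with a sample-to-site map
#'
#' Light container for an integer ASV-by-sample count matrix plus the map
#' from sample ids to transect sites. Counts must be non-negative integers;
#' retained samples must have positive totals.
#'
#' @param counts Integer matrix, ASVs x samples, with dimnames.
#' @param sample_map data.frame with `sample_id` and `site_id` columns (and
#'   optionally `fraction`).
#' @param fraction Fraction label for the whole table: "bulk", "FL" or "PA".
#' @return An `asv_table` (list with `counts`, `sample_map`, `fraction`).
#' @export
asv_table <- function(counts, sample_map, fraction = "bulk") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` needs ASV row names and sample column names", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be non-negative integers", call. = FALSE)
  stopifnot(is.data.frame(sample_map),
            all(c("sample_id", "site_id") %in% names(sample_map)))
  missing <- setdiff(colnames(counts), sample_map$sample_id)
  if (length(missing))
    stop("samples without a site mapping: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(counts = counts, sample_map = sample_map,
                 fraction = fraction),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV table (%s): %d ASVs x %d samples, depth %s\n",
              x$fraction, nrow(x$counts), ncol(x$counts),
              paste(range(colSums(x$counts)), collapse = "-")))
  invisible(x)
}

.get_counts <- function(x) if (inherits(x, "asv_table")) x$counts else as.matrix(x)

#' Discard shallow sequencing libraries
#'
#' Removes samples whose total read count falls below `min_reads`;
#' optionally prunes ASVs left with all-zero rows.
#'
#' @param table An `asv_table` or count matrix.
#' @param min_reads Minimum library size to retain a sample (> 0).
#' @param prune_empty Drop all-zero ASV rows after filtering (default TRUE).
#' @return Same class as the input, filtered.
#' @export
drop_shallow <- function(table, min_reads, prune_empty = TRUE) {
  if (!is.finite(min_reads) || min_reads <= 0)
    stop("`min_reads` must be positive", call. = FALSE)
  counts <- .get_counts(table)
  keep <- colSums(counts) >= min_reads
  if (!any(keep)) stop("all samples fall below `min_reads`", call. = FALSE)
  counts <- counts[, keep, drop = FALSE]
  if (prune_empty) counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (inherits(table, "asv_table")) {
    table$counts <- counts
    table$sample_map <- table$sample_map[
      table$sample_map$sample_id %in% colnames(counts), , drop = FALSE]
    table
  } else counts
}

#' Round half away from zero
#'
#' `round()` in R rounds half to even; averaged rarefied counts are instead
#' rounded half away from zero, which matters at the presence/absence margin.
#' @param x Numeric.
#' @return Rounded values.
#' @export
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Expands one master seed into independent substreams keyed by stable
#' labels, so that adding a sample or reordering stages does not perturb the
#' draws of the others. The result is a positive integer below 2^31.
#'
#' @param seed Master seed (integer).
#' @param label Character label of the substream.
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(paste0(label, ":", seed))
  h <- 104729
  for (k in codes) h <- (h * 131 + k) %% 2147483629
  as.integer(h + 1L)
}

#' Resample one library to a fixed depth with replacement
#'
#' One multinomial draw of `depth` reads with probabilities proportional to
#' the observed counts; the column sum of the result is exactly `depth`.
#'
#' @param x Integer count vector for one sample (positive total).
#' @param depth Target depth (> 0).
#' @return Integer vector of resampled counts.
#' @export
rarefy_once <- function(x, depth) {
  if (!is.finite(depth) || depth <= 0) stop("`depth` must be positive", call. = FALSE)
  tot <- sum(x)
  if (tot <= 0) stop("sample has no reads", call. = FALSE)
  as.integer(stats::rmultinom(1L, size = depth, prob = x / tot))
}

#' Rarefy an ASV table by repeated resampling with replacement
#'
#' Each retained sample is resampled with replacement to exactly `depth`
#' reads, `reps` times; the returned counts are the per-cell mean across
#' repetitions, rounded half away from zero (rounding can be disabled to
#' inspect the raw means). Per-sample random substreams are derived from the
#' master seed by sample id, so adding a sample leaves the others' draws
#' unchanged.
#'
#' Samples whose totals fall below `depth` should be removed beforehand with
#' [drop_shallow()]; they are resampled like any other sample otherwise
#' (resampling is with replacement, so shallower libraries remain valid
#' inputs, just noisier).
#'
#' @param table An `asv_table` or count matrix.
#' @param depth Target depth per sample (> 0).
#' @param reps Number of repetitions (default 50).
#' @param seed Master seed.
#' @param round Round the averaged counts half away from zero (default TRUE).
#' @return Same class as the input with rarefied counts.
#' @export
rarefy <- function(table, depth, reps = 50L, seed = 1L, round = TRUE) {
  if (!is.finite(depth) || depth <= 0)
    stop("`depth` must be positive", call. = FALSE)
  counts <- .get_counts(table)
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (j in seq_len(ncol(counts))) {
    set.seed(derive_seed(seed, paste0("rarefy/", colnames(counts)[j])))
    acc <- numeric(nrow(counts))
    p <- counts[, j] / sum(counts[, j])
    draws <- stats::rmultinom(reps, size = depth, prob = p)
    acc <- rowMeans(draws)
    out[, j] <- if (round) round_half_up(acc) else acc
  }
  if (inherits(table, "asv_table")) { table$counts <- out; table } else out
}

#' Observed ASV richness per sample
#'
#' Alpha diversity as the count of ASVs with nonzero counts.
#'
#' @param x An `asv_table`, count matrix, or single count vector.
#' @return Named integer vector (per sample), or a single count for a vector.
#' @export
observed_asvs <- function(x) {
  if (is.null(dim(x)) && !inherits(x, "asv_table")) return(sum(x > 0))
  counts <- .get_counts(x)
  colSums(counts > 0)
}

#' Relative abundances per sample
#'
#' Divides each column by its total; zero-total columns are an error (remove
#' them first with [drop_shallow()]).
#' @param x An `asv_table` or count matrix.
#' @return Matrix of proportions (columns sum to 1).
#' @export
relative_abundance <- function(x) {
  counts <- .get_counts(x)
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("zero-total sample; drop it first", call. = FALSE)
  sweep(counts, 2, tot, "/")
}

#' Bray--Curtis dissimilarity of two normalized abundance vectors
#'
#' `1 - 2 * sum(pmin(x, y)) / sum(x + y)` for vectors each summing to 1
#' (checked to 1e-9). Symmetric, bounded in `[0, 1]`.
#'
#' @param x,y Non-negative vectors, each summing to 1.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (any(x < 0) || any(y < 0) ||
      abs(sum(x) - 1) > 1e-9 || abs(sum(y) - 1) > 1e-9)
    stop("inputs must be normalized abundances summing to 1", call. = FALSE)
  1 - 2 * sum(pmin(x, y)) / sum(x + y)
}

#' Partition pairwise beta diversity into turnover and nestedness
#'
#' From presence/absence vectors with `a` shared and `b`, `c` unique
#' species: Simpson turnover `min(b,c) / (a + min(b,c))`, Sorensen
#' dissimilarity `(b + c) / (2a + b + c)`, and the nestedness-resultant
#' component as their difference. Turnover captures species replacement;
#' nestedness captures richness-difference-driven loss.
#'
#' @param x,y Logical/binary presence vectors of equal length; each
#'   community must contain at least one species.
#' @return List with `beta_sim`, `beta_sor`, `beta_nes`, and the incidence
#'   counts `a`, `b`, `c`.
#' @export
beta_partition_pair <- function(x, y) {
  x <- as.logical(x); y <- as.logical(y)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (!any(x) || !any(y)) stop("empty community", call. = FALSE)
  a <- sum(x & y)
  b <- sum(x & !y)
  c <- sum(!x & y)
  denom_sim <- a + min(b, c)
  beta_sim <- if (denom_sim == 0) 0 else min(b, c) / denom_sim
  beta_sor <- if (2 * a + b + c == 0) 0 else (b + c) / (2 * a + b + c)
  list(beta_sim = beta_sim, beta_sor = beta_sor,
       beta_nes = beta_sor - beta_sim, a = a, b = b, c = c)
}

# resolve the one sample per transect site, in transect order
.site_samples <- function(table, transect) {
  stopifnot(inherits(table, "asv_table"), inherits(transect, "transect"))
  map <- table$sample_map
  sites <- transect$sites$site_id
  idx <- vapply(sites, function(s) {
    hits <- map$sample_id[map$site_id == s]
    hits <- hits[hits %in% colnames(table$counts)]
    if (length(hits) != 1L)
      stop("site ", s, " has ", length(hits),
           " samples; need exactly one", call. = FALSE)
    hits
  }, character(1))
  unname(idx)
}

#' Beta diversity between consecutive transect sites
#'
#' Computes, for every adjacent downstream pair of sites, either the
#' turnover/nestedness partition on presence/absence (`metric =
#' "partition"`) or Bray--Curtis dissimilarity on relative abundances
#' (`metric = "bray_curtis"`), each record carrying the pair's midpoint
#' cumulative travel time for regression against the travel-time axis.
#'
#' @param table An `asv_table` with one sample per transect site.
#' @param transect A `transect`.
#' @param metric `"partition"` or `"bray_curtis"`.
#' @return data.frame, one row per adjacent pair, ordered by `tt_mid`.
#' @export
consecutive_series <- function(table, transect,
                               metric = c("partition", "bray_curtis")) {
  metric <- match.arg(metric)
  samples <- .site_samples(table, transect)
  counts <- table$counts[, samples, drop = FALSE]
  n <- length(samples)
  tt <- transect$tt_cum
  out <- vector("list", n - 1L)
  rel <- if (metric == "bray_curtis") relative_abundance(counts) else NULL
  for (i in seq_len(n - 1L)) {
    rec <- data.frame(sample_i = samples[i], sample_j = samples[i + 1L],
                      tt_mid = (tt[i] + tt[i + 1L]) / 2,
                      stringsAsFactors = FALSE)
    if (metric == "partition") {
      p <- beta_partition_pair(counts[, i] > 0, counts[, i + 1L] > 0)
      rec$beta_sim <- p$beta_sim; rec$beta_sor <- p$beta_sor
      rec$beta_nes <- p$beta_nes
    } else {
      rec$bray_curtis <- bray_curtis(rel[, i], rel[, i + 1L])
    }
    out[[i]] <- rec
  }
  do.call(rbind, out)
}

#' Whole-river turnover and its contribution to beta diversity
#'
#' Either the endpoint comparison (first vs last site, the default: the
#' parsimonious reading of a single turnover value per dataset) or the
#' Baselga multiple-site Simpson across all sites. The contribution is
#' turnover as a percentage of the total Sorensen dissimilarity.
#'
#' @param table An `asv_table` with one sample per transect site.
#' @param transect A `transect`.
#' @param method `"endpoints"` or `"multisite"`.
#' @return List with `turnover`, `sorensen`, `nestedness`,
#'   `percent_contribution`, `method` and a `degenerate` flag (TRUE when the
#'   total dissimilarity is zero and the contribution is reported as 0).
#' @export
whole_river_turnover <- function(table, transect,
                                 method = c("endpoints", "multisite")) {
  method <- match.arg(method)
  samples <- .site_samples(table, transect)
  counts <- table$counts[, samples, drop = FALSE] > 0
  if (method == "endpoints") {
    p <- beta_partition_pair(counts[, 1L], counts[, ncol(counts)])
    sim <- p$beta_sim; sor <- p$beta_sor
  } else {
    n <- ncol(counts)
    S_i <- colSums(counts)
    S_T <- sum(rowSums(counts) > 0)
    min_sum <- 0; max_sum <- 0
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      b_ij <- sum(counts[, i] & !counts[, j])
      b_ji <- sum(!counts[, i] & counts[, j])
      min_sum <- min_sum + min(b_ij, b_ji)
      max_sum <- max_sum + max(b_ij, b_ji)
    }
    core <- sum(S_i) - S_T
    sim <- if (core + min_sum == 0) 0 else min_sum / (core + min_sum)
    sor <- if (2 * core + min_sum + max_sum == 0) 0 else
      (min_sum + max_sum) / (2 * core + min_sum + max_sum)
  }
  degenerate <- sor == 0
  list(turnover = sim, sorensen = sor, nestedness = sor - sim,
       percent_contribution = if (degenerate) 0 else 100 * sim / sor,
       method = method, degenerate = degenerate)
}

#' Persistence of headwater phylotypes downstream
#'
#' The headwater pool is every ASV present in any of the `n_head` uppermost
#' sites; a pool member persists when it is present in at least
#' `presence_frac` of all downstream samples. Returns the persisting
#' fraction of the pool.
#'
#' @param table An `asv_table` with one sample per transect site.
#' @param transect A `transect`.
#' @param n_head Number of uppermost sites defining the pool (default 3).
#' @param presence_frac Required downstream presence fraction (default 0.9).
#' @return List with `fraction`, `n_pool`, `n_persisting`.
#' @export
headwater_persistence <- function(table, transect, n_head = 3L,
                                  presence_frac = 0.9) {
  samples <- .site_samples(table, transect)
  if (n_head >= length(samples))
    stop("`n_head` must be smaller than the number of sites", call. = FALSE)
  pres <- table$counts[, samples, drop = FALSE] > 0
  head_idx <- seq_len(n_head)
  pool <- rowSums(pres[, head_idx, drop = FALSE]) > 0
  if (!any(pool)) stop("empty headwater pool", call. = FALSE)
  down <- pres[pool, -head_idx, drop = FALSE]
  persisting <- rowMeans(down) >= presence_frac
  list(fraction = mean(persisting), n_pool = sum(pool),
       n_persisting = sum(persisting))
}

#' Read / write ASV tables and sample maps
#'
#' ASV tables are TSV files with ASV ids as row names and sample ids as
#' columns (integer counts); sample maps are CSV with `sample_id`,
#' `site_id` and optional `fraction` columns.
#'
#' @param counts_path Path of the count TSV.
#' @param map_path Path of the sample-map CSV.
#' @param fraction Fraction label for the table.
#' @return `read_asv_table()` returns an `asv_table`.
#' @export
read_asv_table <- function(counts_path, map_path, fraction = "bulk") {
  counts <- as.matrix(utils::read.table(counts_path, header = TRUE, sep = "\t",
                                        row.names = 1L, check.names = FALSE))
  map <- utils::read.csv(map_path, stringsAsFactors = FALSE)
  asv_table(counts, map, fraction = fraction)
}

#' @rdname read_asv_table
#' @param table An `asv_table`.
#' @export
write_asv_table <- function(table, counts_path, map_path) {
  stopifnot(inherits(table, "asv_table"))
  df <- data.frame(asv_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(table$sample_map, map_path, row.names = FALSE, quote = FALSE)
  invisible(counts_path)
}
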