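test_that("shallow libraries are discarded at the read threshold", {
  counts <- matrix(c(3000, 0, 2000, 1155, 4000, 1000), nrow = 2,
                   dimnames = list(c("a1", "a2"), c("s1", "s2", "s3")))
  kept <- drop_shallow(counts, 3155)
  expect_equal(colnames(kept), c("s2", "s3"))
  expect_identical(drop_shallow(counts, 1), counts)
  # brute-force equivalence on a random table
  set.seed(5)
  m <- matrix(rpois(200, 40), nrow = 10,
              dimnames = list(paste0("a", 1:10), paste0("s", 1:20)))
  expect_equal(colnames(drop_shallow(m, 400, prune_empty = FALSE)),
               colnames(m)[colSums(m) >= 400])
  expect_error(drop_shallow(counts, 1e6), "below")
})

test_that("rarefaction conserves depth exactly and converges to expectations", {
  # degenerate single-ASV sample
  one <- matrix(c(500L), 1, 1, dimnames = list("a1", "s1"))
  expect_equal(as.numeric(rarefy(one, depth = 100, reps = 5)), 100)

  # every single repetition hits the depth exactly
  set.seed(9)
  x <- c(50L, 30L, 20L)
  for (i in 1:20) expect_equal(sum(rarefy_once(x, 100)), 100)

  # means converge to depth x proportion (multinomial expectation)
  counts <- matrix(c(500L, 300L, 200L), 3, 1,
                   dimnames = list(paste0("a", 1:3), "s1"))
  m <- rarefy(counts, depth = 100, reps = 200, seed = 1, round = FALSE)
  se <- sqrt(100 * c(.5, .3, .2) * c(.5, .7, .8) / 200)
  expect_true(all(abs(m[, 1] - c(50, 30, 20)) <= 4 * se))
})

test_that("rarefaction is reproducible and per-sample substreams are stable", {
  set.seed(99)
  counts <- matrix(rpois(60, 100), nrow = 6,
                   dimnames = list(paste0("a", 1:6), paste0("s", 1:10)))
  r1 <- rarefy(counts, 200, reps = 10, seed = 4)
  r2 <- rarefy(counts, 200, reps = 10, seed = 4)
  expect_identical(r1, r2)
  # dropping a sample leaves the other samples' draws untouched
  r3 <- rarefy(counts[, -10], 200, reps = 10, seed = 4)
  expect_identical(r3, r1[, -10])
  expect_false(identical(r1, rarefy(counts, 200, reps = 10, seed = 5)))
})

test_that("observed richness counts nonzero ASVs", {
  expect_equal(observed_asvs(c(0, 0, 0)), 0)
  expect_equal(observed_asvs(c(5, 0, 1, 0)), 2)
  set.seed(2)
  m <- matrix(rbinom(300, 3, 0.3), nrow = 30,
              dimnames = list(paste0("a", 1:30), paste0("s", 1:10)))
  expect_equal(unname(observed_asvs(m)),
               unname(apply(m, 2, function(v) sum(v > 0))))
})

test_that("Bray-Curtis matches its definition and vegan on shared input", {
  expect_equal(bray_curtis(c(.5, .5, 0), c(.5, .5, 0)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(.5, .5, 0), c(0, .5, .5)), 0.5)
  expect_error(bray_curtis(c(2, 1), c(.5, .5)), "normalized")
  set.seed(8)
  for (i in 1:10) {
    x <- runif(12); x <- x / sum(x)
    y <- runif(12); y <- y / sum(y)
    expect_equal(bray_curtis(x, y), bray_curtis(y, x))
    expect_equal(bray_curtis(x, y),
                 as.numeric(vegan::vegdist(rbind(x, y), "bray")),
                 tolerance = 1e-12)
  }
})

test_that("beta partition matches exhaustive enumeration and is additive", {
  expect_equal(beta_partition_pair(c(1, 1, 0), c(1, 1, 0))[1:3],
               list(beta_sim = 0, beta_sor = 0, beta_nes = 0))
  dis <- beta_partition_pair(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(dis$beta_sim, 1)
  expect_equal(dis$beta_nes, 0)
  p <- beta_partition_pair(presence_pair(2, 1, 3)$x, presence_pair(2, 1, 3)$y)
  expect_equal(p$beta_sim, 1 / 3)
  expect_equal(p$beta_sor, 0.5)
  expect_equal(p$beta_nes, 0.5 - 1 / 3)
  expect_error(beta_partition_pair(c(0, 0), c(1, 0)), "empty")

  set.seed(21)
  for (i in 1:200) {
    x <- runif(40) < 0.5; y <- runif(40) < 0.5
    if (!any(x) || !any(y)) next
    q <- beta_partition_pair(x, y)
    expect_equal(q$beta_sor, q$beta_sim + q$beta_nes, tolerance = 1e-12)
    o <- partition_oracle(sum(x & y), sum(x & !y), sum(!x & y))
    expect_equal(q$beta_sim, o$beta_sim)
    expect_equal(q$beta_nes, o$beta_nes, tolerance = 1e-12)
  }
})

test_that("consecutive-site series follow the transect ordering", {
  tr <- three_site_transect()
  counts <- matrix(c(5L, 5L, 0L,
                     5L, 5L, 0L,
                     5L, 5L, 0L), nrow = 3,
                   dimnames = list(paste0("a", 1:3), c("a", "b", "c")))
  tab <- toy_asv_table(counts)
  ser <- consecutive_series(tab, tr)
  expect_equal(nrow(ser), 2)
  expect_equal(ser$beta_sim, c(0, 0))
  expect_equal(ser$beta_sor, c(0, 0))
  expect_equal(ser$tt_mid, c(1, 3))
  bc <- consecutive_series(tab, tr, metric = "bray_curtis")
  expect_equal(bc$bray_curtis, c(0, 0))
  # synthetic turnover-structured table: nestedness well below turnover
  tru <- synthetic_truth("jds3like", seed = 6)
  trx <- generate_transect(tru)
  tabx <- generate_asv_table(tru, trx)
  sx <- consecutive_series(tabx, trx)
  expect_equal(nrow(sx), 53)
  expect_lt(median(sx$beta_nes), median(sx$beta_sim) / 3)
})

test_that("whole-river turnover handles degenerate and replaced endpoints", {
  tr <- three_site_transect()
  same <- matrix(rep(c(4L, 2L, 1L), 3), nrow = 3,
                 dimnames = list(paste0("a", 1:3), c("a", "b", "c")))
  w <- whole_river_turnover(toy_asv_table(same), tr)
  expect_equal(w$turnover, 0)
  expect_true(w$degenerate)
  expect_equal(w$percent_contribution, 0)

  swap <- matrix(c(3L, 0L, 2L, 0L, 3L, 0L, 0L, 3L, 0L, 2L, 0L, 3L),
                 nrow = 4, dimnames = list(paste0("a", 1:4), c("a", "b", "c")))
  w2 <- whole_river_turnover(toy_asv_table(swap), tr)
  expect_equal(w2$turnover, 1)
  expect_equal(w2$percent_contribution, 100)
  # multisite Simpson stays within [0, 1] and below/at the Sorensen value
  wm <- whole_river_turnover(toy_asv_table(swap), tr, method = "multisite")
  expect_true(wm$turnover >= 0 && wm$turnover <= 1)
  expect_lte(wm$turnover, wm$sorensen)
})

test_that("headwater persistence matches its definition and is monotone", {
  tr <- build_transect(data.frame(site_id = letters[1:6],
                                  rkm = seq(60, 10, -10), velocity = 2))
  # all ASVs everywhere -> 1; headwater ASVs absent downstream -> 0
  all_there <- matrix(1L, 4, 6, dimnames = list(paste0("a", 1:4), letters[1:6]))
  expect_equal(headwater_persistence(toy_asv_table(all_there), tr)$fraction, 1)
  gone <- all_there; gone[, 4:6] <- 0L; gone[4, ] <- 1L
  expect_equal(
    headwater_persistence(toy_asv_table(gone), tr, presence_frac = 0.9)$fraction,
    0.25)
  # monotone non-increasing in presence_frac
  set.seed(13)
  m <- matrix(rbinom(20 * 6, 1, 0.6), 20, 6,
              dimnames = list(paste0("a", 1:20), letters[1:6]))
  m[1, ] <- 1L
  tab <- toy_asv_table(m)
  fr <- vapply(c(0.2, 0.5, 0.8, 1), function(p)
    headwater_persistence(tab, tr, presence_frac = p)$fraction, numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_error(headwater_persistence(tab, tr, n_head = 6), "smaller")
})

test_that("ASV tables round-trip through TSV and the sample map CSV", {
  tru <- synthetic_truth("jds3like", seed = 3, n_sites = 8L,
                         total_length = 400, tt_target_days = 8,
                         richness_start = 60L, richness_noise_sd = 2,
                         depth = 2000L)
  tr <- generate_transect(tru)
  tab <- generate_asv_table(tru, tr)
  cp <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".csv")
  write_asv_table(tab, cp, mp)
  tab2 <- read_asv_table(cp, mp)
  expect_equal(tab2$counts, tab$counts)
  expect_equal(tab2$sample_map$site_id, tab$sample_map$site_id)
  unlink(c(cp, mp))
})
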