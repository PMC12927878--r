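test_that("ASV selection applies the three filters like a brute-force scan", {
  rel <- matrix(0, 4, 25, dimnames = list(paste0("a", 1:4), paste0("s", 1:25)))
  rel[1, ] <- 0.05                       # prevalent, high, min > 0, ratio 1
  rel[2, 1:24] <- 0.05                   # zero minimum, passes by convention
  rel[3, ] <- 0.004                      # fails the 1% criterion
  rel[4, 1:10] <- 0.05                   # fails prevalence (10 < 20)
  rel <- sweep(rel, 2, colSums(rel), "/")
  sel <- select_asvs(rel, min_prevalence = 20)
  keep2 <- rownames(rel)[apply(rel, 1, function(v) {
    mx <- max(v); mn <- min(v)
    (if (mn == 0) Inf else mx / mn) >= 100 && mx >= 0.01 && sum(v > 0) >= 20
  })]
  expect_setequal(sel, keep2)
  expect_true("a2" %in% sel)
  expect_false("a3" %in% sel)

  # random table equivalence with the scan oracle
  set.seed(19)
  m <- matrix(rexp(40 * 30), 40, 30,
              dimnames = list(paste0("a", 1:40), paste0("s", 1:30)))
  m[m < 0.5] <- 0
  m[, colSums(m) == 0][1, ] <- 1
  m <- sweep(m, 2, colSums(m), "/")
  oracle <- rownames(m)[apply(m, 1, function(v) {
    mx <- max(v); mn <- min(v)
    (if (mn == 0) Inf else mx / mn) >= 100 && mx >= 0.01 && sum(v > 0) >= 20
  })]
  expect_setequal(suppressWarnings(select_asvs(m, min_prevalence = 20)), oracle)
})

test_that("absolute abundance scales relative abundance by TCC", {
  expect_equal(absolute_abundance(0.10, 1e9), 1e8)
  expect_equal(absolute_abundance(0, 5e9), 0)
  expect_equal(absolute_abundance(0.16, 1.44e9), 2.304e8)
  expect_error(absolute_abundance(1.2, 1e9), "\\[0, 1\\]")
  expect_error(absolute_abundance(0.5, 0), "positive")
})

test_that("smoothers reproduce lines exactly and flatten constants", {
  tt <- seq(0, 100, length.out = 30)
  f <- fit_smoother(tt, 5 + 2 * tt)
  expect_lt(max(abs(f$fitted - (5 + 2 * f$grid))), 1e-6)
  d <- derivative_series(f)
  expect_lt(max(abs(d$derivative - 2)), 1e-6)

  # penalty limits: smoothing -> infinity collapses to the straight line
  # (effective df -> 2); penalty -> 0 interpolates the observations
  set.seed(61)
  y <- 5 + 2 * tt + rnorm(30, 0, 3)
  f_inf <- fit_smoother(tt, y, sp = 1e8)
  expect_lt(f_inf$effective_df, 2.05)
  ols <- lm(y ~ tt)
  expect_lt(max(abs(f_inf$fitted -
                      predict(ols, data.frame(tt = f_inf$grid)))), 1e-3)
  f_0 <- fit_smoother(tt, y, basis_dim = 30, sp = 1e-10)
  at_obs <- mgcv::predict.gam(f_0$gam, data.frame(tt = tt))
  expect_lt(max(abs(as.numeric(at_obs) - y)), 1e-3)

  fc <- fit_smoother(tt, rep(3, 30))
  dc <- derivative_series(fc)
  expect_lt(max(abs(dc$derivative)), 1e-8)
  expect_true(all(fc$band_low <= fc$fitted & fc$fitted <= fc$band_high))
  expect_error(fit_smoother(1:5, rnorm(5)), "at least 8")
  # replicate travel times are averaged before fitting
  f2 <- fit_smoother(c(tt, tt), c(5 + 2 * tt + 1, 5 + 2 * tt - 1))
  expect_lt(max(abs(f2$fitted - (5 + 2 * f2$grid))), 1e-6)
})

test_that("spline derivatives match analytic oracles and integrate back", {
  tt <- seq(0, 2 * pi, length.out = 120)
  f <- fit_smoother(tt, sin(tt), basis_dim = 25)
  d <- derivative_series(f)
  expect_lt(max(abs(d$derivative - cos(d$grid))), 0.01)

  # derivative agrees with central finite differences of the fitted curve
  h <- diff(range(f$grid)) * 1e-4
  up <- mgcv::predict.gam(f$gam, data.frame(tt = f$grid + h))
  dn <- mgcv::predict.gam(f$gam, data.frame(tt = f$grid - h))
  fd <- as.numeric((up - dn) / (2 * h))
  expect_lt(max(abs(d$derivative - fd)) / max(abs(fd)), 1e-6)

  # fundamental theorem: trapezoid integral equals the fitted net change
  # (checked on a logistic rise, whose net change is of the curve's scale)
  K <- 1e8; r <- 0.08; t0 <- 60
  tt2 <- seq(0, 120, length.out = 150)
  fl <- fit_smoother(tt2, K / (1 + exp(-r * (tt2 - t0))), basis_dim = 20,
                     grid_n = 400L)
  dl <- derivative_series(fl)
  integral <- sum(diff(dl$grid) *
                    (head(dl$derivative, -1) + tail(dl$derivative, -1)) / 2)
  net <- fl$fitted[length(fl$fitted)] - fl$fitted[1]
  expect_lt(abs(integral - net) / abs(net), 1e-3)
})

test_that("extreme rates land where the logistic oracle puts them", {
  # noiseless logistic: derivative max r*K/4 at t0
  K <- 1e8; r <- 0.08; t0 <- 60
  tt <- seq(0, 120, length.out = 150)
  y <- K / (1 + exp(-r * (tt - t0)))
  f <- fit_smoother(tt, y, basis_dim = 20)
  mc <- max_change(derivative_series(f))
  expect_equal(mc$max_increase, r * K / 4, tolerance = 0.02)
  expect_equal(mc$tt_increase, t0, tolerance = 0.05 * 120)
  expect_true(mc$no_decrease || abs(mc$max_decrease) < 0.02 * r * K / 4)

  dc <- derivative_series(fit_smoother(tt, rep(5, 150)))
  m0 <- max_change(dc)
  expect_equal(m0$max_increase, 0, tolerance = 1e-8)
  expect_equal(m0$max_decrease, 0, tolerance = 1e-8)
})

test_that("sitewise per-capita rates behave like log growth rates", {
  expect_equal(sitewise_rate(1e6, 2e6, 24)$rate_daily, log(2))
  expect_equal(sitewise_rate(5e5, 5e5, 13)$rate_daily, 0)
  # antisymmetry under swapping sites
  r1 <- sitewise_rate(1e6, 4e6, 10)$rate_daily
  r2 <- sitewise_rate(4e6, 1e6, 10)$rate_daily
  expect_equal(r1, -r2)
  ext <- sitewise_rate(1e6, 0, 10)
  expect_true(ext$extinct)
  expect_equal(ext$rate_daily, -Inf)
  expect_error(sitewise_rate(0, 1e6, 10), "positive")
  # ratio against a bulk rate
  rr <- sitewise_rate(1e6, 2e6, 24, bulk_cd_daily = 0.12)
  expect_equal(rr$ratio_to_bulk, log(2) / 0.12)

  # planted bloomer growing at ~100x the bulk rate over a short segment
  bulk <- 0.12                    # 1/d
  rate <- 100 * bulk              # 1/d
  tt_seg <- 10                    # h
  n_up <- 1e5
  n_down <- n_up * exp(rate / 24 * tt_seg)
  est <- sitewise_rate(n_up, n_down, tt_seg, bulk_cd_daily = bulk)
  expect_equal(est$ratio_to_bulk, 100, tolerance = 0.1)
})
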