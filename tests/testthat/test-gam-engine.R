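# The penalized-IRLS engine and GCV selection.

make_series <- function(n, lambda, start = as.Date("2000-01-03"),
                        weekend = FALSE, seed = 1) {
  set.seed(seed)
  dates <- seq(start, by = "day", length.out = n)
  special <- if (weekend) as.integer(iso_weekday(dates) %in% 6:7) else 0L
  as_birth_series(tibble::tibble(
    date = dates, count = rpois(n, lambda), special = special))
}

test_that("intercept-only limit: constant counts, heavy smoothing", {
  n <- 200
  s <- as_birth_series(tibble::tibble(
    date = seq(as.Date("2000-01-01"), by = "day", length.out = n),
    count = 7L, special = 0L))
  d <- build_design(s, gam_control(max_rank_s1 = 12))
  f <- fit_pirls(d, s$count, sp = c(s1 = 1e10))
  expect_true(f$converged)
  expect_equal(f$mu, rep(7, n), tolerance = 1e-6)
})

test_that("canonical-link identity: sum of fitted equals sum of counts", {
  s <- make_series(400, 12, weekend = TRUE, seed = 5)
  d <- build_design(s, gam_control(max_rank_s1 = 15, rank_s2 = 6))
  for (spv in list(c(s1 = 1e-3, s2 = 1e-3), c(s1 = 1, s2 = 10),
                   c(s1 = 1e4, s2 = 1e4))) {
    f <- fit_pirls(d, s$count, sp = spv)
    expect_true(f$converged)
    expect_lt(abs(sum(f$mu) - sum(s$count)) / sum(s$count), 1e-6)
  }
})

test_that("infinite smoothing shrinks to the unpenalized null space", {
  s <- make_series(500, 10, weekend = TRUE, seed = 8)
  d <- build_design(s, gam_control(max_rank_s1 = 20, rank_s2 = 8))
  f <- fit_pirls(d, s$count, sp = c(s1 = 1e12, s2 = 1e12))
  # null space: intercept + linear trend + constant and linear weekend terms
  expect_equal(f$edf_total, 4, tolerance = 1e-3)
  # and the limiting fit matches a plain GLM on the null-space columns
  x <- d$x
  g <- stats::glm(s$count ~ x + s$special + s$special:x, family = poisson())
  expect_equal(f$deviance, deviance(g), tolerance = 1e-5)
  expect_equal(f$mu, unname(fitted(g)), tolerance = 1e-4)
})

test_that("zero weights are equivalent to deleting rows", {
  s <- make_series(300, 9, weekend = TRUE, seed = 3)
  d <- build_design(s, gam_control(max_rank_s1 = 12, rank_s2 = 5))
  drop <- 40:80
  w <- rep(1, 300); w[drop] <- 0
  f_w <- fit_pirls(d, s$count, sp = c(s1 = 2, s2 = 2), weights = w)
  f_d <- fit_pirls(birthgam:::subset_design_rows(d, setdiff(1:300, drop)),
                   s$count[-drop], sp = c(s1 = 2, s2 = 2))
  expect_equal(f_w$coefficients, f_d$coefficients, tolerance = 1e-9)
})

test_that("total edf is non-increasing in each smoothing parameter", {
  s <- make_series(350, 15, weekend = TRUE, seed = 9)
  d <- build_design(s, gam_control(max_rank_s1 = 15, rank_s2 = 6))
  edf1 <- vapply(10^seq(-4, 6, by = 2), function(l) {
    fit_pirls(d, s$count, sp = c(s1 = l, s2 = 1))$edf_total
  }, numeric(1))
  expect_true(all(diff(edf1) <= 1e-6))
  edf2 <- vapply(10^seq(-4, 6, by = 2), function(l) {
    fit_pirls(d, s$count, sp = c(s1 = 1, s2 = l))$edf_total
  }, numeric(1))
  expect_true(all(diff(edf2) <= 1e-6))
})

test_that("GCV picks small edf for noise, large for strong signal", {
  # pure-noise counts around a constant: selected fit stays near-constant
  edfs <- vapply(1:20, function(seed) {
    s <- make_series(300, 10, seed = 100 + seed)
    d <- build_design(s, gam_control(max_rank_s1 = 12))
    sel <- select_smoothing(d, s$count)
    fit_pirls(d, s$count, sel$sp)$edf_total
  }, numeric(1))
  expect_lt(mean(edfs), 5)

  # strongly sinusoidal intensity: selected edf well beyond intercept-only
  set.seed(77)
  n <- 400
  lam <- exp(log(20) + 1 * sin(2 * pi * (1:n) / 100))
  s <- as_birth_series(tibble::tibble(
    date = seq(as.Date("2000-01-01"), by = "day", length.out = n),
    count = rpois(n, lam), special = 0L))
  d <- build_design(s, gam_control(max_rank_s1 = 20))
  sel <- select_smoothing(d, s$count)
  expect_gt(fit_pirls(d, s$count, sel$sp)$edf_total, 6)
})

test_that("a one-point GCV grid returns that point", {
  s <- make_series(200, 8, seed = 4)
  d <- build_design(s, gam_control(max_rank_s1 = 10))
  ctrl <- gam_control(max_rank_s1 = 10, sp_lower = 2, sp_upper = 2,
                      refine_cycles = 0)
  sel <- select_smoothing(d, s$count, ctrl)
  expect_equal(unname(sel$sp[["s1"]]), 100)
})

test_that("unpenalized full-rank fit attains the lowest deviance", {
  # with rank = n and no penalty the fit can interpolate the log pattern of
  # strictly positive counts, so no smaller-rank fit can beat its deviance
  set.seed(12)
  n <- 24
  counts <- rpois(n, 30) + 1L
  s <- as_birth_series(tibble::tibble(
    date = seq(as.Date("2000-01-01"), by = "day", length.out = n),
    count = counts, special = 0L))
  dev_of <- function(q) {
    d <- build_design(s, gam_control(max_rank_s1 = q))
    suppressWarnings(fit_pirls(d, s$count, sp = c(s1 = 0),
                               control = gam_control(max_iter = 500)))$deviance
  }
  expect_lte(dev_of(n), dev_of(10) + 1e-6)
  expect_lte(dev_of(n), dev_of(6) + 1e-6)
  expect_lt(dev_of(n), 1e-4)
})

test_that("the engine agrees with an independent GAM implementation", {
  skip_if_not_installed("mgcv")
  s <- make_series(600, 25, weekend = TRUE, seed = 31)
  x <- (seq_len(600) - 1) / 599
  fit <- fit_birthdate_gam(s, gam_control(max_rank_s1 = 25, rank_s2 = 8))
  mf <- mgcv::gam(
    count ~ s(x, bs = "cr", k = 25) + s(x, bs = "cr", k = 8, by = special),
    family = poisson(),
    data = data.frame(count = s$count, x = x, special = s$special),
    method = "GCV.Cp")
  expect_gt(cor(fit$lambda_hat, fitted(mf)), 0.999)
  expect_lt(max(abs(fit$lambda_hat - fitted(mf)) / fitted(mf)), 0.05)
})
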