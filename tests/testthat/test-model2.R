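canopyA <- function() rate_params(0.85, 3.83, 0.031, 1.0, 1.75, 0.099)

test_that("rate functions evaluate the height-time factorization", {
  p <- canopyA()
  expect_equal(rate_on(p, 0, 6), 3.83)
  expect_equal(rate_on(p, 1, 6), 0.15 * 3.83)
  # a_off = 1: off rate identically zero at the canopy top
  expect_equal(rate_off(p, 1, c(0, 3, 6, 9, 12)), rep(0, 5))
  expect_error(rate_on(p, 1.2, 6), "outside")
  expect_error(rate_on(p, 0.5, 15), "outside")
  expect_error(rate_params(2, 1, 0, 0, 1, 0), "invalid")
})

test_that("integrated rates match the closed form and quadrature", {
  p <- canopyA()
  expect_equal(integrated_rate_on(p, 0, 12), 3.83 * 12 + 0.031 * 144)
  expect_equal(integrated_rate_on(p, 0.7, 0), 0)
  set.seed(6)
  for (i in 1:6) {
    q <- rand_rate_params()
    h <- runif(1)
    ts <- c(1, 6, 11.5)
    expect_equal(integrated_rate_on(q, h, ts),
                 oracle_cumulative(function(t) rate_on(q, h, t), ts),
                 tolerance = 1e-10)
    expect_equal(integrated_rate_off(q, h, ts),
                 oracle_cumulative(function(t) rate_off(q, h, t), ts),
                 tolerance = 1e-10)
  }
})

test_that("all reference canopies have valid (non-negative) rates", {
  tab <- canopy_param_table()
  for (lab in tab$canopy) {
    p <- reference_rate_params(lab, tab)
    hg <- seq(0, 1, by = 0.1)
    tg <- seq(0, 12, by = 0.25)
    expect_true(all(outer(hg, tg, function(h, t) rate_on(p, h, t)) > 0),
                label = paste("on-rate positive, canopy", lab))
    expect_true(all(outer(hg, tg, function(h, t) rate_off(p, h, t)) >= 0),
                label = paste("off-rate non-negative, canopy", lab))
  }
})

test_that("likelihood handles the censored boundary cases analytically", {
  c_on <- 1.3
  c_off <- 0.8
  p <- rate_params(0, c_on, 0, 0, c_off, 0)
  # sunlit whole day: no shaded exposure
  expect_equal(loglik_on(p, rec_sun_all()), 0)
  expect_equal(loglik_off(p, rec_sun_all()), -c_off * 12)
  # shaded whole day: one on-survival term, no off exposure
  expect_equal(loglik_on(p, rec_shade_all()), -c_on * 12)
  expect_equal(loglik_off(p, rec_shade_all()), 0)
  # sunlit at 0, single off-switch at y1 = 4
  r <- switch_record(-1, 4, T_h = 12, h = 0.5)
  expect_equal(loglik_off(p, r), -c_off * 4 + log(c_off))
  expect_equal(loglik_on(p, r), -c_on * 8)
})

test_that("likelihood agrees with the discretization oracle on random records", {
  set.seed(19)
  for (i in 1:6) {
    p <- rand_rate_params()
    recs <- simulate_model2(p, runif(3), seed = 300 + i)
    for (r in recs) {
      expect_equal(loglik_on(p, r), oracle_loglik_m2(p, r, "on", dt = 5e-4),
                   tolerance = 5e-3)
      expect_equal(loglik_off(p, r), oracle_loglik_m2(p, r, "off", dt = 5e-4),
                   tolerance = 5e-3)
    }
  }
})

test_that("fit_model2 is separable and recovers generating parameters", {
  truth <- reference_rate_params("G")
  set.seed(2)
  recs <- simulate_model2(truth, runif(600), seed = 17)
  fit <- fit_model2(recs, label = "G-sim")
  est <- fit$params
  for (nm in c("a_on", "b1_on", "b2_on", "a_off", "b1_off", "b2_off")) {
    # relative 20% with an absolute floor for the small parabolic terms
    expect_lt(abs(est[[nm]] - truth[[nm]]),
              max(0.2 * abs(truth[[nm]]), 0.02),
              label = paste("recovery of", nm))
  }
  # separability: the on-block optimum maximizes l_on alone
  iv <- interval_table(recs)
  base_on <- loglik_on(est, iv)
  base_off <- loglik_off(est, iv)
  for (d in list(c(1e-3, 0, 0), c(0, 1e-3, 0), c(0, 0, 1e-4))) {
    pert <- est; pert$a_on <- est$a_on + d[1]
    pert$b1_on <- est$b1_on + d[2]; pert$b2_on <- est$b2_on + d[3]
    expect_lte(loglik_on(pert, iv), base_on + 1e-6)
    expect_equal(loglik_off(pert, iv), base_off)  # off block untouched
  }
  expect_error(fit_model2(list(rec_sun_all(), rec_shade_all())), "censored")
})

test_that("simulation honours the initial-state law and the h=1 boundary", {
  p <- canopyA()
  # a_off = 1 and h = 1: once sunlit, sunlit forever
  recs <- simulate_model2(p, rep(1, 200), seed = 5)
  for (r in recs) {
    expect_equal(r$x, -1)
    expect_gt(r$y[1], 12)
  }
  # initial state Bernoulli(h)
  recs3 <- simulate_model2(p, rep(0.3, 3000), seed = 8)
  frac <- mean(vapply(recs3, function(r) length(r$x) > 0 && r$x[1] < 0,
                      logical(1)))
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 3000))
  # determinism
  a <- simulate_model2(p, 0.5, seed = 77)
  b <- simulate_model2(p, 0.5, seed = 77)
  expect_identical(a, b)
})

test_that("flux_from_record masks the envelope by the sunlit state", {
  env <- list(t_min = seq(0, 719, by = 1), values = rep(1000, 720))
  expect_equal(flux_from_record(rec_sun_all(), env)$flux, env$values)
  expect_equal(flux_from_record(rec_shade_all(), env)$flux, rep(0, 720))
  r <- switch_record(5, 7, T_h = 12, h = 0.5)
  fl <- flux_from_record(r, env)$flux
  on <- env$t_min / 60 >= 5 & env$t_min / 60 < 7
  expect_true(all(fl[on] > 0))
  expect_true(all(fl[!on] == 0))
})

test_that("fitted parameters round-trip through JSON", {
  set.seed(1)
  recs <- simulate_model2(canopyA(), runif(80), seed = 2)
  fit <- fit_model2(recs, label = "rt")
  f <- tempfile(fileext = ".json")
  write_fitted_json(fit, f, provenance = list(seed = 2))
  back <- read_fitted_json(f)
  for (nm in c("a_on", "b1_on", "b2_on", "a_off", "b1_off", "b2_off"))
    expect_equal(back[[nm]], fit$params[[nm]])
})
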