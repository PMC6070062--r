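test_that("non-rectangular hyperbola limits and bounds", {
  r <- light_response(p_max = 20, phi = 0.06, theta_cvx = 0.9)
  I <- c(0, 10, 50, 200, 1000, 2500)
  P <- nrh_assimilation(r, I)
  expect_equal(P[1], 0)
  expect_true(all(diff(P) >= 0))
  expect_true(all(P <= r$p_max + 1e-12))

  # theta -> 0: rectangular hyperbola
  r0 <- light_response(p_max = 20, phi = 0.06, theta_cvx = 1e-8)
  expect_equal(nrh_assimilation(r0, I), 0.06 * I * 20 / (0.06 * I + 20),
               tolerance = 1e-6)
  # theta = 1: Blackman response min(phi I, Pmax)
  r1 <- light_response(p_max = 20, phi = 0.06, theta_cvx = 1)
  expect_equal(nrh_assimilation(r1, I), pmin(0.06 * I, 20), tolerance = 1e-9)

  expect_error(light_response(20, phi = -1), "phi")
  expect_error(light_response(20, theta_cvx = 1.2), "theta")
  expect_error(nrh_assimilation(r, -5), "non-negative")
})

test_that("diffuse scaling recovers least-squares scalars and height trend", {
  prof <- diffuse_profile(solar_config(dt_min = 10))
  h <- seq(0.05, 0.95, length.out = 60)
  s_true <- 0.2 + 0.7 * h          # deeper patches see less sky
  traces <- outer(s_true, prof)
  fit <- fit_diffuse_scaling(traces, prof, h)
  expect_equal(fit$s, s_true, tolerance = 1e-12)
  expect_true(all(diff(fit$curve$s_mean) > 0))
  # interpolator follows the curve
  expect_equal(fit$fn(0.5), 0.2 + 0.7 * 0.5, tolerance = 0.02)

  expect_equal(fit_diffuse_scaling(matrix(0, 1, length(prof)), prof, 0.5)$s, 0)
  expect_error(fit_diffuse_scaling(traces, prof * 0, h), "zero")
  expect_error(fit_diffuse_scaling(traces[, -1], prof, h), "grid")
})

test_that("daily carbon gain integrates the light response over the day", {
  r <- light_response(p_max = 12.6, phi = 0.062, theta_cvx = 0.83)
  n <- 720
  env_const <- list(t_min = 0:(n - 1), values = rep(500, n))
  # permanently shaded, no diffuse: zero gain
  expect_equal(daily_carbon_gain(rec_shade_all(), env_const, 0, r), 0)
  # constant irradiance: closed-form 12 h * 3600 s * P(I)
  gain <- daily_carbon_gain(rec_sun_all(), env_const, 0, r)
  expect_equal(gain, 12 * 3600 * nrh_assimilation(r, 500), tolerance = 1e-9)
  # monotone in the sunlit fraction at fixed diffuse
  gains <- vapply(c(2, 4, 6, 8), function(len) {
    rec <- switch_record(3, 3 + len, T_h = 12, h = 0.5)
    daily_carbon_gain(rec, env_const, 50, r)
  }, numeric(1))
  expect_true(all(diff(gains) > 0))
  # averaging over realizations
  two <- list(rec_sun_all(), rec_shade_all())
  expect_equal(daily_carbon_gain(two, env_const, 0, r), gain / 2)
})

test_that("photoinhibition scenarios scale layers and order correctly", {
  set.seed(31)
  n <- 144
  h <- runif(30)
  env <- list(t_min = seq(0, 715, by = 5), values = rep(800, n))
  records <- lapply(h, function(hi) switch_record(-1, 13, T_h = 12, h = hi))
  envelopes <- rep(list(env), 30)
  diffuse <- matrix(60, 30, n)

  base <- photoinhibition_scenarios(records, envelopes, diffuse, h,
                                    scenario = "both")
  expect_equal(base$per_layer$reduction_pct[base$per_layer$layer == "bottom"],
               0)
  expect_true(all(base$gains_inhibited <= base$gains_control + 1e-9))

  # no inhibition anywhere: zero reduction
  none <- photoinhibition_scenarios(records, envelopes, diffuse, h,
                                    scalings = c(top = 1, middle = 1,
                                                 bottom = 1),
                                    scenario = "both")
  expect_equal(none$total_reduction_pct, 0)

  # 'both' dominates the single-parameter scenarios
  red <- vapply(c("phi", "theta", "both"), function(sc)
    photoinhibition_scenarios(records, envelopes, diffuse, h,
                              scenario = sc)$total_reduction_pct, numeric(1))
  expect_gte(red[["both"]], red[["phi"]] - 1e-9)
  expect_gte(red[["both"]], red[["theta"]] - 1e-9)
})

test_that("layer assignment splits heights into equal thirds", {
  expect_equal(as.character(assign_layers(c(0.1, 0.5, 0.9))),
               c("bottom", "middle", "top"))
  expect_equal(as.character(assign_layers(c(1 / 3, 2 / 3))),
               c("bottom", "middle"))
})
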