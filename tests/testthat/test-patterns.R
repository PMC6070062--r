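test_that("classification applies the 10% relative rule", {
  env <- c(0.5, rep(100, 5), 0.5)   # sub-cutoff edges
  t_min <- 0:6
  mk <- function(flux) classify_sunlit(
    structure(list(patch_id = 1L, t_min = t_min, flux = flux,
                   envelope = env, h = 0.5), class = "light_trace"))
  expect_true(all(mk(env)$state[2:6]))
  expect_true(all(mk(0.95 * env)$state[2:6]))    # 5% off: still sunlit
  expect_false(any(mk(0.85 * env)$state[2:6]))   # 15% off: shaded
  expect_true(all(is.na(mk(env)$state[c(1, 7)])))
  expect_error(classify_sunlit(
    structure(list(patch_id = 1L, t_min = t_min, flux = env[-1],
                   envelope = env, h = 0.5), class = "light_trace"),
    envelope = env), "grids")
})

test_that("switch extraction encodes the four boundary cases", {
  pat <- function(state) structure(
    list(patch_id = 1L, t_min = seq(0, 719, by = 1), state = state,
         T_h = 12, h = 0.4), class = "binary_pattern")

  r <- extract_switches(pat(rep(TRUE, 720)))
  expect_length(r$x, 1)
  expect_lt(r$x[1], 0)
  expect_gt(r$y[1], 12)

  st <- rep(FALSE, 720); st[seq_len(180)] <- TRUE  # sunlit before 3 h
  r2 <- extract_switches(pat(st))
  expect_equal(r2$x, -1)
  expect_equal(r2$y, 3)

  r3 <- extract_switches(pat(rep(FALSE, 720)))
  expect_length(r3$x, 0)

  st4 <- rep(FALSE, 720); st4[300:720] <- TRUE
  r4 <- extract_switches(pat(st4))
  expect_equal(r4$x, 299 / 60)
  expect_gt(r4$y[1], 12)
})

test_that("classify -> extract -> reconstruct round-trips at grid resolution", {
  # fast alternation: one-minute flicker for 10 min then sunlit
  st <- rep(TRUE, 720)
  st[1:10] <- rep(c(FALSE, TRUE), 5)
  pat <- structure(list(patch_id = 1L, t_min = 0:719, state = st,
                        T_h = 12, h = 0.2), class = "binary_pattern")
  rec <- extract_switches(pat)
  expect_length(rec$x, 5)  # 5 on/off pairs (last off is the sentinel)
  expect_identical(reconstruct_pattern(rec, 0:719), st)

  # property: random patterns round-trip exactly
  set.seed(10)
  for (i in 1:20) {
    s <- runif(720) < 0.5
    # smooth into runs so patterns look like light traces
    s <- rep(s[seq(1, 720, by = 24)], each = 24)
    p <- structure(list(patch_id = i, t_min = 0:719, state = s,
                        T_h = 12, h = runif(1)), class = "binary_pattern")
    r <- extract_switches(p)
    expect_identical(reconstruct_pattern(r, 0:719), s)
    expect_length(r$x, length(r$y))
  }
})

test_that("switch_record validates alternation", {
  expect_error(switch_record(c(3, 2), c(5, 6)), "alternate")
  expect_error(switch_record(5, 3), "alternate")
  expect_silent(switch_record(c(-1, 5), c(3, 13)))
})

test_that("duration distributions exclude censored boundary periods", {
  r <- switch_record(2, 5, T_h = 12, h = 0.5)   # sunlit on (2,5) only
  d <- duration_distributions(list(r))
  expect_equal(d$sunlit, 180)
  expect_length(d$shaded, 0)    # both shaded periods touch the boundary

  expect_length(duration_distributions(list(rec_sun_all()))$sunlit, 0)

  r2 <- switch_record(c(2, 6), c(4, 9), T_h = 12, h = 0.5)
  d2 <- duration_distributions(list(r2))
  expect_equal(sort(d2$sunlit), c(120, 180))
  expect_equal(d2$shaded, 120)
})

test_that("constant-rate durations match the exponential holding-time oracle", {
  p <- rate_params(0, 3, 0, 0, 5, 0)   # constant rates, no height effect
  recs <- simulate_model2(p, rep(0.5, 400), seed = 31)
  d <- duration_distributions(recs)
  expect_gt(length(d$sunlit), 200)
  # mean sunlit duration ~ 1/lambda_off = 12 min
  se <- sd(d$sunlit) / sqrt(length(d$sunlit))
  expect_lt(abs(mean(d$sunlit) - 60 / 5), 4 * se + 1)
})

test_that("switch records round-trip through CSV", {
  recs <- c(fig2_records(h = 0.3),
            list(switch_record(c(1.5, 7), c(3, 11), T_h = 12, h = 0.9,
                               patch_id = 9L)))
  for (i in seq_along(recs)) recs[[i]]$patch_id <- i
  f <- tempfile(fileext = ".csv")
  write_switch_records(recs, f, provenance = c(tool = "test"))
  back <- read_switch_records(f)
  expect_length(back, length(recs))
  for (i in seq_along(recs)) {
    expect_equal(back[[i]]$x, recs[[i]]$x)
    expect_equal(back[[i]]$y, recs[[i]]$y)
    expect_equal(back[[i]]$h, recs[[i]]$h)
  }
})
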