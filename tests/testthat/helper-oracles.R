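# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: quadrature instead of the cubic, a
# Bernoulli-product discretization instead of the interval likelihood, and a
# plain-R ray-triangle loop instead of the compiled kernel.

# standard solar declination, degrees
oracle_declination <- function(day) 23.45 * sin(2 * pi * (284 + day) / 365)

# integrate a rate function numerically
oracle_cumulative <- function(rate_fn, t) {
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    stats::integrate(rate_fn, 0, ti, rel.tol = 1e-12,
                     abs.tol = 1e-12)$value
  }, numeric(1))
}

# Bernoulli-product discretization of a point-process log-likelihood over an
# exposure set: each step of width dt survives with probability
# exp(-lambda(t) dt) (the step form of "no event in (t, t+dt)"; the cruder
# 1 - lambda dt variant carries an O(lambda^2 T dt) bias that would swamp
# the comparison tolerance at realistic switching rates), and events
# contribute log lambda. `exposure` is a data frame of (t0, t1) intervals
# during which the process is "at risk"; `events` are the interior event
# times (each must terminate one exposure interval). No closed-form
# integration is used anywhere.
oracle_loglik_discretized <- function(rate_fn, exposure, events, dt = 1e-4) {
  ll <- 0
  for (i in seq_len(nrow(exposure))) {
    t0 <- exposure$t0[i]
    t1 <- exposure$t1[i]
    if (t1 <= t0) next
    grid <- seq(t0, t1, by = dt)
    mids <- grid[-length(grid)] + dt / 2
    ll <- ll - sum(rate_fn(mids) * dt)
    # partial last step
    rem <- t1 - grid[length(grid)]
    if (rem > 1e-12)
      ll <- ll - rate_fn(t1 - rem / 2) * rem
  }
  ll + sum(log(rate_fn(events)))
}

# model-1 discretization oracle: exposure is the whole window
oracle_loglik_m1 <- function(theta, events, T_h = 12, t_md = 6, dt = 1e-4) {
  rate_fn <- function(t) theta[1] + theta[2] * t + theta[3] * (t - t_md)^2
  oracle_loglik_discretized(rate_fn, data.frame(t0 = 0, t1 = T_h),
                            events, dt)
}

# model-2 per-state discretization oracle built from a record's intervals
oracle_loglik_m2 <- function(params, record, state = c("on", "off"),
                             dt = 1e-4) {
  state <- match.arg(state)
  iv <- record_intervals(record)
  expo_state <- if (state == "on") "shade" else "sun"
  sel <- iv$state == expo_state
  expo <- iv[sel, c("t0", "t1")]
  events <- iv$t1[sel & iv$ended]
  h <- record$h
  rate_fn <- if (state == "on") {
    function(t) rate_on(params, h, t)
  } else {
    function(t) rate_off(params, h, t)
  }
  if (nrow(expo) == 0L) return(0)
  oracle_loglik_discretized(rate_fn, expo, events, dt)
}

# plain-R Moller-Trumbore over every triangle (no wrapping, no indexing)
oracle_occluded <- function(canopy, patch, sun_dir) {
  sun_dir <- sun_dir / sqrt(sum(sun_dir^2))
  p <- canopy$patches[patch, ]
  o <- c(p$cx, p$cy, p$cz)
  v <- canopy$vertices
  f <- canopy$faces
  for (k in seq_len(nrow(f))) {
    if (k == patch) next
    a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; cc <- v[f[k, 3], ]
    e1 <- b - a; e2 <- cc - a
    hh <- c(sun_dir[2] * e2[3] - sun_dir[3] * e2[2],
            sun_dir[3] * e2[1] - sun_dir[1] * e2[3],
            sun_dir[1] * e2[2] - sun_dir[2] * e2[1])
    det <- sum(e1 * hh)
    if (abs(det) < 1e-12) next
    s <- o - a
    u <- sum(s * hh) / det
    if (u < -1e-9 || u > 1 + 1e-9) next
    q <- c(s[2] * e1[3] - s[3] * e1[2],
           s[3] * e1[1] - s[1] * e1[3],
           s[1] * e1[2] - s[2] * e1[1])
    vv <- sum(sun_dir * q) / det
    if (vv < -1e-9 || u + vv > 1 + 1e-9) next
    t <- sum(e2 * q) / det
    if (t > 1e-9) return(TRUE)
  }
  FALSE
}

# random valid parameter draws ---------------------------------------------

rand_m1_theta <- function() {
  repeat {
    th <- c(runif(1, 0.5, 4), runif(1, -0.2, 0.2), runif(1, -0.08, 0.08))
    tg <- seq(0, 12, by = 0.01)
    if (all(th[1] + th[2] * tg + th[3] * (tg - 6)^2 > 0.05)) return(th)
  }
}

rand_rate_params <- function() {
  repeat {
    p <- try(rate_params(runif(1, 0, 0.95), runif(1, 0.5, 4),
                         runif(1, -0.05, 0.2),
                         runif(1, 0, 1), runif(1, 0.5, 4),
                         runif(1, -0.05, 0.2)), silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
}
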