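#' Height- and time-dependent switching rates (two-state model)
#'
#' The main model: each patch alternates between shaded and sunlit states,
#' switching on (shaded to sunlit) at rate
#' `lambda_h_on(t) = (1 - a_on h) (b1_on + b2_on (t - t_md)^2)` and off at
#' the analogous `lambda_h_off(t)`, where `h` is the patch's normalized
#' height. Rates depend linearly on height and parabolically (symmetric
#' about noon) on time. Validity requires `lambda_on > 0` and
#' `lambda_off >= 0` over the whole `[0,1] x [0,T]` domain; `a_off = 1` is
#' permitted and makes the off rate exactly zero at the canopy top, where
#' unobstructed patches stay permanently sunlit.
#'
#' @param a_on,a_off height slopes (dimensionless).
#' @param b1_on,b1_off constant rate coefficients, per hour.
#' @param b2_on,b2_off parabolic rate coefficients, per hour cubed.
#' @param t_md solar noon, hours (default 6).
#' @param T_h window length, hours (default 12).
#' @return object of class `rate_params`.
#' @export
rate_params <- function(a_on, b1_on, b2_on, a_off, b1_off, b2_off,
                        t_md = 6, T_h = 12) {
  p <- structure(list(a_on = a_on, b1_on = b1_on, b2_on = b2_on,
                      a_off = a_off, b1_off = b1_off, b2_off = b2_off,
                      t_md = t_md, T_h = T_h),
                 class = "rate_params")
  v <- .validate_rates(p)
  if (!v$ok) stop("invalid rate parameters: ", v$why)
  p
}

# validity on the [0,1] x [0,T] grid; on-rate strictly positive, off-rate
# non-negative. Linearity in h means checking h in {0, 1} suffices, and the
# parabola's extrema lie at t in {0, t_md, T}.
.validate_rates <- function(p) {
  tc <- c(0, p$t_md, p$T_h)
  par_on <- p$b1_on + p$b2_on * (tc - p$t_md)^2
  par_off <- p$b1_off + p$b2_off * (tc - p$t_md)^2
  ch <- c(1, 1 - p$a_on)
  cf <- c(1, 1 - p$a_off)
  lam_on <- as.vector(outer(ch, par_on))
  lam_off <- as.vector(outer(cf, par_off))
  if (any(lam_on <= 0))
    return(list(ok = FALSE, why = "on-rate not strictly positive",
                margin = min(lam_on)))
  if (any(lam_off < 0))
    return(list(ok = FALSE, why = "off-rate negative",
                margin = min(lam_off)))
  list(ok = TRUE, why = "", margin = min(lam_on, lam_off))
}

.check_ht <- function(p, h, t) {
  if (any(h < 0 | h > 1)) stop("h outside [0, 1]")
  if (any(t < 0 | t > p$T_h)) stop("t outside [0, T]")
}

#' On- and off-switching rates
#' @param params a [rate_params()].
#' @param h normalized height(s) in \[0, 1\].
#' @param t time(s) in hours, in \[0, T\].
#' @return rate(s), per hour.
#' @export
rate_on <- function(params, h, t) {
  stopifnot(inherits(params, "rate_params"))
  .check_ht(params, h, t)
  (1 - params$a_on * h) * (params$b1_on + params$b2_on * (t - params$t_md)^2)
}

#' @rdname rate_on
#' @export
rate_off <- function(params, h, t) {
  stopifnot(inherits(params, "rate_params"))
  .check_ht(params, h, t)
  (1 - params$a_off * h) * (params$b1_off + params$b2_off * (t - params$t_md)^2)
}

#' Integrated switching rates
#'
#' Closed-form cubic `Lambda_h(t) = (1 - a h) (b1 t + b2 ((t - t_md)^3 +
#' t_md^3) / 3)`; zero at `t = 0` and non-decreasing for valid parameters.
#'
#' @inheritParams rate_on
#' @return integrated rate(s), dimensionless.
#' @export
integrated_rate_on <- function(params, h, t) {
  stopifnot(inherits(params, "rate_params"))
  .check_ht(params, h, t)
  c_h <- 1 - params$a_on * h
  c_h * .cum_eval(params$b1_on, 0, params$b2_on / 3, params$t_md, t)
}

#' @rdname integrated_rate_on
#' @export
integrated_rate_off <- function(params, h, t) {
  stopifnot(inherits(params, "rate_params"))
  .check_ht(params, h, t)
  c_h <- 1 - params$a_off * h
  c_h * .cum_eval(params$b1_off, 0, params$b2_off / 3, params$t_md, t)
}

# interval-bookkeeping log-likelihood core. For the "on" likelihood, shaded
# intervals are the exposure: each contributes the survival term
# -(Lambda_on(t1) - Lambda_on(t0)) at the patch height, and, when the
# interval ends with an interior on-switch, the event term
# log lambda_on(t1). The "off" likelihood mirrors this over sunlit
# intervals. This interval form reduces to the textbook per-event sums in
# the interior and handles all four censored boundary cases uniformly.
.loglik_state <- function(a, b1, b2, tmd, iv, want_state) {
  sel <- iv$state == want_state
  if (!any(sel)) return(0)
  h <- iv$h[sel]
  c_h <- 1 - a * h
  g <- function(t) .cum_eval(b1, 0, b2 / 3, tmd, t)
  surv <- -c_h * (g(iv$t1[sel]) - g(iv$t0[sel]))
  ev <- iv$ended[sel]
  lam <- c_h[ev] * (b1 + b2 * (iv$t1[sel][ev] - tmd)^2)
  if (any(lam <= 0)) return(-Inf)
  sum(surv) + sum(log(lam))
}

#' Log-likelihood of the on-rate parameters given switching records
#'
#' Sums per-patch contributions over all shaded exposure intervals: survival
#' terms for time spent shaded and log-rate terms at interior on-switches.
#' A patch sunlit for the whole day has no shaded exposure and contributes 0.
#'
#' @param params a [rate_params()] (or list with the on/off fields).
#' @param records a [switch_record()] or list of them, or a pre-computed
#'   [interval_table()].
#' @return scalar log-likelihood.
#' @export
loglik_on <- function(params, records) {
  iv <- if (is.data.frame(records)) records else interval_table(records)
  .loglik_state(params$a_on, params$b1_on, params$b2_on, params$t_md,
                iv, "shade")
}

#' @rdname loglik_on
#' @export
loglik_off <- function(params, records) {
  iv <- if (is.data.frame(records)) records else interval_table(records)
  .loglik_state(params$a_off, params$b1_off, params$b2_off, params$t_md,
                iv, "sun")
}

#' @rdname loglik_on
#' @export
loglik_model2 <- function(params, records) {
  iv <- if (is.data.frame(records)) records else interval_table(records)
  loglik_on(params, iv) + loglik_off(params, iv)
}

# penalized per-state objective for the optimizer. theta = (a, b1, b2).
# Feasibility: rate factor (1 - a h) must be positive (non-negative for the
# off state) at every observed h, and the time parabola non-negative with
# positive values at the observed event times; soft penalties steer the
# simplex back into the feasible region.
.m2_objective <- function(theta, iv, want_state, tmd, T_h, strict) {
  a <- theta[1L]; b1 <- theta[2L]; b2 <- theta[3L]
  hmax <- 1
  cmin <- 1 - a * hmax
  cmin0 <- 1 - a * 0
  tc <- c(0, tmd, T_h)
  parab <- b1 + b2 * (tc - tmd)^2
  pen <- 0
  if (strict && cmin <= 0) pen <- pen + 1 + abs(cmin)
  if (!strict && cmin < 0) pen <- pen + 1 + abs(cmin)
  if (cmin0 <= 0) pen <- pen + 1 + abs(cmin0)
  if (strict && min(parab) <= 0) pen <- pen + 1 + abs(min(parab))
  if (!strict && min(parab) < 0) pen <- pen + 1 + abs(min(parab))
  if (pen > 0) return(-1e10 * pen)
  ll <- .loglik_state(a, b1, b2, tmd, iv, want_state)
  if (!is.finite(ll)) return(-1e10)
  ll
}

.fit_state <- function(iv, want_state, tmd, T_h, strict, init, control) {
  fit <- optim(init, .m2_objective, iv = iv, want_state = want_state,
               tmd = tmd, T_h = T_h, strict = strict,
               method = "Nelder-Mead", control = control)
  # one polish from the optimum; Nelder-Mead benefits from a restart
  fit2 <- optim(fit$par, .m2_objective, iv = iv, want_state = want_state,
                tmd = tmd, T_h = T_h, strict = strict,
                method = "Nelder-Mead", control = control)
  if (fit2$value > fit$value) fit <- fit2
  fit
}

#' Maximum-likelihood fit of the two-state switching model
#'
#' The on-rate parameters appear only in the shaded-exposure likelihood and
#' the off-rate parameters only in the sunlit-exposure likelihood, so the
#' two triples are fitted independently (Nelder-Mead with soft positivity
#' penalties; the off-rate is allowed to touch zero at `h = 1`,
#' i.e. `a_off = 1`). Initial values default to height-slope 0.5 and
#' moment-matching constant rates (events per hour of exposure).
#'
#' @param records list of [switch_record()]s (or an [interval_table()]).
#' @param init optional [rate_params()] or named list to start from.
#' @param label canopy label carried into the result.
#' @param control passed to [stats::optim()]; defaults `maxit = 5000`,
#'   `reltol = 1e-10`.
#' @return object of class `fitted_canopy`: `params` ([rate_params()]),
#'   `loglik_on`, `loglik_off`, `loglik`, `n_patches`, `n_on_events`,
#'   `n_off_events`, `convergence`, `label`.
#' @export
fit_model2 <- function(records, init = NULL, label = NA_character_,
                       control = list()) {
  iv <- if (is.data.frame(records)) records else interval_table(records)
  tmd <- 6; T_h <- 12
  if (!is.data.frame(records) && length(records) > 0L) {
    r1 <- if (inherits(records, "switch_record")) records else records[[1L]]
    T_h <- r1$T_h
  }
  n_on <- sum(iv$ended[iv$state == "shade"])
  n_off <- sum(iv$ended[iv$state == "sun"])
  if (n_on + n_off == 0L)
    stop("all records are fully censored: no switching events to fit")
  control <- utils::modifyList(list(maxit = 5000L, reltol = 1e-10,
                                    fnscale = -1), control)

  exp_shade <- sum(iv$t1[iv$state == "shade"] - iv$t0[iv$state == "shade"])
  exp_sun <- sum(iv$t1[iv$state == "sun"] - iv$t0[iv$state == "sun"])
  if (is.null(init)) {
    init_on <- c(0.5, max(n_on, 1L) / max(exp_shade, 1e-6), 0)
    init_off <- c(0.5, max(n_off, 1L) / max(exp_sun, 1e-6), 0)
  } else {
    init_on <- c(init$a_on, init$b1_on, init$b2_on)
    init_off <- c(init$a_off, init$b1_off, init$b2_off)
  }

  f_on <- .fit_state(iv, "shade", tmd, T_h, strict = TRUE, init_on, control)
  f_off <- .fit_state(iv, "sun", tmd, T_h, strict = FALSE, init_off, control)
  if (f_on$value <= -1e9 || f_off$value <= -1e9)
    stop("optimizer failed to find feasible rate parameters")

  params <- rate_params(f_on$par[1L], f_on$par[2L], f_on$par[3L],
                        f_off$par[1L], f_off$par[2L], f_off$par[3L],
                        t_md = tmd, T_h = T_h)
  structure(list(params = params, loglik_on = f_on$value,
                 loglik_off = f_off$value,
                 loglik = f_on$value + f_off$value,
                 n_patches = length(unique(iv$patch_id)),
                 n_on_events = n_on, n_off_events = n_off,
                 convergence = max(f_on$convergence, f_off$convergence),
                 label = label),
            class = "fitted_canopy")
}

#' @export
print.fitted_canopy <- function(x, ...) {
  p <- x$params
  cat(sprintf("fitted_canopy%s: %d patches, %d on / %d off events\n",
              if (is.na(x$label)) "" else paste0(" ", x$label),
              x$n_patches, x$n_on_events, x$n_off_events))
  cat(sprintf("  on : a = %.3f, b1 = %.3f, b2 = %.4f\n",
              p$a_on, p$b1_on, p$b2_on))
  cat(sprintf("  off: a = %.3f, b1 = %.3f, b2 = %.4f\n",
              p$a_off, p$b1_off, p$b2_off))
  cat(sprintf("  loglik %.3f (on %.3f, off %.3f)\n",
              x$loglik, x$loglik_on, x$loglik_off))
  invisible(x)
}

#' Simulate switching records from the two-state model
#'
#' The initial state is sunlit with probability `h` (patches near the top
#' tend to start sunlit). Holding times are then drawn alternately by the
#' inversion method from the state-appropriate integrated rate at the
#' patch's height, until the window ends; censored boundary states receive
#' their sentinel encodings.
#'
#' @param params a [rate_params()].
#' @param h normalized height(s) in \[0, 1\]; one record per element.
#' @param seed RNG seed.
#' @param patch_id ids for the records (defaults to `seq_along(h)`).
#' @return a [switch_record()] for scalar `h`, else a list of them.
#' @export
simulate_model2 <- function(params, h, seed = 1L, patch_id = seq_along(h)) {
  stopifnot(inherits(params, "rate_params"))
  if (any(h < 0 | h > 1)) stop("h outside [0, 1]")
  tmd <- params$t_md; T_h <- params$T_h
  n <- length(h)
  set.seed(seed)

  sun <- runif(n) < h           # current state, TRUE = sunlit
  init_sun <- sun
  t_cur <- numeric(n)
  active <- rep(TRUE, n)
  events <- vector("list", n)   # interior event times, alternating
  c_on <- 1 - params$a_on * h
  c_off <- 1 - params$a_off * h

  while (any(active)) {
    idx <- which(active)
    E <- rexp(length(idx))
    s <- sun[idx]
    # exposure in state "sunlit" waits for an off event, and vice versa
    A <- ifelse(s, c_off[idx] * params$b1_off, c_on[idx] * params$b1_on)
    C <- ifelse(s, c_off[idx] * params$b2_off / 3,
                c_on[idx] * params$b2_on / 3)
    u <- .cum_solve(A, 0, C, tmd, t_cur[idx], E, T_h)
    done <- is.na(u)
    active[idx[done]] <- FALSE
    hit <- idx[!done]
    uh <- u[!done]
    for (k in seq_along(hit))
      events[[hit[k]]] <- c(events[[hit[k]]], uh[k])
    t_cur[hit] <- uh
    sun[hit] <- !sun[hit]
  }

  recs <- lapply(seq_len(n), function(i)
    .record_from_events(init_sun[i], events[[i]], T_h, h[i], patch_id[i]))
  if (n == 1L) recs[[1L]] else recs
}

# assemble a switch_record from an initial state and alternating interior
# event times (first event flips the initial state)
.record_from_events <- function(init_sun, ev, T_h, h, patch_id) {
  ne <- length(ev)
  if (init_sun) {
    y <- ev[seq_len(ne) %% 2L == 1L]   # odd events are off-switches
    x <- c(-1, ev[seq_len(ne) %% 2L == 0L])
    if (length(x) > length(y)) y <- c(y, T_h + 1)  # ends sunlit
  } else {
    x <- ev[seq_len(ne) %% 2L == 1L]
    y <- ev[seq_len(ne) %% 2L == 0L]
    if (length(x) > length(y)) y <- c(y, T_h + 1)
  }
  switch_record(x, y, T_h = T_h, h = h, patch_id = patch_id)
}

#' Direct-light flux implied by a switching record
#'
#' `flux(t) = A_dr(t) * I(patch sunlit at t)`: the envelope during sunlit
#' intervals and zero otherwise.
#'
#' @param record a [switch_record()].
#' @param envelope an `envelope_trace` (or list with `t_min`, `values`).
#' @return a `light_trace`.
#' @export
flux_from_record <- function(record, envelope) {
  stopifnot(inherits(record, "switch_record"))
  state <- reconstruct_pattern(record, envelope$t_min)
  structure(list(patch_id = record$patch_id, t_min = envelope$t_min,
                 flux = envelope$values * as.numeric(state),
                 envelope = envelope$values, h = record$h),
            class = "light_trace")
}

#' Serialize a fitted canopy to JSON
#' @param fit a `fitted_canopy` from [fit_model2()].
#' @param path output path.
#' @param provenance optional named list merged into the JSON.
#' @export
write_fitted_json <- function(fit, path, provenance = NULL) {
  stopifnot(inherits(fit, "fitted_canopy"))
  p <- fit$params
  obj <- list(label = fit$label,
              params = p[c("a_on", "b1_on", "b2_on",
                           "a_off", "b1_off", "b2_off", "t_md", "T_h")],
              loglik = fit$loglik, loglik_on = fit$loglik_on,
              loglik_off = fit$loglik_off, n_patches = fit$n_patches,
              n_on_events = fit$n_on_events, n_off_events = fit$n_off_events)
  if (!is.null(provenance)) obj$provenance <- provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read rate parameters from JSON written by [write_fitted_json()]
#' @param path JSON path.
#' @return a [rate_params()].
#' @export
read_fitted_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(rate_params, obj$params)
}
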