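#' Single-patch non-homogeneous Poisson switching model
#'
#' The preliminary model treats the switching times of one patch as events of
#' a non-homogeneous Poisson process with quadratic intensity
#' `lambda(t; theta) = theta1 + theta2 t + theta3 (t - t_md)^2` over the
#' window `(0, T)` hours, with `t_md` solar noon. The intensity must be
#' strictly positive on the whole window; this is validated on a fine grid at
#' construction.
#'
#' @param theta numeric length-3 vector `(theta1, theta2, theta3)`.
#' @param t_md solar noon, hours (default 6).
#' @param T_h window length, hours (default 12).
#' @return object of class `model1_params`.
#' @export
model1_params <- function(theta, t_md = 6, T_h = 12) {
  theta <- as.numeric(theta)
  if (length(theta) != 3L) stop("theta must have length 3")
  tg <- seq(0, T_h, by = 0.01)
  lam <- theta[1L] + theta[2L] * tg + theta[3L] * (tg - t_md)^2
  if (any(lam <= 0))
    stop("intensity is not strictly positive on [0, T] for these parameters")
  structure(list(theta = theta, t_md = t_md, T_h = T_h),
            class = "model1_params")
}

#' Intensity of the single-patch model
#' @param params a [model1_params()].
#' @param t time(s) in hours, in \[0, T\].
#' @return rate(s), per hour.
#' @export
intensity <- function(params, t) {
  stopifnot(inherits(params, "model1_params"))
  if (any(t < 0 | t > params$T_h)) stop("t outside [0, T]")
  params$theta[1L] + params$theta[2L] * t +
    params$theta[3L] * (t - params$t_md)^2
}

#' Integrated intensity of the single-patch model
#'
#' Closed-form cubic: `Lambda(t) = th1 t + th2 t^2/2 +
#' th3 ((t - t_md)^3 + t_md^3)/3`, with `Lambda(0) = 0`.
#'
#' @inheritParams intensity
#' @return Lambda(t), dimensionless.
#' @export
integrated_intensity <- function(params, t) {
  stopifnot(inherits(params, "model1_params"))
  if (any(t < 0 | t > params$T_h)) stop("t outside [0, T]")
  th <- params$theta
  .cum_eval(th[1L], th[2L] / 2, th[3L] / 3, params$t_md, t)
}

#' Log-likelihood of event times under the single-patch model
#'
#' `l(theta) = -Lambda(T) + sum_i log lambda(v_i)` per realization; a list of
#' event vectors is treated as independent realizations pooled by summing
#' (so the survival term enters once per realization).
#'
#' @param params a [model1_params()].
#' @param events sorted event times in (0, T), or a list of such vectors.
#' @return log-likelihood (scalar).
#' @export
loglik_model1 <- function(params, events) {
  stopifnot(inherits(params, "model1_params"))
  if (!is.list(events)) events <- list(events)
  all_ev <- unlist(events)
  if (length(all_ev) > 0L) {
    if (any(all_ev <= 0 | all_ev >= params$T_h))
      stop("events must lie strictly inside (0, T)")
    if (any(vapply(events, is.unsorted, logical(1))))
      stop("events must be sorted")
  }
  -length(events) * integrated_intensity(params, params$T_h) +
    sum(log(intensity(params, all_ev)))
}

# penalized objective used by the optimizer: soft positivity penalty keeps
# the feasible region open while preserving concavity inside it
.m1_objective <- function(theta, events, t_md, T_h, grid) {
  lam <- theta[1L] + theta[2L] * grid + theta[3L] * (grid - t_md)^2
  if (any(lam <= 0)) return(-1e10 * (1 + abs(min(lam))))
  p <- structure(list(theta = theta, t_md = t_md, T_h = T_h),
                 class = "model1_params")
  loglik_model1(p, events)
}

#' Maximum-likelihood fit of the single-patch model
#'
#' Maximizes the log-likelihood by Nelder-Mead with a soft penalty enforcing
#' strict positivity of the intensity on `[0, T]`. Multiple realizations
#' (list input) are pooled. Deterministic given `init` and `seed` (restarts
#' perturb the initial simplex reproducibly).
#'
#' @param events event vector or list of event vectors (realizations).
#' @param init optional [model1_params()] or length-3 numeric start; default
#'   is the constant-rate MLE `n / (R T)`.
#' @param t_md,T_h window geometry, hours.
#' @param restarts extra random restarts (default 3).
#' @param seed seed for restart perturbations.
#' @param control passed to [stats::optim()]; sensible defaults set.
#' @return list of class `model1_fit`: `params`, `loglik`, `convergence`
#'   (0 = converged), `n_events`, `n_realizations`.
#' @export
fit_model1 <- function(events, init = NULL, t_md = 6, T_h = 12,
                       restarts = 3L, seed = 1L, control = list()) {
  if (!is.list(events)) events <- list(events)
  n <- length(unlist(events))
  if (n < 1L) stop("need at least one event to fit")
  if (is.null(init)) init <- c(n / (length(events) * T_h), 0, 0)
  if (inherits(init, "model1_params")) init <- init$theta
  control <- utils::modifyList(list(maxit = 5000L, reltol = 1e-10,
                                    fnscale = -1), control)
  grid <- seq(0, T_h, by = 0.01)

  set.seed(seed)
  starts <- c(list(init), lapply(seq_len(restarts), function(i)
    init * runif(3L, 0.5, 1.5) + c(0.1, 0, 0)))
  best <- NULL
  for (s in starts) {
    fit <- optim(s, .m1_objective, events = events, t_md = t_md, T_h = T_h,
                 grid = grid, method = "Nelder-Mead", control = control)
    if (is.null(best) || fit$value > best$value) best <- fit
  }
  if (best$value <= -1e9)
    stop("optimizer failed to find a feasible intensity")
  structure(list(params = model1_params(best$par, t_md = t_md, T_h = T_h),
                 loglik = best$value, convergence = best$convergence,
                 n_events = n, n_realizations = length(events)),
            class = "model1_fit")
}

#' @export
print.model1_fit <- function(x, ...) {
  th <- x$params$theta
  cat(sprintf(
    "model1_fit: lambda(t) = %.4g + %.4g t + %.4g (t - %g)^2\n",
    th[1L], th[2L], th[3L], x$params$t_md))
  cat(sprintf("  loglik %.4f over %d events (%d realizations); %s\n",
              x$loglik, x$n_events, x$n_realizations,
              if (x$convergence == 0) "converged" else
                paste("optim code", x$convergence)))
  invisible(x)
}

#' Simulate event times from the single-patch model
#'
#' Inversion method: each waiting time solves
#' `Lambda(v + s) - Lambda(v) = -log(1 - U)` for uniform `U`; the cumulative
#' intensity is cubic and monotone, solved by bisection. Simulation stops at
#' the first waiting time extending beyond `T`.
#'
#' @param params a [model1_params()].
#' @param seed RNG seed; identical seeds give identical realizations.
#' @param n number of independent realizations.
#' @return numeric vector of event times (n = 1) or a list of vectors.
#' @export
simulate_model1 <- function(params, seed = 1L, n = 1L) {
  stopifnot(inherits(params, "model1_params"))
  th <- params$theta
  A <- th[1L]; B <- th[2L] / 2; C <- th[3L] / 3
  tmd <- params$t_md; T_h <- params$T_h
  set.seed(seed)

  v <- numeric(n)           # current time per realization
  active <- rep(TRUE, n)
  out <- vector("list", n)
  while (any(active)) {
    idx <- which(active)
    E <- rexp(length(idx))
    u <- .cum_solve(A, B, C, tmd, v[idx], E, T_h)
    done <- is.na(u)
    active[idx[done]] <- FALSE
    hit <- idx[!done]
    for (k in seq_along(hit))
      out[[hit[k]]] <- c(out[[hit[k]]], u[!done][k])
    v[hit] <- u[!done]
  }
  out <- lapply(out, function(x) if (is.null(x)) numeric(0) else x)
  if (n == 1L) out[[1L]] else out
}
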