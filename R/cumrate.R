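# Cumulative-rate helpers shared by both switching models.
#
# Every intensity used in the package is of the quadratic family
#   lambda(t) = A' + 2 B t + 3 C (t - t_md)^2-ish; concretely we work with
# the cumulative form
#   Lambda(t) = A t + B t^2 + C ((t - t_md)^3 + t_md^3),
# which is 0 at t = 0, cubic, and (for valid parameters) non-decreasing on
# [0, T]. The single-patch model uses (A, B, C) = (th1, th2/2, th3/3); the
# height-dependent two-state model uses (A, B, C) = (c b1, 0, c b2 / 3) with
# c = 1 - a h.

.cum_eval <- function(A, B, C, tmd, t) {
  A * t + B * t^2 + C * ((t - tmd)^3 + tmd^3)
}

# Solve Lambda(u) - Lambda(v) = E for u in (v, T], vectorized over draws.
# Lambda is monotone for valid parameters, so plain bisection is exact
# enough; entries with insufficient cumulative rate left before T return NA
# (no further event in the window).
.cum_solve <- function(A, B, C, tmd, v, E, T_h, iters = 60L) {
  target <- .cum_eval(A, B, C, tmd, v) + E
  no_event <- .cum_eval(A, B, C, tmd, T_h) < target
  lo <- v
  hi <- rep_len(T_h, length(v))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    below <- .cum_eval(A, B, C, tmd, mid) < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  u <- (lo + hi) / 2
  u[no_event] <- NA_real_
  u
}
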