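#' Light-response parameters (non-rectangular hyperbola)
#'
#' The photosynthetic light response is modelled by the non-rectangular
#' hyperbola: the assimilation rate `P(I)` is the lower root of
#' `theta P^2 - (phi I + Pmax) P + phi I Pmax = 0`. `phi` is the apparent
#' quantum yield (initial slope, mol CO2 per mol photons), `theta_cvx` the
#' convexity in (0, 1\], and `p_max` the light-saturated rate. The defaults
#' `phi = 0.062` and `theta_cvx = 0.83` are typical field-measured values
#' for wheat flag leaves and are exposed as configuration, not constants of
#' the model.
#'
#' @param p_max light-saturated assimilation, umol CO2 m-2 s-1.
#' @param phi quantum yield (> 0).
#' @param theta_cvx convexity, in (0, 1].
#' @param layer optional layer tag (`"top"`, `"middle"`, `"bottom"`).
#' @return object of class `light_response`.
#' @export
light_response <- function(p_max, phi = 0.062, theta_cvx = 0.83,
                           layer = NA_character_) {
  if (phi <= 0) stop("phi must be positive")
  if (theta_cvx <= 0 || theta_cvx > 1) stop("theta_cvx must be in (0, 1]")
  if (p_max <= 0) stop("p_max must be positive")
  structure(list(phi = phi, theta_cvx = theta_cvx, p_max = p_max,
                 layer = layer),
            class = "light_response")
}

#' Canopy-layer light responses
#'
#' Per-layer maximum photosynthetic capacities measured in a wheat canopy:
#' 28.6 (top), 12.6 (middle) and 4.7 (bottom) umol m-2 s-1.
#'
#' @param phi,theta_cvx shared shape parameters (see [light_response()]).
#' @return named list of [light_response()]s (`top`, `middle`, `bottom`).
#' @export
layer_responses <- function(phi = 0.062, theta_cvx = 0.83) {
  list(top = light_response(28.6, phi, theta_cvx, "top"),
       middle = light_response(12.6, phi, theta_cvx, "middle"),
       bottom = light_response(4.7, phi, theta_cvx, "bottom"))
}

#' Non-rectangular hyperbola assimilation
#'
#' Lower root of the NRH quadratic; continuous and non-decreasing in the
#' irradiance `I`, never exceeding `p_max`. As `theta_cvx -> 0` it tends to
#' the rectangular hyperbola `phi I Pmax / (phi I + Pmax)`; at
#' `theta_cvx = 1` it equals `min(phi I, Pmax)`.
#'
#' @param response a [light_response()].
#' @param I irradiance(s), umol photons m-2 s-1 (>= 0).
#' @param phi_scale,theta_scale multiplicative photoinhibition scalings
#'   applied to `phi` / `theta_cvx` (default 1 = uninhibited).
#' @return assimilation rate(s), umol CO2 m-2 s-1.
#' @export
nrh_assimilation <- function(response, I, phi_scale = 1, theta_scale = 1) {
  stopifnot(inherits(response, "light_response"))
  if (any(I < 0)) stop("irradiance must be non-negative")
  phi <- response$phi * phi_scale
  th <- response$theta_cvx * theta_scale
  pm <- response$p_max
  s <- phi * I + pm
  if (th < 1e-8)                       # rectangular-hyperbola limit
    return(phi * I * pm / pmax(s, .Machine$double.eps))
  disc <- pmax(s^2 - 4 * th * phi * I * pm, 0)
  (s - sqrt(disc)) / (2 * th)
}

#' Per-patch diffuse-light scaling factors
#'
#' Diffuse light on every patch shares the diurnal shape of the horizontal
#' diffuse profile; each patch only scales its amplitude. The scaling is the
#' least-squares scalar `s_j = sum(trace_j * profile) / sum(profile^2)`,
#' clamped to \[0, 1\], and a mean-scaling curve versus normalized height is
#' built over 100 equal bins and interpolated piecewise-linearly between bin
#' midpoints.
#'
#' @param traces matrix of per-patch diffuse traces (patches x times).
#' @param profile reference diffuse profile on the same grid (not all zero).
#' @param h normalized heights of the patches.
#' @param n_bins number of height bins for the mean curve.
#' @return list of class `diffuse_scaling`: `s` (per patch), `curve`
#'   (data frame `h_mid`, `s_mean`), `fn` (function of `h`).
#' @export
fit_diffuse_scaling <- function(traces, profile, h, n_bins = 100L) {
  traces <- as.matrix(traces)
  if (ncol(traces) != length(profile))
    stop("traces and profile must share the time grid")
  ss <- sum(profile^2)
  if (ss == 0) stop("reference profile is identically zero")
  s <- pmin(1, pmax(0, as.vector(traces %*% profile) / ss))
  bin <- pmin(n_bins, floor(h * n_bins) + 1L)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  means <- tapply(s, factor(bin, levels = seq_len(n_bins)), mean)
  keep <- !is.na(means)
  fn <- if (sum(keep) < 2L) {
    v <- as.numeric(means[keep][1L])
    function(x) rep(v, length(x))
  } else {
    approxfun(mids[keep], means[keep], rule = 2)
  }
  structure(list(s = s,
                 curve = data.frame(h_mid = mids[keep],
                                    s_mean = as.numeric(means[keep])),
                 fn = fn),
            class = "diffuse_scaling")
}

#' Daily carbon gain of a patch
#'
#' Trapezoidal time integral over the window of the assimilation of total
#' irradiance `direct * sunlit-indicator + diffuse`. When a list of records
#' is given the gains of the realizations are averaged (the assimilation is
#' nonlinear, so gains, not light, are averaged).
#'
#' @param record a [switch_record()] or list of them (realizations).
#' @param envelope an `envelope_trace` (or list with `t_min`, `values`).
#' @param diffuse diffuse trace on the same grid (numeric; 0 allowed).
#' @param response a [light_response()].
#' @param phi_scale,theta_scale photoinhibition scalings (see
#'   [nrh_assimilation()]).
#' @return daily gain, umol CO2 m-2.
#' @export
daily_carbon_gain <- function(record, envelope, diffuse, response,
                              phi_scale = 1, theta_scale = 1) {
  if (inherits(record, "switch_record")) record <- list(record)
  if (length(diffuse) == 1L) diffuse <- rep(diffuse, length(envelope$t_min))
  gains <- vapply(record, function(r) {
    sun <- reconstruct_pattern(r, envelope$t_min)
    I <- envelope$values * as.numeric(sun) + diffuse
    P <- nrh_assimilation(response, I, phi_scale, theta_scale)
    # trapezoid over the grid plus the final step out to the window end T
    # (the grid runs 0 .. T - dt)
    dt_s <- diff(envelope$t_min[1:2]) * 60
    .trapz(envelope$t_min * 60, P) + P[length(P)] * dt_s
  }, numeric(1))
  mean(gains)
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Assign canopy layers by normalized height
#'
#' Equal thirds: `top` for `h > 2/3`, `middle` for `1/3 < h <= 2/3`,
#' `bottom` for `h <= 1/3`.
#'
#' @param h normalized heights.
#' @return factor with levels `top`, `middle`, `bottom`.
#' @export
assign_layers <- function(h) {
  factor(ifelse(h > 2 / 3, "top", ifelse(h > 1 / 3, "middle", "bottom")),
         levels = c("top", "middle", "bottom"))
}

#' Photoinhibition scenarios: per-layer reduction in daily carbon gain
#'
#' Photoinhibition is modelled as a multiplicative scaling of the
#' light-response shape parameters in each canopy layer (midday measurements
#' give 0.857 for the top layer, 0.955 for the middle, 1.0 for the bottom).
#' Three scenarios scale the quantum yield `phi`, the convexity `theta`, or
#' both. For each patch the daily gain is computed with and without the
#' scaling and the reduction is `1 - gain_inhibited / gain_control`,
#' aggregated per layer and in total.
#'
#' @param records list (one element per patch) of [switch_record()]s or
#'   lists of records (realizations, averaged).
#' @param envelopes list of `envelope_trace`s, one per patch.
#' @param diffuse list (or matrix rows) of per-patch diffuse traces.
#' @param h normalized heights, one per patch.
#' @param responses per-layer responses, as from [layer_responses()].
#' @param scalings named numeric, layer scaling factors.
#' @param scenario `"phi"`, `"theta"`, or `"both"`.
#' @return list: `per_layer` data frame (`layer`, `control`, `inhibited`,
#'   `reduction_pct`), `total_reduction_pct`, `gains_control` (per patch),
#'   `gains_inhibited`, `scenario`.
#' @export
photoinhibition_scenarios <- function(records, envelopes, diffuse, h,
                                      responses = layer_responses(),
                                      scalings = c(top = 0.857,
                                                   middle = 0.955,
                                                   bottom = 1.0),
                                      scenario = c("both", "phi", "theta")) {
  scenario <- match.arg(scenario)
  layers <- assign_layers(h)
  np <- length(h)
  g0 <- numeric(np)
  g1 <- numeric(np)
  for (j in seq_len(np)) {
    lay <- as.character(layers[j])
    resp <- responses[[lay]]
    sc <- scalings[[lay]]
    ps <- if (scenario %in% c("phi", "both")) sc else 1
    ts <- if (scenario %in% c("theta", "both")) sc else 1
    dif <- if (is.matrix(diffuse)) diffuse[j, ] else diffuse[[j]]
    g0[j] <- daily_carbon_gain(records[[j]], envelopes[[j]], dif, resp)
    g1[j] <- daily_carbon_gain(records[[j]], envelopes[[j]], dif, resp,
                               phi_scale = ps, theta_scale = ts)
  }
  agg <- function(sel) {
    c0 <- sum(g0[sel]); c1 <- sum(g1[sel])
    c(control = c0, inhibited = c1,
      reduction_pct = if (c0 > 0) 100 * (1 - c1 / c0) else 0)
  }
  per <- t(vapply(levels(layers), function(l) agg(layers == l), numeric(3)))
  per_layer <- data.frame(layer = rownames(per), per, row.names = NULL)
  tot <- agg(rep(TRUE, np))
  list(per_layer = per_layer,
       total_reduction_pct = unname(tot["reduction_pct"]),
       gains_control = g0, gains_inhibited = g1, scenario = scenario)
}
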