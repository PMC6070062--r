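#' Solar and clear-sky configuration
#'
#' Bundles the geographic and atmospheric settings that determine solar
#' position and the clear-sky direct-beam envelope. Time is solar time in
#' hours over the analysis window `(0, T)`; `t = t_md` is solar noon, so with
#' the defaults (`T = 12`, `t_md = 6`) the window runs from 0600 h to 1800 h.
#' The defaults correspond to latitude 53 deg, day 182 (1 July) and
#' atmospheric transmittance 0.5. `solar_constant` is the extraterrestrial
#' beam in PPFD units; the default 4600 umol m-2 s-1 is chosen so that the
#' noon envelope on a horizontal surface is ~1800 umol m-2 s-1 under the
#' default settings. It cancels in the (relative) sunlit-shaded
#' classification.
#'
#' @param latitude degrees, in (-90, 90).
#' @param day_of_year integer in 1..365.
#' @param transmittance atmospheric transmittance, in (0, 1].
#' @param solar_constant extraterrestrial beam PPFD, umol m-2 s-1.
#' @param T_h window length in hours.
#' @param t_md_h solar noon, hours after window start.
#' @param dt_min grid step, minutes; must divide `T_h * 60` evenly.
#' @return an object of class `solar_config`, including the time grid
#'   `t_grid_min` (minutes, `0, dt, ..., T*60 - dt`).
#' @export
solar_config <- function(latitude = 53, day_of_year = 182,
                         transmittance = 0.5, solar_constant = 4600,
                         T_h = 12, t_md_h = 6, dt_min = 1) {
  if (abs(latitude) >= 90) stop("latitude must be strictly between -90 and 90")
  if (day_of_year < 1 || day_of_year > 365) stop("day_of_year must be 1..365")
  if (transmittance <= 0 || transmittance > 1)
    stop("transmittance must be in (0, 1]")
  if (solar_constant <= 0) stop("solar_constant must be positive")
  if ((T_h * 60) %% dt_min != 0) stop("dt_min must divide T_h * 60 evenly")
  structure(list(latitude = latitude, day_of_year = day_of_year,
                 transmittance = transmittance,
                 solar_constant = solar_constant,
                 T_h = T_h, t_md_h = t_md_h, dt_min = dt_min,
                 t_grid_min = seq(0, T_h * 60 - dt_min, by = dt_min)),
            class = "solar_config")
}

# solar declination, degrees
.declination <- function(day_of_year) {
  23.45 * sin(2 * pi * (284 + day_of_year) / 365)
}

#' Sine of solar elevation
#' @param config a [solar_config()].
#' @param t_h time(s), hours after window start.
#' @return numeric vector of sin(elevation); negative when the sun is below
#'   the horizon.
#' @export
solar_elevation_sin <- function(config, t_h) {
  d2r <- pi / 180
  phi <- config$latitude * d2r
  delta <- .declination(config$day_of_year) * d2r
  H <- 15 * (t_h - config$t_md_h) * d2r     # hour angle
  sin(phi) * sin(delta) + cos(phi) * cos(delta) * cos(H)
}

#' Unit direction toward the sun
#'
#' Coordinates are (east, north, up); derived from the standard
#' declination / hour-angle geometry.
#'
#' @param config a [solar_config()].
#' @param t_h time(s), hours after window start.
#' @return matrix with one row per time, columns (x = east, y = north,
#'   z = up); unit rows.
#' @export
solar_direction <- function(config, t_h) {
  d2r <- pi / 180
  phi <- config$latitude * d2r
  delta <- .declination(config$day_of_year) * d2r
  H <- 15 * (t_h - config$t_md_h) * d2r
  sa <- solar_elevation_sin(config, t_h)
  dir <- cbind(-cos(delta) * sin(H),
               (sin(delta) - sa * sin(phi)) / cos(phi),
               sa)
  dir / sqrt(rowSums(dir^2))
}

#' Clear-sky direct-beam envelope on an oriented patch
#'
#' The irradiance a patch would receive from the direct beam with no shading:
#' `A_dr(t) = S0 * tau^m * |cos(incidence)|`, with optical air mass
#' `m = 1 / sin(elevation)` and the incidence cosine taken as an absolute
#' value (leaves are two-sided). Zero whenever the sun is below the horizon.
#'
#' @param config a [solar_config()].
#' @param patch_normal unit 3-vector (east, north, up).
#' @param t_h time(s) in hours; defaults to the config grid.
#' @return envelope values, umol m-2 s-1.
#' @export
direct_envelope <- function(config, patch_normal = c(0, 0, 1),
                            t_h = config$t_grid_min / 60) {
  patch_normal <- patch_normal / sqrt(sum(patch_normal^2))
  sa <- solar_elevation_sin(config, t_h)
  up <- sa > 1e-9
  out <- numeric(length(t_h))
  if (any(up)) {
    dir <- solar_direction(config, t_h[up])
    beam <- config$solar_constant * config$transmittance^(1 / sa[up])
    out[up] <- beam * abs(drop(dir %*% patch_normal))
  }
  out
}

# direct-beam magnitude S0 * tau^m at each time (0 at night), plus sun
# directions; shared by trace_canopy
.beam_and_dirs <- function(config, t_h) {
  sa <- solar_elevation_sin(config, t_h)
  up <- sa > 1e-9
  beam <- numeric(length(t_h))
  beam[up] <- config$solar_constant * config$transmittance^(1 / sa[up])
  dirs <- matrix(0, length(t_h), 3L)
  if (any(up)) dirs[up, ] <- solar_direction(config, t_h[up])
  list(beam = beam, dirs = dirs, up = up)
}

#' Diurnal diffuse-light profile on a horizontal surface
#'
#' Simple isotropic clear-sky partition: the diffuse flux is a fixed fraction
#' (0.3) of the radiation removed from the beam by the atmosphere,
#' `0.3 * S0 * (1 - tau^m) * sin(elevation)`. Symmetric about solar noon,
#' zero at night, and decreasing in `transmittance` (clearer skies scatter
#' less).
#'
#' @inheritParams direct_envelope
#' @return diffuse PPFD, umol m-2 s-1.
#' @export
diffuse_profile <- function(config, t_h = config$t_grid_min / 60) {
  sa <- solar_elevation_sin(config, t_h)
  up <- sa > 1e-9
  out <- numeric(length(t_h))
  out[up] <- 0.3 * config$solar_constant *
    (1 - config$transmittance^(1 / sa[up])) * sa[up]
  out
}

#' Envelope trace for one patch
#' @param config a [solar_config()].
#' @param patch_normal unit 3-vector.
#' @param patch_id identifier carried through.
#' @return object of class `envelope_trace`: list with `patch_id`,
#'   `t_min` and `values`.
#' @export
envelope_trace <- function(config, patch_normal = c(0, 0, 1), patch_id = 1L) {
  structure(list(patch_id = patch_id, t_min = config$t_grid_min,
                 values = direct_envelope(config, patch_normal)),
            class = "envelope_trace")
}
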