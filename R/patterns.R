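#' Classify a light trace into sunlit and shaded states
#'
#' A patch is sunlit at a grid time when the traced direct flux is within
#' `threshold` (relative) of the clear-sky envelope on that patch, i.e.
#' `|flux - A_dr| <= threshold * A_dr`; otherwise shaded. Times at which the
#' envelope is below `daylight_cutoff` (pre-sunrise / post-sunset within the
#' window) are excluded from the analysis (state `NA`) since the relative
#' comparison is undefined as `A_dr -> 0`.
#'
#' @param trace a `light_trace` (from [light_trace()]) or numeric flux vector.
#' @param envelope an `envelope_trace` or numeric vector on the same grid;
#'   defaults to the envelope carried by the trace.
#' @param threshold relative tolerance for "sunlit" (default 0.10).
#' @param daylight_cutoff minimum envelope, umol m-2 s-1.
#' @return object of class `binary_pattern`: list with `patch_id`, `t_min`,
#'   `state` (logical, `TRUE` = sunlit, `NA` outside daylight), `T_h`, `h`.
#' @export
classify_sunlit <- function(trace, envelope = NULL, threshold = 0.10,
                            daylight_cutoff = 1) {
  if (inherits(trace, "light_trace")) {
    flux <- trace$flux
    t_min <- trace$t_min
    patch_id <- trace$patch_id
    h <- trace$h
    if (is.null(envelope)) envelope <- trace$envelope
  } else {
    flux <- as.numeric(trace)
    t_min <- seq_along(flux) - 1
    patch_id <- NA_integer_
    h <- NA_real_
  }
  env <- if (inherits(envelope, "envelope_trace")) {
    if (length(envelope$values) != length(flux) ||
        !isTRUE(all.equal(envelope$t_min, t_min)))
      stop("trace and envelope grids do not match")
    envelope$values
  } else {
    if (length(envelope) != length(flux))
      stop("trace and envelope grids do not match")
    as.numeric(envelope)
  }
  state <- abs(flux - env) <= threshold * env
  low <- env < daylight_cutoff
  state[low] <- NA
  # interior low-envelope times (sun grazing the leaf plane) are
  # unobservable for the relative classification; carry the last observed
  # state forward. Leading/trailing runs (outside daylight) stay NA and are
  # excluded from the analysis window.
  obs <- which(!low)
  if (length(obs) > 0L && any(low)) {
    inner <- seq(min(obs), max(obs))
    nas <- inner[low[inner]]
    if (length(nas) > 0L) {
      idx <- findInterval(nas, obs)
      state[nas] <- state[obs[idx]]
    }
  }
  T_h <- (max(t_min) + diff(t_min[1:2])) / 60
  structure(list(patch_id = patch_id, t_min = t_min, state = state,
                 T_h = T_h, h = h),
            class = "binary_pattern")
}

#' Switching record of a sunlit-shaded pattern
#'
#' A patch's day is characterized by the ordered alternating times of
#' on-switches (shaded to sunlit), `x`, and off-switches (sunlit to shaded),
#' `y`, over the window `(0, T)` in hours. Boundary states are encoded by
#' sentinels whose magnitudes are irrelevant: `x[1] < 0` means the patch was
#' already sunlit at `t = 0`, and `y[n] > T` means it was still sunlit at
#' `t = T`; all other times lie strictly inside `(0, T)` and alternate as
#' `x1 < y1 < x2 < ... < xn < yn`. A patch shaded all day with no switches
#' has `n = 0`.
#'
#' @param x on-switch times, hours (`-1` sentinel allowed in position 1).
#' @param y off-switch times, hours (`T + 1` sentinel allowed in position n).
#' @param T_h window length, hours.
#' @param h normalized height of the patch, in \[0, 1\].
#' @param patch_id identifier.
#' @return object of class `switch_record`.
#' @export
switch_record <- function(x, y, T_h = 12, h = NA_real_, patch_id = NA_integer_) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n > 0L) {
    if (is.unsorted(as.vector(rbind(x, y)), strictly = TRUE))
      stop("switch times must strictly alternate: x1 < y1 < x2 < ...")
    if (any(x[-1L] <= 0) || any(x > T_h))
      stop("interior on-times must lie in (0, T)")
    if (any(y[-n] >= T_h) || any(y <= 0))
      stop("interior off-times must lie in (0, T)")
  }
  structure(list(patch_id = patch_id, h = h, x = x, y = y, T_h = T_h),
            class = "switch_record")
}

#' @export
print.switch_record <- function(x, ...) {
  n <- length(x$x)
  cat(sprintf("switch_record patch %s (h = %.3f): %d on/off pairs%s%s\n",
              x$patch_id, x$h, n,
              if (n > 0L && x$x[1L] < 0) ", sunlit at t=0" else "",
              if (n > 0L && x$y[n] > x$T_h) ", sunlit at t=T" else ""))
  invisible(x)
}

#' Extract the switching record from a binary pattern
#'
#' Switch times are placed at the grid point where the new state is first
#' observed, so that [reconstruct_pattern()] round-trips exactly at grid
#' resolution. Grid points with `NA` state (outside daylight) are trimmed
#' from the ends of the window.
#'
#' @param pattern a `binary_pattern` from [classify_sunlit()].
#' @param h normalized height of the patch; defaults to the one carried by
#'   the pattern.
#' @return a [switch_record()].
#' @export
extract_switches <- function(pattern, h = pattern$h) {
  stopifnot(inherits(pattern, "binary_pattern"))
  ok <- !is.na(pattern$state)
  if (!any(ok)) stop("pattern has no daylight time points")
  idx <- range(which(ok))
  if (any(is.na(pattern$state[idx[1L]:idx[2L]])))
    stop("NA states inside the daylight window are not supported")
  st <- pattern$state[idx[1L]:idx[2L]]
  t_h <- pattern$t_min[idx[1L]:idx[2L]] / 60
  T_h <- pattern$T_h

  chg <- which(st[-1L] != st[-length(st)]) + 1L   # first index of new state
  times <- t_h[chg]
  to_sun <- st[chg]
  x <- times[to_sun]
  y <- times[!to_sun]
  if (st[1L]) x <- c(-1, x)                        # sunlit at window start
  if (st[length(st)]) y <- c(y, T_h + 1)           # sunlit at window end
  switch_record(x, y, T_h = T_h, h = h, patch_id = pattern$patch_id)
}

#' Reconstruct the binary state at grid times from a switching record
#'
#' @param record a [switch_record()].
#' @param t_min grid times in minutes.
#' @return logical vector, `TRUE` = sunlit.
#' @export
reconstruct_pattern <- function(record, t_min) {
  t_h <- t_min / 60
  iv <- record_intervals(record)
  state <- logical(length(t_h))
  for (i in seq_len(nrow(iv))) {
    sel <- t_h >= iv$t0[i] - 1e-12 & t_h < iv$t1[i] - 1e-12
    state[sel] <- iv$state[i] == "sun"
  }
  # the last grid point belongs to the final interval
  state[t_h >= iv$t1[nrow(iv)] - 1e-12] <- iv$state[nrow(iv)] == "sun"
  state
}

#' Decompose a switching record into state intervals
#'
#' Walks the alternating event times and returns the exposure intervals the
#' likelihood bookkeeping is built on: each row is a maximal interval during
#' which the patch stayed in one state; `ended` flags intervals terminated by
#' an interior switch (which contribute a log-rate term) as opposed to the
#' end of the window (censored; survival term only).
#'
#' @param record a [switch_record()].
#' @return data frame with columns `state` ("sun"/"shade"), `t0`, `t1`,
#'   `ended` (logical).
#' @export
record_intervals <- function(record) {
  stopifnot(inherits(record, "switch_record"))
  T_h <- record$T_h
  n <- length(record$x)
  init_sun <- n > 0L && record$x[1L] < 0
  ev <- c(record$x[record$x > 0], record$y[record$y <= T_h])
  type <- c(rep(TRUE, sum(record$x > 0)), rep(FALSE, sum(record$y <= T_h)))
  o <- order(ev)
  ev <- ev[o]; type <- type[o]                 # TRUE = on-switch
  # alternation sanity: each event must flip the current state
  state <- init_sun
  for (k in seq_along(ev)) {
    if (type[k] == state)
      stop("malformed alternation in record for patch ", record$patch_id)
    state <- type[k]
  }
  t0 <- c(0, ev)
  t1 <- c(ev, T_h)
  states <- rep(c(init_sun, !init_sun), length.out = length(t0))
  data.frame(state = ifelse(states, "sun", "shade"), t0 = t0, t1 = t1,
             ended = c(rep(TRUE, length(ev)), FALSE))
}

#' Pooled interval table for a list of records
#' @param records list of [switch_record()]s.
#' @return data frame of intervals with the patch height `h` attached.
#' @export
interval_table <- function(records) {
  if (inherits(records, "switch_record")) records <- list(records)
  do.call(rbind, lapply(records, function(r) {
    iv <- record_intervals(r)
    iv$h <- r$h
    iv$patch_id <- r$patch_id
    iv
  }))
}

#' Durations of completed sunlit and shaded periods
#'
#' Periods censored by the window boundary (before the first switch or after
#' the last) are excluded; only fully observed periods contribute.
#'
#' @param records list of [switch_record()]s.
#' @return list with numeric vectors `sunlit` and `shaded`, durations in
#'   minutes.
#' @export
duration_distributions <- function(records) {
  if (inherits(records, "switch_record")) records <- list(records)
  if (length(records) == 0L) stop("need at least one record")
  sun <- numeric(0)
  sha <- numeric(0)
  for (r in records) {
    n <- length(r$x)
    if (n == 0L) next
    interior_pair <- r$x > 0 & r$y <= r$T_h
    sun <- c(sun, (r$y[interior_pair] - r$x[interior_pair]) * 60)
    if (n > 1L) sha <- c(sha, (r$x[-1L] - r$y[-n]) * 60)
  }
  list(sunlit = sun, shaded = sha)
}

#' Write switching records as CSV
#'
#' Long format with columns `patch_id, h, T_h, kind, time_h`; sentinel rows
#' (negative on-time, off-time beyond `T_h`) encode the censored boundary
#' states.
#'
#' @param records list of [switch_record()]s.
#' @param path output path.
#' @param provenance optional named character vector of `#` header lines.
#' @export
write_switch_records <- function(records, path, provenance = NULL) {
  if (inherits(records, "switch_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    n <- length(r$x)
    if (n == 0L)
      return(data.frame(patch_id = r$patch_id, h = r$h, T_h = r$T_h,
                        kind = "none", time_h = NA_real_))
    data.frame(patch_id = r$patch_id, h = r$h, T_h = r$T_h,
               kind = rep(c("on", "off"), each = n),
               time_h = c(r$x, r$y))
  })
  .write_csv_prov(do.call(rbind, rows), path, provenance)
  invisible(path)
}

#' Read switching records written by [write_switch_records()]
#' @param path CSV path.
#' @return list of [switch_record()]s.
#' @export
read_switch_records <- function(path) {
  df <- read.csv(path, comment.char = "#")
  lapply(split(df, df$patch_id), function(d) {
    if (identical(d$kind[1L], "none"))
      return(switch_record(numeric(0), numeric(0), T_h = d$T_h[1L],
                           h = d$h[1L], patch_id = d$patch_id[1L]))
    switch_record(sort(d$time_h[d$kind == "on"]),
                  sort(d$time_h[d$kind == "off"]),
                  T_h = d$T_h[1L], h = d$h[1L], patch_id = d$patch_id[1L])
  })
}
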