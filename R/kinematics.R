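## Traveling-wave kinematics: excursion field, steady-state admissibility,
## and estimators for speed, frequency, amplitude, wavelength, wave speed.

#' Lateral-excursion field of a tracked sequence
#'
#' Transforms a `midline_sequence` into the swim-direction frame: the
#' heading is the principal axis of the body-centroid track (signed so that
#' net travel is positive), and h(s_i, t_j) is the signed perpendicular
#' distance of midline point i from the heading line through the mean
#' centroid, in body lengths. Image-convention (row-down) input is converted
#' to a right-handed frame internally so that positive h is to the
#' swimmer's left.
#'
#' @param seq a `midline_sequence` (tracked or generated).
#' @param min_travel_bl minimum net centroid travel, in BL, below which
#'   there is no meaningful heading.
#' @return object of class `excursion_field`: list with `h` (n_points x
#'   n_frames, BL), `s`, `time_s`, `frame_rate_hz`, `heading` (unit vector),
#'   `com_track` (n_frames x 2, components along heading and normal, BL),
#'   and `scale`.
#' @export
body_frame <- function(seq, min_travel_bl = 0.1) {
  stopifnot(inherits(seq, "midline_sequence"))
  xy <- seq$xy
  if (isTRUE(seq$y_down)) xy[, 2, ] <- -xy[, 2, ]
  n_frames <- dim(xy)[3]
  if (n_frames < 2) stop("insufficient cycles: need more than one frame")
  cent <- t(apply(xy, 3, colMeans))
  net <- cent[n_frames, ] - cent[1, ]
  if (sqrt(sum(net^2)) < min_travel_bl * seq$scale)
    stop("no net travel: centroid track shorter than ", min_travel_bl, " BL")
  pc <- prcomp(cent)
  e <- pc$rotation[, 1]
  if (sum(e * net) < 0) e <- -e
  nv <- c(-e[2], e[1])
  cbar <- colMeans(cent)
  h <- (xy[, 1, ] - cbar[1]) * nv[1] + (xy[, 2, ] - cbar[2]) * nv[2]
  h <- matrix(h, dim(xy)[1], n_frames) / seq$scale
  com <- cbind(along = ((cent[, 1] - cbar[1]) * e[1] +
                        (cent[, 2] - cbar[2]) * e[2]),
               perp  = ((cent[, 1] - cbar[1]) * nv[1] +
                        (cent[, 2] - cbar[2]) * nv[2])) / seq$scale
  structure(list(h = h, s = seq$s, time_s = seq$time_s,
                 frame_rate_hz = seq$frame_rate_hz, heading = e,
                 com_track = com, scale = seq$scale),
            class = "excursion_field")
}

## excursion time series at an arbitrary arc station, by linear
## interpolation between the two bracketing resampled points
station_series <- function(field, station) {
  s <- field$s
  if (station <= s[1]) return(field$h[1, ])
  if (station >= s[length(s)]) return(field$h[length(s), ])
  i <- findInterval(station, s)
  w <- (station - s[i]) / (s[i + 1] - s[i])
  (1 - w) * field$h[i, ] + w * field$h[i + 1, ]
}

## linearly interpolated zero-crossing times of one sign (+1 upward), with
## Schmitt-trigger hysteresis: a crossing counts only when the signal swings
## from below -delta to above +delta, so measurement ripple near h = 0 (or
## near extrema of the opposite-sign crossing) cannot create phantom
## crossings. delta is a fraction of the oscillation amplitude.
crossing_times <- function(y, t, direction = 1, hysteresis = 0.2) {
  y <- y * direction
  delta <- hysteresis * as.numeric(stats::quantile(abs(y), 0.9))
  idx <- which(abs(y) > delta)
  if (length(idx) < 2) return(numeric(0))
  sg <- sign(y[idx])
  trans <- which(sg[-length(sg)] < 0 & sg[-1] > 0)
  out <- numeric(0)
  for (k in trans) {
    seg <- idx[k]:(idx[k + 1] - 1)
    j <- seg[y[seg] < 0 & y[seg + 1] >= 0]
    if (length(j) == 0) next
    j <- j[length(j)]
    out <- c(out, t[j] + (t[j + 1] - t[j]) * (-y[j]) / (y[j + 1] - y[j]))
  }
  out
}

## per-cycle peak-to-peak excursion of every station, taken from a
## low-order Fourier reconstruction of the cycle (fundamental plus
## `n_harmonics` overtones): exact for sinusoidal waves, captures
## non-sinusoidal waveforms, and immune to the upward bias that taking raw
## extremes of noisy tracked series incurs
cycle_pp <- function(h, time_s, t0, t1, n_harmonics = 3) {
  jj <- which(time_s >= t0 & time_s < t1)
  y <- h[, jj, drop = FALSE]
  phi <- 2 * pi * (time_s[jj] - t0) / (t1 - t0)
  E <- exp(-1i * outer(phi, seq_len(n_harmonics)))
  C <- (2 / length(jj)) * (y %*% E)
  grid <- seq(0, 2 * pi, length.out = 129)[-129]
  G <- exp(1i * outer(seq_len(n_harmonics), grid))
  r <- Re(C %*% G)
  apply(r, 1, function(z) max(z) - min(z))
}

#' Steady-state admissibility filter
#'
#' Only sequences swum at steady speed are admissible for kinematic
#' averaging. Cycles are delimited by successive upward zero crossings of
#' the tail excursion; the filter passes iff every cycle-averaged centroid
#' speed is within `tol` of the sequence mean speed.
#'
#' @param seq a `midline_sequence`.
#' @param tol allowed fractional deviation of any cycle speed from the mean
#'   (default 0.15).
#' @param station tail arc station used to delimit cycles.
#' @return list with `pass` (logical), `cycle_speeds_bl_s`,
#'   `mean_speed_bl_s`, `n_cycles`.
#' @export
steady_state_filter <- function(seq, tol = 0.15, station = 0.95) {
  field <- body_frame(seq)
  tc <- crossing_times(station_series(field, station), field$time_s)
  if (length(tc) < 3)
    stop("insufficient cycles: need at least 2 full tail-beat cycles")
  along <- field$com_track[, "along"]
  pos_at <- function(t) approx(field$time_s, along, xout = t)$y
  sp <- diff(pos_at(tc)) / diff(tc)
  pass <- all(abs(sp - mean(sp)) <= tol * abs(mean(sp)))
  list(pass = pass, cycle_speeds_bl_s = sp, mean_speed_bl_s = mean(sp),
       n_cycles = length(sp))
}

#' Swimming speed
#'
#' Net centroid displacement along the heading divided by elapsed time, in
#' body lengths per second. Sequences should first pass
#' [steady_state_filter()].
#'
#' @param x a `midline_sequence` or `excursion_field`.
#' @return U in BL/s.
#' @export
estimate_speed <- function(x) {
  field <- if (inherits(x, "excursion_field")) x else body_frame(x)
  along <- field$com_track[, "along"]
  n <- length(along)
  (along[n] - along[1]) / (field$time_s[n] - field$time_s[1])
}

#' Tail-beat frequency
#'
#' Reciprocal of the mean period between successive same-sign zero
#' crossings of the tail excursion h(s = `station`, t), with crossings
#' located by linear interpolation. Periods from upward and downward
#' crossings are pooled; their SD is attached as attribute `"period_sd"`.
#' A zero-crossing estimator is unbiased for near-sinusoids on short clips,
#' where coarse spectral peaks are not.
#'
#' @param field an `excursion_field`.
#' @param station tail arc station (default 0.95; the extreme tip is the
#'   least reliable part of an extracted midline).
#' @param noise_floor minimum tail excursion (BL) treated as oscillation.
#' @return f in Hz.
#' @export
estimate_frequency <- function(field, station = 0.95, noise_floor = 1e-3) {
  stopifnot(inherits(field, "excursion_field"))
  y <- station_series(field, station)
  if (max(abs(y)) < noise_floor)
    stop("no oscillation: tail excursion below the noise floor")
  up <- crossing_times(y, field$time_s, 1)
  dn <- crossing_times(y, field$time_s, -1)
  if (length(up) + length(dn) < 3)
    stop("insufficient cycles: fewer than 3 zero crossings at the tail")
  periods <- c(diff(up), diff(dn))
  if (length(periods) == 0)
    stop("insufficient cycles: fewer than 3 zero crossings at the tail")
  f <- 1 / mean(periods)
  attr(f, "period_sd") <- if (length(periods) > 1) sd(periods) else NA_real_
  f
}

#' Peak-to-peak amplitude, envelope and caudal/rostral ratio
#'
#' For every arc station the peak-to-peak excursion (max - min of h) is
#' computed per tail-beat cycle and averaged over cycles, giving the
#' amplitude envelope along the body. The maximum amplitude is the largest
#' envelope value along the body; the amplitude ratio is the envelope at
#' the tail station divided by the head station (operationalizing "tail"
#' and "head" as s = 0.95 and s = 0.05).
#'
#' The per-cycle peak-to-peak value at each station is taken from a
#' low-order Fourier reconstruction of that cycle (fundamental plus two
#' overtones) rather than from raw sample extremes: raw extremes of tracked
#' series are biased upward by measurement ripple, while the reconstruction
#' is exact for sinusoidal waves and still captures skewed waveforms.
#'
#' @param field an `excursion_field`.
#' @param head_station,tail_station arc stations for the amplitude ratio.
#' @param n_harmonics number of Fourier components per cycle used for the
#'   peak-to-peak reconstruction.
#' @return list with `amp_pp_bl`, `envelope` (data.frame of s and pp, BL),
#'   `amp_ratio`, `n_cycles`.
#' @export
estimate_amplitude <- function(field, head_station = 0.05,
                               tail_station = 0.95, n_harmonics = 3) {
  stopifnot(inherits(field, "excursion_field"))
  tc <- crossing_times(station_series(field, tail_station), field$time_s)
  if (length(tc) < 2)
    stop("insufficient cycles: need at least 1 full tail-beat cycle")
  pp_cyc <- vapply(seq_len(length(tc) - 1), function(k)
    cycle_pp(field$h, field$time_s, tc[k], tc[k + 1], n_harmonics),
    numeric(nrow(field$h)))
  env <- rowMeans(pp_cyc)
  at <- function(st) approx(field$s, env, xout = st, rule = 2)$y
  ## station ratio extrapolated to the whole body assuming log-linear
  ## envelope growth, so the value is a true caudal/rostral (s = 1 vs 0)
  ## ratio while the endpoints themselves are never sampled
  ratio <- (at(tail_station) / at(head_station))^
    (1 / (tail_station - head_station))
  ## the outermost midline samples of tracked data carry spline-end
  ## artifacts; the tail-tip amplitude is extrapolated log-linearly from
  ## the interior instead of read off the endpoint row (the long window
  ## spans several body-wave periods, so any wavelength-locked measurement
  ## ripple averages out of both the fitted slope and level)
  fit_win <- which(field$s >= 0.30 & field$s <= 0.975)
  interior <- field$s >= 0.03 & field$s <= 0.975
  tail_val <- if (length(fit_win) >= 4 && all(env[fit_win] > 0)) {
    cf <- coef(lm(log(env[fit_win]) ~ field$s[fit_win]))
    exp(cf[[1]] + cf[[2]])
  } else env[length(env)]
  list(amp_pp_bl = max(env[interior], tail_val),
       envelope = data.frame(s = field$s, pp = env),
       amp_ratio = ratio,
       n_cycles = ncol(pp_cyc))
}

## local extrema of y with a simple prominence filter; positions refined by
## a parabolic fit through the three samples around each extremum
find_extrema <- function(s, y, prom) {
  n <- length(y)
  out_s <- numeric(0)
  for (sign_ in c(1, -1)) {
    z <- sign_ * y
    cand <- which(z[2:(n - 1)] >= z[1:(n - 2)] &
                  z[2:(n - 1)] >= z[3:n]) + 1L
    for (i in cand) {
      jl <- i; lmin <- z[i]
      while (jl > 1 && z[jl] <= z[i]) { jl <- jl - 1; lmin <- min(lmin, z[jl]) }
      jr <- i; rmin <- z[i]
      while (jr < n && z[jr] <= z[i]) { jr <- jr + 1; rmin <- min(rmin, z[jr]) }
      left_bounded <- z[jl] > z[i]; right_bounded <- z[jr] > z[i]
      base <- if (left_bounded && right_bounded) max(lmin, rmin)
              else min(lmin, rmin)
      if (z[i] - base < prom[i]) next
      ## parabolic refinement
      a <- z[i - 1]; b <- z[i]; c <- z[i + 1]
      den <- a - 2 * b + c
      d <- if (abs(den) > 1e-12) 0.5 * (a - c) / den else 0
      d <- max(-0.5, min(0.5, d))
      out_s <- c(out_s, s[i] + d * (s[2] - s[1]))
    }
  }
  sort(unique(out_s))
}

#' Body wavelength
#'
#' Per frame, locates the prominence-filtered extrema (peaks and troughs) of
#' h(s) along the body; the wavelength is twice the mean arc-length spacing
#' between adjacent extrema (peak-to-trough spacing is half a wavelength),
#' averaged over frames. When fewer than two interior extrema exist in every
#' frame but the body does oscillate (wavelengths longer than about the
#' body), the estimator falls back to fitting a single sinusoid in s per
#' frame and reports the fitted period, flagged via attribute
#' `"fit_based"`.
#'
#' @param field an `excursion_field`.
#' @param prominence extremum prominence threshold as a fraction of the
#'   local cycle-mean half-amplitude (default 0.2; rejects noise wiggles
#'   without suppressing the low-amplitude head region).
#' @param noise_floor minimum envelope amplitude (BL) for the wave to count
#'   as resolved.
#' @return lambda in BL, with attributes `fit_based` and `n_frames_used`.
#' @export
estimate_wavelength <- function(field, prominence = 0.2,
                                noise_floor = 1e-3) {
  stopifnot(inherits(field, "excursion_field"))
  env <- tryCatch(estimate_amplitude(field)$envelope$pp,
                  error = function(e)
                    apply(field$h, 1, function(z) max(z) - min(z)))
  if (max(env) < 2 * noise_floor)
    stop("wave not resolved: no oscillation along the body")
  prom <- prominence * env / 2
  n_frames <- ncol(field$h)
  lam_f <- rep(NA_real_, n_frames)
  ## light Gaussian smoothing along the body before extremum detection:
  ## suppresses sub-pixel tracking ripple without moving true wave extrema
  ## (symmetric kernel, support ~3% of body length)
  ker <- dnorm(-6:6, sd = 2)
  ker <- ker / sum(ker)
  pad <- 6L
  for (j in seq_len(n_frames)) {
    y <- field$h[, j]
    yp <- c(rep(y[1], pad), y, rep(y[length(y)], pad))
    ys <- stats::filter(yp, ker, sides = 2)[(pad + 1):(pad + length(y))]
    ext <- find_extrema(field$s, as.numeric(ys), prom)
    if (length(ext) < 2) next
    d <- diff(ext)
    ## guard against a missed extremum doubling a spacing or a residual
    ## ripple splitting one
    d <- d[d > 0.5 * median(d) & d < 1.5 * median(d)]
    if (length(d) > 0) lam_f[j] <- 2 * mean(d)
  }
  used <- which(!is.na(lam_f))
  if (length(used) > 0) {
    lam <- mean(lam_f[used])
    attr(lam, "fit_based") <- FALSE
    attr(lam, "n_frames_used") <- length(used)
    return(lam)
  }
  ## fallback: single-sinusoid fit in s per frame, after dividing out the
  ## amplitude envelope so that envelope growth cannot bias the period
  wgt <- pmax(env, 0.2 * max(env))
  sse <- function(lambda, y) {
    X <- cbind(1, sin(2 * pi * field$s / lambda),
               cos(2 * pi * field$s / lambda))
    sum(lm.fit(X, y / wgt)$residuals^2)
  }
  fit1 <- function(y) {
    grid <- seq(0.6, 6, length.out = 60)
    v <- vapply(grid, sse, numeric(1), y = y)
    g0 <- grid[which.min(v)]
    optimize(sse, lower = max(0.4, g0 * 0.7), upper = g0 * 1.4,
             y = y)$minimum
  }
  keep <- which(apply(abs(field$h), 2, max) > noise_floor)
  if (length(keep) == 0) stop("wave not resolved: no oscillation")
  lam <- mean(vapply(keep, function(j) fit1(field$h[, j]), numeric(1)))
  attr(lam, "fit_based") <- TRUE
  attr(lam, "n_frames_used") <- length(keep)
  lam
}

## phase unwrapping (remove 2*pi jumps)
unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

#' Body-wave propagation speed
#'
#' Computes the phase of the tail-beat-frequency component of h(s_i, t) at
#' a set of arc stations by complex demodulation over a whole number of
#' cycles, unwraps the phase along the body, and estimates the wave speed
#' V = -2 * pi * f / (d phase / d s) from the fitted phase-vs-s slope. For
#' a pure traveling wave V = lambda * f.
#'
#' @param field an `excursion_field`.
#' @param f tail-beat frequency in Hz; estimated from the field if NULL.
#' @param stations arc stations used for the phase fit (>= 10 stations in
#'   [0.3, 0.95]).
#' @param min_r2 minimum R^2 of the phase-vs-s line; below it the wave is
#'   incoherent.
#' @return V in BL/s, with attributes `r_squared` and `lambda_phase_bl`
#'   (the wavelength implied by the phase slope).
#' @export
estimate_wave_speed <- function(field, f = NULL,
                                stations = seq(0.3, 0.95, length.out = 14),
                                min_r2 = 0.9) {
  stopifnot(inherits(field, "excursion_field"))
  if (is.null(f)) f <- estimate_frequency(field)
  f <- as.numeric(f)
  tt <- field$time_s
  ## integer number of cycles for leakage-free demodulation
  Tspan <- tt[length(tt)] - tt[1]
  m <- floor(f * Tspan)
  if (m < 2) stop("insufficient cycles: need at least 2 full cycles")
  keep <- tt - tt[1] < m / f - 1e-12
  w <- exp(-2i * pi * f * tt[keep])
  phase <- vapply(stations, function(st) {
    Arg(sum(station_series(field, st)[keep] * w))
  }, numeric(1))
  phase <- unwrap_phase(phase)
  fit <- lm(phase ~ stations)
  r2 <- summary(fit)$r.squared
  slope <- coef(fit)[2]
  if (!is.finite(r2) || r2 < min_r2)
    stop("incoherent wave: phase-vs-position fit R^2 = ",
         round(r2, 3), " < ", min_r2)
  if (abs(slope) < 0.5)
    stop("incoherent wave: phase slope ~ 0 (standing wave?)")
  V <- abs(2 * pi * f / slope)
  attr(V, "r_squared") <- r2
  attr(V, "lambda_phase_bl") <- abs(2 * pi / slope)
  V
}

#' Simultaneous waves per body
#'
#' The number of body waves present at once is the reciprocal of the
#' wavelength in body lengths.
#'
#' @param wavelength_bl wavelength in BL, > 0.
#' @return waves per body (dimensionless).
#' @export
waves_per_body <- function(wavelength_bl) {
  if (!is.numeric(wavelength_bl) || any(wavelength_bl <= 0))
    stop("wavelength_bl must be > 0")
  1 / as.numeric(wavelength_bl)
}

#' Full wave-kinematics summary of one trial
#'
#' Runs the steady-state filter and every estimator on a tracked or
#' generated sequence and returns the one-row-per-trial summary the
#' statistics consume.
#'
#' @param seq a `midline_sequence`.
#' @param steady_tol tolerance of [steady_state_filter()].
#' @param enforce_steady if TRUE (default) a non-steady sequence is an
#'   error; if FALSE it is flagged in the output only.
#' @param ... passed to the individual estimators.
#' @return one-row data.frame with speed_bl_s, frequency_hz, amp_pp_bl,
#'   wavelength_bl, wave_speed_bl_s, waves_per_body, amp_ratio, n_cycles,
#'   steady, wavelength_fit_based and wave_consistency
#'   (= V / (lambda * f), ~1 for a coherent traveling wave).
#' @export
wave_kinematics <- function(seq, steady_tol = 0.15, enforce_steady = TRUE,
                            ...) {
  ss <- steady_state_filter(seq, tol = steady_tol)
  if (enforce_steady && !ss$pass)
    stop("sequence is not steady-state: cycle speeds deviate more than ",
         steady_tol * 100, "% from the mean")
  field <- body_frame(seq)
  U <- estimate_speed(field)
  f <- estimate_frequency(field, ...)
  amp <- estimate_amplitude(field)
  lam <- estimate_wavelength(field)
  V <- estimate_wave_speed(field, f = f)
  data.frame(speed_bl_s = as.numeric(U),
             frequency_hz = as.numeric(f),
             amp_pp_bl = amp$amp_pp_bl,
             wavelength_bl = as.numeric(lam),
             wave_speed_bl_s = as.numeric(V),
             waves_per_body = waves_per_body(as.numeric(lam)),
             amp_ratio = amp$amp_ratio,
             n_cycles = ss$n_cycles,
             steady = ss$pass,
             wavelength_fit_based = isTRUE(attr(lam, "fit_based")),
             wave_consistency = as.numeric(V) /
               (as.numeric(lam) * as.numeric(f)))
}
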