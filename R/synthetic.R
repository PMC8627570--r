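## Synthetic anguilliform swimmer: ground-truth midline sequences, rendered
## silhouette stacks, and whole virtual cohorts.

#' Parameters of a synthetic anguilliform swimmer
#'
#' Defines the kinematic ground truth of one steadily swimming individual:
#' a lateral traveling wave h(s, t) = A(s) sin(2 * pi * (s / lambda - f * t))
#' running head to tail along the body, with a geometrically growing
#' amplitude envelope A(s) = (A_pp / 2) * r^(s - 1) so that the
#' caudal/rostral peak-to-peak ratio A(1)/A(0) equals `amp_ratio`, while the
#' body translates at constant forward speed. Arc position s is normalized
#' body length (0 = snout, 1 = tail tip).
#'
#' Defaults are the kinematics of a healthy (sham-operated) larval lamprey:
#' wavelength 0.79 BL, tail-beat frequency 3.6 Hz, maximum peak-to-peak
#' amplitude 0.16 BL, caudal/rostral amplitude ratio 4.8, forward speed
#' 1.83 BL/s.
#'
#' @param body_length_mm physical body length in mm.
#' @param wavelength_bl body wavelength lambda in body lengths (BL), > 0.
#' @param frequency_hz tail-beat (wave) frequency f in Hz, > 0.
#' @param amp_pp_tail_bl maximum peak-to-peak amplitude at the tail, in BL,
#'   in [0, 1); the sinusoid half-amplitude is half this value.
#' @param amp_ratio caudal/rostral amplitude ratio (>= 1); 1 gives a uniform
#'   envelope.
#' @param speed_bl_s forward swimming speed U in BL/s.
#' @param heading_deg swim direction in the lab frame, degrees CCW from +x.
#' @param noise_sd_bl SD of additive Gaussian noise applied independently to
#'   each midline coordinate, in BL (0 = noise-free).
#' @param seed optional integer seed used when noise is drawn.
#' @return an object of class `swimmer_params`.
#' @export
swimmer_params <- function(body_length_mm = 120,
                           wavelength_bl = 0.79,
                           frequency_hz = 3.6,
                           amp_pp_tail_bl = 0.16,
                           amp_ratio = 4.8,
                           speed_bl_s = 1.83,
                           heading_deg = 0,
                           noise_sd_bl = 0,
                           seed = NULL) {
  stopifnot(is.numeric(body_length_mm), body_length_mm > 0)
  if (!is.numeric(wavelength_bl) || wavelength_bl <= 0)
    stop("wavelength_bl must be > 0")
  if (!is.numeric(frequency_hz) || frequency_hz <= 0)
    stop("frequency_hz must be > 0")
  if (!is.numeric(amp_pp_tail_bl) || amp_pp_tail_bl < 0 || amp_pp_tail_bl >= 1)
    stop("amp_pp_tail_bl must be in [0, 1)")
  if (!is.numeric(amp_ratio) || amp_ratio < 1)
    stop("amp_ratio must be >= 1")
  if (!is.numeric(noise_sd_bl) || noise_sd_bl < 0)
    stop("noise_sd_bl must be >= 0")
  structure(list(body_length_mm = body_length_mm,
                 wavelength_bl = wavelength_bl,
                 frequency_hz = frequency_hz,
                 amp_pp_tail_bl = amp_pp_tail_bl,
                 amp_ratio = amp_ratio,
                 speed_bl_s = speed_bl_s,
                 heading_deg = heading_deg,
                 noise_sd_bl = noise_sd_bl,
                 seed = seed),
            class = "swimmer_params")
}

## trapezoidal cumulative integral on a uniform-ish grid
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

envelope_at <- function(params, s) {
  (params$amp_pp_tail_bl / 2) * params$amp_ratio^(s - 1)
}

#' Generate a ground-truth midline sequence
#'
#' Builds lab-frame midline coordinates for a synthetic swimmer. The wave is
#' prescribed as lateral displacement h(s, t) over arc length s, and the
#' along-body coordinate is integrated so that s is true arc length: the
#' generated body is inextensible (constant curve length) up to quadrature
#' error. The body centroid advances along the heading at exactly U body
#' lengths per second. Phase speed of the wave is lambda * f in arc length
#' by construction.
#'
#' @param params a [swimmer_params()] object.
#' @param frame_rate_hz sampling rate; must be at least 10 x the wave
#'   frequency (sampling adequacy).
#' @param n_frames number of frames to generate (>= 1).
#' @param n_points number of midline points per frame, equally spaced in arc
#'   length.
#' @return a `midline_sequence`: list with `xy` (n_points x 2 x n_frames
#'   array of lab coordinates in mm, y up), `s`, `time_s`, `frame_rate_hz`,
#'   `scale` (mm per BL), `units`, `y_down = FALSE`, the noise-free `truth`
#'   array, and the generating `params`.
#' @export
generate_midline_sequence <- function(params, frame_rate_hz, n_frames,
                                      n_points = 100) {
  stopifnot(inherits(params, "swimmer_params"))
  if (frame_rate_hz < 10 * params$frequency_hz)
    stop(sprintf(paste0("sampling adequacy violated: frame_rate_hz (%g) is ",
                        "below the Nyquist-style bound of 10 x frequency_hz ",
                        "(= %g Hz)"),
                 frame_rate_hz, 10 * params$frequency_hz))
  stopifnot(n_frames >= 1, n_points >= 5)

  lam <- params$wavelength_bl
  f   <- params$frequency_hz
  r   <- params$amp_ratio
  A_t <- params$amp_pp_tail_bl / 2
  BL  <- params$body_length_mm
  th  <- params$heading_deg * pi / 180
  e   <- c(cos(th), sin(th))          # heading unit vector
  nv  <- c(-sin(th), cos(th))         # left normal (right-handed, y up)

  ## realizability: |dh/ds| must stay < 1 for an arc-length body
  slope_max <- A_t * r^(0) * sqrt(log(r)^2 + (2 * pi / lam)^2)
  if (slope_max >= 0.999)
    stop("wave too steep: |dh/ds| reaches ", round(slope_max, 3),
         "; reduce amplitude or increase wavelength")

  s_fine <- seq(0, 1, length.out = 2001)
  s_out  <- seq(0, 1, length.out = n_points)
  A_fine <- A_t * r^(s_fine - 1)
  A_out  <- A_t * r^(s_out - 1)
  tt <- (seq_len(n_frames) - 1) / frame_rate_hz

  xy <- array(NA_real_, dim = c(n_points, 2, n_frames))
  for (j in seq_len(n_frames)) {
    phi_f <- 2 * pi * (s_fine / lam - f * tt[j])
    dh <- A_fine * (log(r) * sin(phi_f) + (2 * pi / lam) * cos(phi_f))
    x_fine <- cumtrapz(s_fine, sqrt(pmax(0, 1 - dh^2)))
    x_s <- approx(s_fine, x_fine, xout = s_out)$y
    h_s <- A_out * sin(2 * pi * (s_out / lam - f * tt[j]))
    ## head leads: along-body coordinate decreases tailward, centered so the
    ## centroid sits on the U*t track
    xi <- -(x_s - mean(x_s))
    adv <- params$speed_bl_s * tt[j]
    xy[, 1, j] <- BL * ((adv + xi) * e[1] + h_s * nv[1])
    xy[, 2, j] <- BL * ((adv + xi) * e[2] + h_s * nv[2])
  }

  truth <- xy
  if (params$noise_sd_bl > 0) {
    if (!is.null(params$seed)) set.seed(params$seed)
    xy <- xy + array(rnorm(length(xy), sd = params$noise_sd_bl * BL),
                     dim = dim(xy))
  }

  structure(list(xy = xy, s = s_out, time_s = tt,
                 frame_rate_hz = frame_rate_hz,
                 scale = BL, units = "mm", y_down = FALSE,
                 truth = truth, params = params),
            class = "midline_sequence")
}

#' @export
print.midline_sequence <- function(x, ...) {
  cat(sprintf("midline_sequence: %d frames x %d points, %g fps, units %s (%g/%s BL)\n",
              dim(x$xy)[3], dim(x$xy)[1], x$frame_rate_hz, x$units,
              x$scale, x$units))
  invisible(x)
}

#' Rendering specification for silhouette frame stacks
#'
#' @param pixels_per_bl image scale, pixels per body length.
#' @param width_profile function of arc position s in [0, 1] returning the
#'   body half-width in BL; the default is a blunt-snout, taper-tail lamprey
#'   profile with maximum half-width 0.04 BL.
#' @param image_size optional c(rows, cols); if NULL and `follow = FALSE`
#'   the image is sized to the whole track, if `follow = TRUE` to the body.
#' @param foreground,background pixel intensities in [0, 1] for body and
#'   water.
#' @param follow if TRUE the camera window tracks the swimmer and a per-frame
#'   integer origin is recorded, so global pixel coordinates remain
#'   consistent across frames while images stay small.
#' @return object of class `render_spec`.
#' @export
render_spec <- function(pixels_per_bl = 150,
                        width_profile = NULL,
                        image_size = NULL,
                        foreground = 1, background = 0,
                        follow = FALSE) {
  stopifnot(pixels_per_bl > 0)
  if (is.null(width_profile))
    width_profile <- function(s)
      0.04 * pmin(1, sqrt(pmax(s, 0) / 0.08)) * pmin(1, pmax(0, (1 - s)) / 0.12)
  structure(list(pixels_per_bl = pixels_per_bl,
                 width_profile = width_profile,
                 image_size = image_size,
                 foreground = foreground, background = background,
                 follow = follow),
            class = "render_spec")
}

#' Render a midline sequence into a silhouette frame stack
#'
#' Rasterizes each frame's body as the union of disks centered on a finely
#' resampled midline with the local half-width from the render spec, on a
#' light/dark background as configured. Images use the usual image
#' convention (origin top-left, row index downwards); the per-frame
#' ground-truth midline is returned in the same global pixel coordinates
#' that the tracker reports, enabling direct round-trip comparison.
#'
#' @param seq a `midline_sequence` from [generate_midline_sequence()].
#' @param spec a [render_spec()].
#' @return a `frame_stack`: list with `frames` (list of matrices with values
#'   background/foreground), `origin` (n_frames x 2 matrix of (row, col)
#'   offsets: global = local + origin), `truth_px` (n_points x 2 x n_frames,
#'   columns (x = col, y = row), global), `frame_rate_hz`, `pixels_per_bl`,
#'   and `spec`.
#' @export
render_frames <- function(seq, spec = render_spec()) {
  stopifnot(inherits(seq, "midline_sequence"), inherits(spec, "render_spec"))
  ppbl <- spec$pixels_per_bl
  k <- ppbl / seq$scale                  # units -> px
  n_frames <- dim(seq$xy)[3]
  w_bl <- spec$width_profile(seq$s)
  rad_max <- max(w_bl) * ppbl
  margin <- ceiling(rad_max) + 3

  ## global pixel coordinates, row-down: gx = x * k, grow = -y * k
  gx <- seq$xy[, 1, , drop = FALSE] * k
  gr <- -seq$xy[, 2, , drop = FALSE] * k

  n_render <- max(200L, ceiling(2 * ppbl))
  s_r <- seq(0, 1, length.out = n_render)
  rad_r <- pmax(spec$width_profile(s_r) * ppbl, 0)

  if (spec$follow) {
    half_r <- (max(apply(gr, 3, max) - apply(gr, 3, min)) / 2)
    half_c <- (max(apply(gx, 3, max) - apply(gx, 3, min)) / 2)
    nr <- ceiling(2 * (half_r + margin)); nc <- ceiling(2 * (half_c + margin))
    if (!is.null(spec$image_size)) {
      nr <- spec$image_size[1]; nc <- spec$image_size[2]
    }
    origin <- matrix(0L, n_frames, 2)
    for (j in seq_len(n_frames)) {
      origin[j, 1] <- as.integer(floor((max(gr[, , j]) + min(gr[, , j])) / 2 - nr / 2))
      origin[j, 2] <- as.integer(floor((max(gx[, , j]) + min(gx[, , j])) / 2 - nc / 2))
    }
  } else {
    off_r <- floor(min(gr) - margin); off_c <- floor(min(gx) - margin)
    if (is.null(spec$image_size)) {
      nr <- ceiling(max(gr) + margin - off_r)
      nc <- ceiling(max(gx) + margin - off_c)
    } else {
      nr <- spec$image_size[1]; nc <- spec$image_size[2]
    }
    origin <- matrix(c(rep(as.integer(off_r), n_frames),
                       rep(as.integer(off_c), n_frames)), n_frames, 2)
  }

  frames <- vector("list", n_frames)
  truth_px <- array(NA_real_, dim = c(dim(seq$xy)[1], 2, n_frames))
  for (j in seq_len(n_frames)) {
    lr <- gr[, , j] - origin[j, 1]
    lc <- gx[, , j] - origin[j, 2]
    if (min(lr) - rad_max < 1 || max(lr) + rad_max > nr ||
        min(lc) - rad_max < 1 || max(lc) + rad_max > nc)
      stop(sprintf("body leaves the field of view at frame %d", j))
    xr <- spline(seq$s, lc, xout = s_r)$y
    yr <- spline(seq$s, lr, xout = s_r)$y
    m <- cpp_render_frame(xr, yr, rad_r, nr, nc)
    if (spec$background != 0 || spec$foreground != 1)
      m <- spec$background + (spec$foreground - spec$background) * m
    frames[[j]] <- m
    truth_px[, 1, j] <- gx[, , j]
    truth_px[, 2, j] <- gr[, , j]
  }
  structure(list(frames = frames, origin = origin, truth_px = truth_px,
                 frame_rate_hz = seq$frame_rate_hz, pixels_per_bl = ppbl,
                 spec = spec, params = seq$params),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_stack: %d frames of %d x %d px, %g fps, %g px/BL\n",
              length(x$frames), d[1], d[2], x$frame_rate_hz, x$pixels_per_bl))
  invisible(x)
}

#' Specification of a virtual study cohort
#'
#' Group-level kinematic means and SDs for a three-treatment spinal
#' transection study (sham control, transection at the 5th gill, transection
#' at mid-body). Defaults are the published group summaries for larval
#' lampreys: sample sizes (3, 11, 3); wavelength 0.79/0.53/0.61 BL,
#' peak-to-peak amplitude 0.16/0.11/0.13 BL, frequency 3.6/4.1/3.7 Hz for
#' sham/5th-gill/mid-body; speed 1.83 BL/s (sham) and 1.12 BL/s (transected
#' groups, reported jointly); caudal/rostral amplitude ratio 4.8/1.7/1.9;
#' percent axon regeneration uniform on 33.3-84.2% for transected animals,
#' missing for sham.
#'
#' @param n named integer vector of individuals per treatment
#'   (sham, fifth_gill, mid_body), all >= 1.
#' @param means,sds named lists of per-treatment numeric vectors with
#'   components wavelength_bl, amp_pp_tail_bl, frequency_hz, speed_bl_s,
#'   amp_ratio; all SDs >= 0.
#' @param regen_range percent axon regeneration range for transected
#'   individuals, within [0, 100].
#' @param trials_per_individual number of analyzed swimming sequences per
#'   individual.
#' @param within_sd_frac trial-to-trial variation within an individual,
#'   as a fraction of the group SD.
#' @param seed integer RNG seed; a single global stream drives all draws.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = c(sham = 3, fifth_gill = 11, mid_body = 3),
                        means = NULL, sds = NULL,
                        regen_range = c(33.3, 84.2),
                        trials_per_individual = 3,
                        within_sd_frac = 0.5,
                        seed = 1L) {
  default_means <- list(
    sham       = c(wavelength_bl = 0.79, amp_pp_tail_bl = 0.16,
                   frequency_hz = 3.6, speed_bl_s = 1.83, amp_ratio = 4.8),
    fifth_gill = c(wavelength_bl = 0.53, amp_pp_tail_bl = 0.11,
                   frequency_hz = 4.1, speed_bl_s = 1.12, amp_ratio = 1.7),
    mid_body   = c(wavelength_bl = 0.61, amp_pp_tail_bl = 0.13,
                   frequency_hz = 3.7, speed_bl_s = 1.12, amp_ratio = 1.9))
  default_sds <- list(
    sham       = c(wavelength_bl = 0.01, amp_pp_tail_bl = 0.01,
                   frequency_hz = 0.31, speed_bl_s = 0.08, amp_ratio = 0.43),
    fifth_gill = c(wavelength_bl = 0.06, amp_pp_tail_bl = 0.02,
                   frequency_hz = 0.81, speed_bl_s = 0.35, amp_ratio = 0.49),
    mid_body   = c(wavelength_bl = 0.08, amp_pp_tail_bl = 0.01,
                   frequency_hz = 0.32, speed_bl_s = 0.35, amp_ratio = 0.18))
  if (is.null(means)) means <- default_means
  if (is.null(sds)) sds <- default_sds
  groups <- c("sham", "fifth_gill", "mid_body")
  if (!all(groups %in% names(n)) || any(n[groups] < 1))
    stop("n must name sham, fifth_gill and mid_body, each >= 1")
  if (any(unlist(sds) < 0)) stop("all SDs must be >= 0")
  if (any(regen_range < 0) || any(regen_range > 100) ||
      regen_range[1] > regen_range[2])
    stop("regen_range must be an increasing range within [0, 100]")
  stopifnot(trials_per_individual >= 1, within_sd_frac >= 0)
  structure(list(n = n[groups], means = means[groups], sds = sds[groups],
                 regen_range = regen_range,
                 trials_per_individual = trials_per_individual,
                 within_sd_frac = within_sd_frac, seed = as.integer(seed)),
            class = "cohort_spec")
}

## inverse-CDF truncated normal draw from the current RNG stream
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

## physical truncation bounds per parameter
.param_bounds <- list(wavelength_bl = c(0.05, Inf),
                      amp_pp_tail_bl = c(0.005, 0.9),
                      frequency_hz = c(0.2, Inf),
                      speed_bl_s = c(0.02, Inf),
                      amp_ratio = c(1, Inf))

#' Generate a virtual cohort of swimming trials
#'
#' Draws per-individual kinematic parameters from truncated-normal
#' distributions at the group means/SDs (truncated at physical bounds), a
#' uniform percent axon regeneration for transected individuals (missing for
#' sham), and per-trial parameters as the individual values plus
#' truncated-normal trial-to-trial variation of SD `within_sd_frac` x group
#' SD. A single global RNG stream seeded from `spec$seed` drives every draw;
#' the draw order is: for each treatment (sham, fifth_gill, mid_body), for
#' each individual, the five parameters in the order wavelength, amplitude,
#' frequency, speed, amplitude ratio, then regeneration, then per trial the
#' same five parameters. Identical seed gives an identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per trial: individual_id, treatment,
#'   regeneration_pct, trial, and the true wavelength_bl, amp_pp_tail_bl,
#'   frequency_hz, speed_bl_s, amp_ratio; attribute `"params"` holds the
#'   corresponding [swimmer_params()] list.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  pars <- c("wavelength_bl", "amp_pp_tail_bl", "frequency_hz",
            "speed_bl_s", "amp_ratio")
  rows <- list(); plist <- list(); id <- 0L
  for (g in names(spec$n)) {
    mu <- spec$means[[g]]; sg <- spec$sds[[g]]
    for (i in seq_len(spec$n[[g]])) {
      id <- id + 1L
      ind <- vapply(pars, function(p) {
        b <- .param_bounds[[p]]
        rtruncnorm1(1, mu[[p]], sg[[p]], b[1], b[2])
      }, numeric(1))
      regen <- if (g == "sham") NA_real_ else
        runif(1, spec$regen_range[1], spec$regen_range[2])
      for (tr in seq_len(spec$trials_per_individual)) {
        trial <- vapply(pars, function(p) {
          b <- .param_bounds[[p]]
          rtruncnorm1(1, ind[[p]], spec$within_sd_frac * sg[[p]], b[1], b[2])
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = sprintf("ind%02d", id), treatment = g,
          regeneration_pct = regen, trial = tr,
          as.list(trial), stringsAsFactors = FALSE)
        plist[[length(plist) + 1L]] <- swimmer_params(
          wavelength_bl = trial[["wavelength_bl"]],
          frequency_hz = trial[["frequency_hz"]],
          amp_pp_tail_bl = trial[["amp_pp_tail_bl"]],
          amp_ratio = trial[["amp_ratio"]],
          speed_bl_s = trial[["speed_bl_s"]])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "params") <- plist
  out
}
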