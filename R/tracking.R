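## Midline tracking: silhouette segmentation, centerline extraction,
## head/tail orientation and assembly into a tracked sequence.

#' Segment the swimmer silhouette from a single frame
#'
#' Thresholds the frame (Otsu by default), keeps the largest connected
#' foreground component, and fills interior holes. The swimmer is assumed to
#' be the minority intensity class when `object = "auto"`; pass "bright" or
#' "dark" to force polarity.
#'
#' @param frame numeric matrix (single-channel image).
#' @param threshold "otsu" or a fixed numeric threshold on the intensity
#'   scale of `frame`.
#' @param object "auto", "bright" (swimmer brighter than water) or "dark".
#' @param min_area minimum component area in pixels; below it the frame is
#'   treated as containing no swimmer.
#' @return logical matrix mask of the swimmer.
#' @export
segment_body <- function(frame, threshold = "otsu", object = "auto",
                         min_area = 20) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  rng <- range(frame)
  if (diff(rng) == 0) stop("no swimmer detected: frame is constant")
  if (identical(threshold, "otsu")) {
    sc <- (frame - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(sc)) * diff(rng) + rng[1]
  } else {
    stopifnot(is.numeric(threshold))
    th <- threshold
  }
  bright <- frame > th
  mask <- switch(match.arg(object, c("auto", "bright", "dark")),
                 bright = bright,
                 dark = !bright,
                 auto = if (sum(bright) <= sum(!bright)) bright else !bright)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  tab <- tabulate(as.integer(lab))
  if (length(tab) == 0 || max(tab) < min_area)
    stop("no swimmer detected: no component above min_area")
  keep <- which.max(tab)
  comp <- matrix(as.integer(lab) == keep, nrow(frame), ncol(frame))
  filled <- EBImage::fillHull(EBImage::Image(comp * 1))
  matrix(as.numeric(filled) > 0, nrow(frame), ncol(frame))
}

## march from a path endpoint along the local tangent to the mask boundary,
## recovering the body tip that thinning erodes away
extend_tip <- function(pt, ref, mask, max_ext) {
  d <- pt - ref
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) return(pt)
  d <- d / nd
  last <- pt
  steps <- seq(0.5, max_ext, by = 0.5)
  for (t in steps) {
    p <- pt + t * d
    r <- round(p[2]); c <- round(p[1])
    if (r < 1 || r > nrow(mask) || c < 1 || c > ncol(mask) || !mask[r, c])
      break
    last <- p
  }
  last
}

## slide each midline point to the midpoint of the transverse foreground
## run along the local normal: skeletons of a bent tube cut corners at
## strong bends and are pixel-quantized, while the transverse-slice center
## is the true centerline (sub-pixel) for a locally straight-edged body
refine_center <- function(xy, mask, halfwidth_px, step = 0.25) {
  n <- nrow(xy)
  tang <- rbind(xy[2, ] - xy[1, ],
                (xy[3:n, ] - xy[1:(n - 2), ]) / 2,
                xy[n, ] - xy[n - 1, ])
  len <- sqrt(rowSums(tang^2))
  len[len < 1e-9] <- 1
  tang <- tang / len
  nx <- -tang[, 2]; ny <- tang[, 1]
  ts <- seq(-halfwidth_px, halfwidth_px, by = step)
  X <- outer(xy[, 1], rep(1, length(ts))) + outer(nx, ts)
  Y <- outer(xy[, 2], rep(1, length(ts))) + outer(ny, ts)
  ri <- round(Y); ci <- round(X)
  ok <- ri >= 1 & ri <= nrow(mask) & ci >= 1 & ci <= ncol(mask)
  M <- matrix(FALSE, n, length(ts))
  M[ok] <- mask[cbind(ri[ok], ci[ok])]
  mid <- which.min(abs(ts))
  ctr <- numeric(n)
  run <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    row <- M[i, ]
    if (!row[mid]) next
    lo <- mid; while (lo > 1 && row[lo - 1]) lo <- lo - 1
    hi <- mid; while (hi < length(ts) && row[hi + 1]) hi <- hi + 1
    ctr[i] <- (ts[lo] + ts[hi]) / 2
    run[i] <- ts[hi] - ts[lo]
  }
  ## where the body folds close to itself the transverse run merges with
  ## the adjacent body segment; anomalously long runs (vs the typical body
  ## width) or large shifts mean contamination - keep the skeleton point
  med_run <- median(run, na.rm = TRUE)
  bad <- is.na(run) | run > 1.8 * med_run | abs(ctr) > 2
  ctr[bad] <- 0
  xy + cbind(nx * ctr, ny * ctr)
}

#' Extract an unoriented body midline from a mask
#'
#' Skeletonizes the mask (Zhang-Suen thinning), takes the longest geodesic
#' path between skeleton endpoints as the body axis (which also discards
#' short spur branches), extends both ends along their tangents to the mask
#' boundary to recover the tapered tips, smooths x(s) and y(s) with cubic
#' smoothing splines, and resamples to `n_points` equally spaced in arc
#' length.
#'
#' @param mask logical matrix from [segment_body()].
#' @param n_points number of output points (default 100, resolving
#'   wavelengths of about 0.5 BL with >= 50 samples per wave).
#' @param smoothing fixed smoothing-spline parameter (`spar` of
#'   [stats::smooth.spline()]); the same value is used for every frame and
#'   treatment.
#' @param min_path_frac minimum fraction of skeleton pixels the axis path
#'   must cover; below it the centerline is ambiguous (branched skeleton).
#' @return object of class `body_midline`: list with `xy` (n_points x 2,
#'   columns x = image column, y = image row), `s` in [0, 1],
#'   `body_length_px`, `frame_index`, `time_s`.
#' @export
extract_midline <- function(mask, n_points = 100, smoothing = 0.4,
                            min_path_frac = 0.8) {
  stopifnot(is.matrix(mask))
  mm <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  res <- cpp_skeleton_path(mm)
  path <- res$path
  if (nrow(path) < 5)
    stop("ambiguous centerline: skeleton too small")
  if (nrow(path) < min_path_frac * res$n_skeleton)
    stop("ambiguous centerline: branched skeleton with no dominant path")
  area <- sum(mask)
  if (nrow(path) < 2 * sqrt(area))
    stop("ambiguous centerline: object not elongated")

  ## (x = col, y = row)
  px <- cbind(path[, 2], path[, 1])
  k <- min(6L, nrow(px))
  max_ext <- max(6, 0.15 * nrow(px))
  tip1 <- extend_tip(px[1, ], px[k, ], mask, max_ext)
  tip2 <- extend_tip(px[nrow(px), ], px[nrow(px) - k + 1, ], mask, max_ext)
  px <- rbind(tip1, px, tip2)

  if (nrow(px) > 400) px <- px[unique(round(seq(1, nrow(px), length.out = 400))), ]
  u <- c(0, cumsum(sqrt(rowSums(diff(px)^2))))
  u <- u / max(u)
  fx <- smooth.spline(u, px[, 1], spar = smoothing, cv = FALSE)
  fy <- smooth.spline(u, px[, 2], spar = smoothing, cv = FALSE)
  uu <- seq(0, 1, length.out = max(400L, nrow(px)))
  xs <- predict(fx, uu)$y
  ys <- predict(fy, uu)$y
  arc <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  L <- arc[length(arc)]
  s_out <- seq(0, 1, length.out = n_points)
  xr <- approx(arc / L, xs, xout = s_out)$y
  yr <- approx(arc / L, ys, xout = s_out)$y

  ## sub-pixel correction: skeletons cut corners at bends, the transverse
  ## slice center does not; then a light second smoothing pass and a final
  ## arc-length resampling
  halfwidth <- 1.5 * area / max(L, 1) + 2
  ref <- refine_center(cbind(xr, yr), mask, halfwidth)
  u2 <- c(0, cumsum(sqrt(rowSums(diff(ref)^2))))
  u2 <- u2 / max(u2)
  fx2 <- smooth.spline(u2, ref[, 1], spar = smoothing, cv = FALSE)
  fy2 <- smooth.spline(u2, ref[, 2], spar = smoothing, cv = FALSE)
  uu2 <- seq(0, 1, length.out = 4 * n_points)
  xs2 <- predict(fx2, uu2)$y
  ys2 <- predict(fy2, uu2)$y
  arc2 <- c(0, cumsum(sqrt(diff(xs2)^2 + diff(ys2)^2)))
  L <- arc2[length(arc2)]
  xr <- approx(arc2 / L, xs2, xout = s_out)$y
  yr <- approx(arc2 / L, ys2, xout = s_out)$y
  structure(list(xy = cbind(x = xr, y = yr), s = s_out,
                 body_length_px = L, frame_index = NA_integer_,
                 time_s = NA_real_),
            class = "body_midline")
}

#' Orient per-frame midlines and assemble a tracked sequence
#'
#' Enforces a consistent point ordering across frames (matching each frame
#' to its predecessor), then identifies the head as the end with the smaller
#' lateral-excursion variance over time: in anguilliform swimming the wave
#' amplitude grows toward the tail, so the quieter end is rostral. This is
#' robust to erratic swimming paths, unlike motion-direction heuristics.
#'
#' @param midlines list of `body_midline` objects sharing `n_points`,
#'   covering at least one full wave period.
#' @param frame_rate_hz acquisition rate in frames per second.
#' @param min_var_ratio minimum tail/head excursion-variance ratio; below it
#'   orientation is ambiguous and an error is raised rather than guessing.
#' @param length_tol tolerated coefficient of variation of body length
#'   across frames before a QC warning.
#' @return `midline_sequence` in pixel units (`y_down = TRUE`): `xy`
#'   (n_points x 2 x n_frames, columns (x = col, y = row)), `s`, `time_s`,
#'   `frame_rate_hz`, `scale` (= mean body length in px, i.e. pixels per
#'   BL), `body_length_px` per frame.
#' @export
orient_and_track <- function(midlines, frame_rate_hz, min_var_ratio = 1.2,
                             length_tol = 0.05) {
  stopifnot(length(midlines) >= 1, frame_rate_hz > 0)
  np <- vapply(midlines, function(m) nrow(m$xy), integer(1))
  if (length(unique(np)) != 1)
    stop("all midlines must share the same number of points")
  n_frames <- length(midlines)
  n_points <- np[1]

  xy <- array(NA_real_, dim = c(n_points, 2, n_frames))
  xy[, , 1] <- midlines[[1]]$xy
  if (n_frames > 1) {
    for (j in 2:n_frames) {
      cur <- midlines[[j]]$xy
      d_fwd <- sum((cur - xy[, , j - 1])^2)
      d_rev <- sum((cur[n_points:1, ] - xy[, , j - 1])^2)
      xy[, , j] <- if (d_rev < d_fwd) cur[n_points:1, ] else cur
    }
  }

  ## head/tail disambiguation by lateral-excursion variance at the two ends
  cent <- t(apply(xy, 3, colMeans))
  if (n_frames >= 2) {
    pc <- prcomp(cent)
    e <- pc$rotation[, 1]
    nv <- c(-e[2], e[1])
    cbar <- colMeans(cent)
    end_perp <- function(idx) {
      q <- t(apply(xy[idx, , , drop = FALSE], 3,
                   function(m) colMeans(matrix(m, ncol = 2))))
      (q[, 1] - cbar[1]) * nv[1] + (q[, 2] - cbar[2]) * nv[2]
    }
    k <- max(1L, min(3L, n_points %/% 10))
    vA <- var(end_perp(seq_len(k)))
    vB <- var(end_perp(n_points - seq_len(k) + 1L))
    if (!is.finite(vA) || !is.finite(vB) || min(vA, vB) <= 0 ||
        max(vA, vB) / min(vA, vB) < min_var_ratio)
      stop("orientation ambiguous: lateral-excursion variance ratio between ",
           "candidate ends is below ", min_var_ratio)
    if (vA > vB) xy <- xy[n_points:1, , , drop = FALSE]
  }

  bl <- vapply(midlines, function(m) m$body_length_px, numeric(1))
  cv <- sd(bl) / mean(bl)
  if (is.finite(cv) && cv > length_tol)
    warning(sprintf("body length unstable across frames (CV = %.1f%%)",
                    100 * cv))
  structure(list(xy = xy, s = seq(0, 1, length.out = n_points),
                 time_s = (seq_len(n_frames) - 1) / frame_rate_hz,
                 frame_rate_hz = frame_rate_hz,
                 scale = mean(bl), units = "px", y_down = TRUE,
                 body_length_px = bl, truth = NULL, params = NULL),
            class = "midline_sequence")
}

#' Track the midline through a silhouette frame stack
#'
#' Convenience wrapper: segment each frame, extract its midline, map local
#' window coordinates to global pixel coordinates using the stack's
#' per-frame origin, and orient the result into a `midline_sequence`.
#'
#' Frames on which segmentation or extraction fails (e.g. a momentarily
#' self-occluding body giving a branched skeleton) are tolerated up to
#' `max_dropout` as a fraction of the stack and filled by linear
#' interpolation of the neighboring tracked midlines; more than that is an
#' error.
#'
#' @param stack a `frame_stack` from [render_frames()] or
#'   [read_frame_stack()].
#' @param threshold,object,min_area passed to [segment_body()]; the Otsu
#'   threshold is computed once on the first frame and reused for the
#'   stack (rendered and laser-lit stacks have stable illumination).
#' @param n_points,smoothing passed to [extract_midline()].
#' @param max_dropout tolerated fraction of untrackable frames.
#' @param ... passed to [orient_and_track()].
#' @return a tracked `midline_sequence` in global pixel coordinates, with
#'   attribute `"dropped_frames"` listing any interpolated frames.
#' @export
track_frames <- function(stack, threshold = "otsu", object = "auto",
                         min_area = 20, n_points = 100, smoothing = 0.4,
                         max_dropout = 0.05, ...) {
  stopifnot(inherits(stack, "frame_stack") || is.list(stack))
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  origin <- if (inherits(stack, "frame_stack")) stack$origin else
    matrix(0L, length(frames), 2)
  if (identical(threshold, "otsu")) {
    m1 <- frames[[1]]
    rng <- range(m1)
    if (diff(rng) > 0)
      threshold <- EBImage::otsu(EBImage::Image((m1 - rng[1]) / diff(rng))) *
        diff(rng) + rng[1]
  }
  mids <- vector("list", length(frames))
  errs <- character(0)
  for (j in seq_along(frames)) {
    m <- tryCatch({
      mask <- segment_body(frames[[j]], threshold = threshold,
                           object = object, min_area = min_area)
      extract_midline(mask, n_points = n_points, smoothing = smoothing)
    }, error = function(e) conditionMessage(e))
    if (is.character(m)) {
      errs <- c(errs, sprintf("frame %d: %s", j, m))
      next
    }
    m$xy[, 1] <- m$xy[, 1] + origin[j, 2]   # x = col
    m$xy[, 2] <- m$xy[, 2] + origin[j, 1]   # y = row
    m$frame_index <- j
    mids[[j]] <- m
  }
  fr <- if (inherits(stack, "frame_stack")) stack$frame_rate_hz else
    stop("frame_rate_hz unknown; pass a frame_stack")
  good <- which(!vapply(mids, is.null, logical(1)))
  if (length(good) == 0) stop("tracking failed on every frame: ", errs[1])
  dropped <- setdiff(seq_along(frames), good)
  if (length(dropped) > max_dropout * length(frames))
    stop(sprintf("tracking failed on %d of %d frames (first: %s)",
                 length(dropped), length(frames), errs[1]))
  out <- orient_and_track(mids[good], frame_rate_hz = fr, ...)
  if (length(dropped) > 0) {
    n <- length(frames)
    np <- dim(out$xy)[1]
    xy <- array(NA_real_, dim = c(np, 2, n))
    xy[, , good] <- out$xy
    for (i in seq_len(np)) for (d in 1:2)
      xy[i, d, dropped] <- approx(good, out$xy[i, d, ], xout = dropped,
                                  rule = 2)$y
    bl <- rep(NA_real_, n)
    bl[good] <- out$body_length_px
    bl[dropped] <- approx(good, out$body_length_px, xout = dropped,
                          rule = 2)$y
    out$xy <- xy
    out$body_length_px <- bl
    out$time_s <- (seq_len(n) - 1) / fr
    out$scale <- mean(bl)
  } else {
    out$time_s <- (good - 1) / fr
  }
  attr(out, "dropped_frames") <- dropped
  out
}
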