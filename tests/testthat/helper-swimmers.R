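# Shared synthetic fixtures, built once per test run and cached.

sham_params <- function(...) {
  swimmer_params(wavelength_bl = 0.79, frequency_hz = 3.6,
                 amp_pp_tail_bl = 0.16, amp_ratio = 4.8,
                 speed_bl_s = 1.83, ...)
}

gill_params <- function(...) {
  swimmer_params(wavelength_bl = 0.53, frequency_hz = 4.1,
                 amp_pp_tail_bl = 0.11, amp_ratio = 1.7,
                 speed_bl_s = 1.12, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a rendered + tracked sham-like clip reused across tracking/kinematics tests
sham_clip <- function() {
  cached("sham_clip", {
    sq <- generate_midline_sequence(sham_params(), 250, 300)
    stk <- render_frames(sq, render_spec(follow = TRUE))
    list(seq = sq, stack = stk, tracked = track_frames(stk))
  })
}

gill_clip <- function() {
  cached("gill_clip", {
    sq <- generate_midline_sequence(gill_params(), 250, 300)
    stk <- render_frames(sq, render_spec(follow = TRUE))
    list(seq = sq, stack = stk, tracked = track_frames(stk))
  })
}

# RMS distance from tracked interior points to the (densely interpolated)
# ground-truth midline curve of frame j
midline_rms <- function(stack, tracked, j, interior = 4:97) {
  tp <- stack$truth_px[, , j]
  dense <- cbind(spline(seq_len(nrow(tp)), tp[, 1], n = 1000)$y,
                 spline(seq_len(nrow(tp)), tp[, 2], n = 1000)$y)
  d <- vapply(interior, function(i)
    sqrt(min((dense[, 1] - tracked$xy[i, 1, j])^2 +
             (dense[, 2] - tracked$xy[i, 2, j])^2)), numeric(1))
  sqrt(mean(d^2))
}

# hand-coded sums-of-squares one-way ANOVA oracle
anova_oracle <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g); n <- length(y)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(z) length(z) * (mean(z) - gm)^2))
  ssw <- sum(tapply(y, g, function(z) sum((z - mean(z))^2)))
  dfb <- k - 1; dfw <- n - k
  Fv <- (ssb / dfb) / (ssw / dfw)
  list(F = Fv, df1 = dfb, df2 = dfw,
       p = pf(Fv, dfb, dfw, lower.tail = FALSE))
}

# normal-equations OLS oracle for simple regression
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}
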