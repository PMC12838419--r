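# shared fixtures, all built in code

circle_contour <- function(r = 1, n = 360, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  contour2d(cbind(center[1L] + r * cos(th), center[2L] + r * sin(th)))
}

ellipse_contour <- function(a = 2, b = 1, n = 256, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  contour2d(cbind(center[1L] + a * cos(th), center[2L] + b * sin(th)))
}

# analytic elliptical pullback with an injected cumulative twist profile
elliptical_series <- function(cum_twist_deg, a = 2, b = 1.5,
                              spacing = 0.4, offset = c(0.2, 0.1)) {
  # catheter twist rotates the image about the catheter (the origin), after
  # the section is expressed in catheter-centred coordinates
  contours <- lapply(cum_twist_deg, function(tw)
    rotate_contour(translate_contour(ellipse_contour(a, b), -offset), tw))
  pullback_series(contours, oct_calibration(frame_spacing_mm = spacing))
}

# smooth random per-frame twist increments bounded by `amp` degrees
smooth_twist <- function(n, amp, seed) {
  set.seed(seed)
  inc <- c(0, amp * runif(1, 0.5, 1) *
             sin(2 * pi * seq_len(n - 1L) / runif(1, 10, 30) +
                   runif(1, 0, 2 * pi)))
  cumsum(inc)
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
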