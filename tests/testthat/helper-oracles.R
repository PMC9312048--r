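# Shared fixtures and independent oracles. The oracles deliberately use a
# different computational route than the package code they check.

# Independent ray-intersection oracle: rotate the outline so the ray lies
# along the positive x-axis from the origin, then find segments straddling
# y = 0 and interpolate their x-crossings. No parametric 2x2 solve, unlike
# cast_ray.
oracle_ray_lengths <- function(origin_pt, axis_to, theta_deg, vertices) {
  u <- axis_to - origin_pt
  phi <- atan2(u[2], u[1]) + theta_deg * pi / 180  # ray bearing, world frame
  co <- cos(-phi); si <- sin(-phi)
  vx <- vertices[, 1] - origin_pt[1]
  vy <- vertices[, 2] - origin_pt[2]
  rx <- co * vx - si * vy
  ry <- si * vx + co * vy
  n <- length(rx)
  y1 <- ry[-n]; y2 <- ry[-1L]; x1 <- rx[-n]; x2 <- rx[-1L]
  straddle <- (y1 <= 0 & y2 > 0) | (y1 > 0 & y2 <= 0)
  xc <- x1[straddle] + (0 - y1[straddle]) / (y2[straddle] - y1[straddle]) *
    (x2[straddle] - x1[straddle])
  xc <- sort(xc[xc > 0])
  # vertex-exact hits are shared by two segments: merge them
  xc[c(TRUE, diff(xc) > 1e-9)]
}

# half-ellipse arc with semi-axes a (along baseline) and b (height),
# centred on the origin; dense enough that chord error is far below 1e-6
# relative
half_ellipse_fixture <- function(a = 25, b = 15, n = 5001) {
  t <- seq(pi, 0, length.out = n)
  v <- cbind(a * cos(t), b * sin(t))
  v[1, ] <- c(-a, 0); v[n, ] <- c(a, 0)
  baseline <- baseline_spec(c(-a, 0), c(a, 0))
  list(outline = sinus_outline(v, id = "half_ellipse"),
       baseline = baseline,
       origin = origin_spec(c(0, 0), baseline),
       a = a, b = b)
}

# closed-form polar radius of the ellipse at angle theta from the +x axis
ellipse_radius <- function(theta_deg, a, b) {
  th <- theta_deg * pi / 180
  a * b / sqrt(b^2 * cos(th)^2 + a^2 * sin(th)^2)
}

# hand-built 6-vertex arc whose 90-degree ray is crossed transversally at
# height 14 and touched at the valley vertex (0, 8): exercises both the
# outermost rule and vertex-hit merging
w_arc_fixture <- function() {
  v <- rbind(c(-10, 0), c(-2, 12), c(1, 15), c(0, 8), c(3, 12), c(10, 0))
  baseline <- baseline_spec(c(-10, 0), c(10, 0))
  list(outline = sinus_outline(v, id = "w_arc"),
       baseline = baseline,
       origin = origin_spec(c(0, 0), baseline))
}

# rigid rotation + translation of a point matrix
apply_rigid <- function(v, angle_deg, shift) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(v %*% t(R), 2, -shift)
}

# quick standardized profile of a generated truth
profile_of <- function(truth, ...) {
  standardize_profile(measure_profile(truth$outline, truth$baseline,
                                      truth$origin, ...))
}
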