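test_that("ray fan is an inclusive arithmetic sequence strictly inside (0, 180)", {
  fan <- ray_angles()
  expect_identical(fan, seq(3, 177, by = 3))
  # exhaustive enumeration oracle: multiples of 3 in [3, 177]
  expect_length(fan, sum((1:179) %% 3 == 0 & 1:179 >= 3 & 1:179 <= 177))
  expect_equal(ray_angles(90, 3, 90), 90)
  expect_error(ray_angles(0, 3, 177), class = "tdm_config_error")
  expect_error(ray_angles(3, 3, 180), class = "tdm_config_error")
  expect_error(ray_angles(3, 4, 177), class = "tdm_config_error")
  expect_error(ray_angles(3, -3, 177), class = "tdm_config_error")
})

test_that("origin placement intersects the midline with the baseline segment", {
  b <- baseline_spec(c(-10, 0), c(10, 0))
  o <- place_origin(c(0, -5), c(0, 5), b)
  expect_equal(o$origin, c(0, 0))
  expect_equal(o$right_baseline_RB, 10)
  expect_equal(o$midline_ratio_r, 0.5)

  # analytic line-segment intersection: line through (1,0),(2,10) meets the
  # x-axis at (1,0); baseline (-8,0)->(12,0) has B = 20, RB = 11
  b2 <- baseline_spec(c(-8, 0), c(12, 0))
  o2 <- place_origin(c(1, 0), c(2, 10), b2)
  expect_equal(o2$origin, c(1, 0))
  expect_equal(o2$right_baseline_RB, 11)
  expect_equal(midline_ratio(o2), 0.55)

  expect_error(place_origin(c(0, 5), c(10, 5), b), class = "tdm_geometry_error")
  expect_error(place_origin(c(50, -5), c(50, 5), b), class = "tdm_geometry_error")
})

test_that("midline ratio is RB/B and scale-invariant", {
  b <- baseline_spec(c(0, 0), c(20, 0))
  expect_equal(midline_ratio(origin_spec(c(10, 0), b)), 0.5)
  expect_equal(midline_ratio(origin_spec(c(9, 0), b)), 0.55)
  expect_equal(midline_ratio(origin_spec(c(20, 0), b)), 0)
  for (c_scale in c(0.1, 3, 250)) {
    bc <- baseline_spec(c(0, 0), c(20 * c_scale, 0))
    expect_equal(midline_ratio(origin_spec(c(9 * c_scale, 0), bc)), 0.55)
  }
})

test_that("cast_ray returns the outermost crossing and merges vertex hits", {
  # semicircle of radius 20: every ray length is the radius
  th <- seq(pi, 0, length.out = 721)
  v <- cbind(20 * cos(th), 20 * sin(th)); v[1, ] <- c(-20, 0); v[721, ] <- c(20, 0)
  semi <- sinus_outline(v)
  b <- baseline_spec(c(-20, 0), c(20, 0))
  o <- origin_spec(c(0, 0), b)
  m <- cast_ray(o, 90, semi)
  expect_equal(m$line_length_L, 20, tolerance = 1e-5)
  expect_identical(m$n_crossings, 1L)
  expect_false(m$outermost_used)

  # W-shaped arc: transversal crossing at 14, vertex touch at 8
  w <- w_arc_fixture()
  mw <- cast_ray(w$origin, 90, w$outline)
  expect_equal(mw$line_length_L, 14)
  expect_identical(mw$n_crossings, 2L)
  expect_true(mw$outermost_used)
  # both crossings confirmed by the independent straddle-interpolation oracle
  xc <- oracle_ray_lengths(w$origin$origin, w$baseline$right_terminus, 90,
                           w$outline$vertices)
  expect_equal(xc, c(8, 14))

  # rectangular arc, 45-degree ray exits exactly through the corner (10, 10)
  rect <- sinus_outline(rbind(c(-10, 0), c(-10, 10), c(10, 10), c(10, 0)))
  br <- baseline_spec(c(-10, 0), c(10, 0))
  mr <- cast_ray(origin_spec(c(0, 0), br), 45, rect)
  expect_equal(mr$line_length_L, 10 * sqrt(2))
  expect_identical(mr$n_crossings, 1L)

  expect_error(cast_ray(o, 0, semi), class = "tdm_config_error")
  expect_error(cast_ray(o, 180, semi), class = "tdm_config_error")
})

test_that("measured profiles match closed-form geometry", {
  # half-ellipse: polar radius in closed form at every angle
  he <- half_ellipse_fixture(a = 25, b = 15)
  prof <- measure_profile(he$outline, he$baseline, he$origin)
  expect_identical(nrow(prof$measurements), 59L)
  expect_identical(prof$measurements$angle_theta, seq(3, 177, by = 3))
  expected <- ellipse_radius(prof$measurements$angle_theta, he$a, he$b)
  expect_equal(prof$measurements$line_length_L, expected, tolerance = 1e-6)

  # rotational symmetry: semicircle gives a flat profile at the radius
  th <- seq(pi, 0, length.out = 2001)
  v <- cbind(12 * cos(th), 12 * sin(th)); v[1, ] <- c(-12, 0); v[2001, ] <- c(12, 0)
  b <- baseline_spec(c(-12, 0), c(12, 0))
  prof2 <- measure_profile(sinus_outline(v), b, origin_spec(c(0, 0), b))
  expect_equal(prof2$measurements$line_length_L, rep(12, 59), tolerance = 1e-5)
})

test_that("line length equals angle perimeter minus the right baseline", {
  expect_equal(line_length_from_perimeter(30, 10), 20)
  expect_equal(line_length_from_perimeter(10, 10), 0)
  expect_error(line_length_from_perimeter(5, 10), class = "tdm_data_error")
  # internal consistency with cast_ray: RB + L reconstructs the perimeter
  he <- half_ellipse_fixture()
  m <- cast_ray(he$origin, 60, he$outline)
  P <- he$origin$right_baseline_RB + m$line_length_L
  expect_equal(line_length_from_perimeter(P, he$origin$right_baseline_RB),
               m$line_length_L, tolerance = 1e-9)
})

test_that("leveling rotation preserves the baseline-relative geometry", {
  g <- generate_outline(seed = 11)
  # identity rotation
  lev0 <- rotate_to_level(g$outline, g$baseline, g$origin, angle_deg = 0)
  expect_equal(lev0$outline$vertices, g$outline$vertices)

  # tilt everything by 5 degrees, then level: baseline slope returns to 0
  tilt <- rotate_to_level(g$outline, g$baseline, g$origin, angle_deg = 5)
  expect_equal(atan2(tilt$baseline$right_terminus[2] - tilt$baseline$left_terminus[2],
                     tilt$baseline$right_terminus[1] - tilt$baseline$left_terminus[1]),
               5 * pi / 180, tolerance = 1e-12)
  lev <- rotate_to_level(tilt$outline, tilt$baseline, tilt$origin)
  slope <- lev$baseline$right_terminus[2] - lev$baseline$left_terminus[2]
  expect_lt(abs(slope), 1e-9)
  expect_equal(lev$baseline$length_B, g$baseline$length_B, tolerance = 1e-12)

  # the 59 lengths are invariant: angles are measured from the baseline
  p_tilt <- measure_profile(tilt$outline, tilt$baseline, tilt$origin)
  p_lev <- measure_profile(lev$outline, lev$baseline, lev$origin)
  expect_equal(p_tilt$measurements$line_length_L,
               p_lev$measurements$line_length_L, tolerance = 1e-9)
})

test_that("eligibility flags mirror the method's inclusion rules", {
  b <- baseline_spec(c(-10, 0), c(10, 0))
  o <- origin_spec(c(0, 0), b)
  # arc entirely below the baseline
  below <- sinus_outline(rbind(c(-10, 0), c(0, -8), c(10, 0)))
  r1 <- check_eligibility(below, b, o)
  expect_false(r1$eligible)
  expect_true("above_baseline" %in% r1$failed)
  # origin at a terminus: midline not spanned
  arc <- sinus_outline(rbind(c(-10, 0), c(0, 9), c(10, 0)))
  r2 <- check_eligibility(arc, b, origin_spec(c(10, 0), b))
  expect_false(r2$eligible)
  expect_true("midline_spanned" %in% r2$failed)
  # arc not anchored on the termini
  loose <- sinus_outline(rbind(c(-7, 0), c(0, 9), c(10, 0)))
  r3 <- check_eligibility(loose, b, o)
  expect_true("arc_continuous" %in% r3$failed)
  # a standard synthetic outline is eligible and fully measurable
  g <- generate_outline(seed = 5)
  expect_true(check_eligibility(g$outline, g$baseline, g$origin)$eligible)
  expect_silent(measure_profile(g$outline, g$baseline, g$origin))
  # measuring an ineligible outline is an error
  expect_error(measure_profile(below, b, o), class = "tdm_geometry_error")
})

test_that("profiles are equivariant to scaling and invariant to rigid motion", {
  g <- generate_outline(seed = 21)
  p0 <- measure_profile(g$outline, g$baseline, g$origin)
  s0 <- standardize_profile(p0)
  for (c_scale in c(0.5, 7)) {
    bs <- baseline_spec(g$baseline$left_terminus * c_scale,
                        g$baseline$right_terminus * c_scale)
    ps <- measure_profile(sinus_outline(g$outline$vertices * c_scale), bs,
                          origin_spec(g$origin$origin * c_scale, bs))
    expect_equal(ps$measurements$line_length_L,
                 p0$measurements$line_length_L * c_scale, tolerance = 1e-9)
    expect_equal(ps$baseline$length_B, p0$baseline$length_B * c_scale)
    expect_equal(ps$origin$midline_ratio_r, p0$origin$midline_ratio_r,
                 tolerance = 1e-12)
    expect_equal(standardize_profile(ps)$s, s0$s, tolerance = 1e-9)
  }
  # rigid motion: rotate 17 degrees and translate (31, -12)
  mv <- function(p) drop(apply_rigid(rbind(p), 17, c(31, -12)))
  bm <- baseline_spec(mv(g$baseline$left_terminus), mv(g$baseline$right_terminus))
  pm <- measure_profile(sinus_outline(apply_rigid(g$outline$vertices, 17, c(31, -12))),
                        bm, origin_spec(mv(g$origin$origin), bm))
  expect_equal(pm$measurements$line_length_L, p0$measurements$line_length_L,
               tolerance = 1e-9)
  expect_equal(pm$origin$midline_ratio_r, p0$origin$midline_ratio_r,
               tolerance = 1e-12)
})

test_that("every ray length equals the brute-force outermost crossing", {
  set.seed(404)
  for (rep in 1:40) {
    g <- generate_outline(outline_params(n_vertices = 121),
                          seed = sample.int(1e6, 1))
    prof <- measure_profile(g$outline, g$baseline, g$origin)
    for (i in seq(1, 59, by = 7)) {
      xc <- oracle_ray_lengths(g$origin$origin, g$baseline$right_terminus,
                               prof$measurements$angle_theta[i],
                               g$outline$vertices)
      expect_equal(prof$measurements$line_length_L[i], max(xc),
                   tolerance = 1e-9)
    }
  }
})
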