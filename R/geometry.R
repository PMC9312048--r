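# Core geometry of the Total Difference Method: the supraorbital baseline,
# the origin on it, the counter-clockwise fan of rays, and ray/outline
# intersection under the outermost-crossing rule.
#
# Coordinate convention: calibrated millimetres, x increasing toward the
# image-right baseline terminus, y increasing superiorly (y-up). Raster
# inputs are converted from y-down at the I/O boundary (see raster-io.R).
# The 0-degree datum is the origin -> right-terminus direction; angles
# increase counter-clockwise, so the ray fan sweeps from just above the
# right baseline arm (3 degrees) to just above the left (177 degrees).

# geometric tolerances (mm); fixed package-wide
TOL_GEOM   <- 1e-9   # intersection merging / rigid-motion checks
TOL_ANCHOR <- 1e-6   # arc endpoint / origin-on-baseline anchoring

rot2 <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

cross2 <- function(ax, ay, bx, by) ax * by - ay * bx

#' Supraorbital baseline specification
#'
#' The baseline is the line demarcating the inferior border of the frontal
#' sinus, running between its left and right termini (image left and image
#' right). Its length standardizes all line lengths in the Total Difference
#' Method.
#'
#' @param left_terminus,right_terminus numeric (x, y) pairs in millimetres.
#' @return An object of class `baseline_spec` with elements `left_terminus`,
#'   `right_terminus` and `length_B` (Euclidean length, mm).
#' @export
#' @examples
#' baseline_spec(c(-30, 0), c(30, 0))
baseline_spec <- function(left_terminus, right_terminus) {
  l <- as_point(left_terminus, "left_terminus")
  r <- as_point(right_terminus, "right_terminus")
  B <- sqrt(sum((r - l)^2))
  if (B <= 0) tdm_geometry_error("baseline termini coincide (zero-length baseline)")
  structure(list(left_terminus = l, right_terminus = r, length_B = B),
            class = "baseline_spec")
}

#' @export
print.baseline_spec <- function(x, ...) {
  cat(sprintf("Sinus baseline: (%.3f, %.3f) -> (%.3f, %.3f), B = %.4f mm\n",
              x$left_terminus[1], x$left_terminus[2],
              x$right_terminus[1], x$right_terminus[2], x$length_B))
  invisible(x)
}

#' Origin specification on the baseline
#'
#' The origin is the point where the facial midline meets the sinus baseline;
#' it is the fulcrum of all 59 measurement rays. The right baseline `RB` runs
#' from the origin to the image-right terminus, and the midline ratio
#' `r = RB / B` summarizes origin placement (about 0.5 when centred).
#'
#' @param origin numeric (x, y) point; must lie on the baseline segment
#'   (anchoring tolerance 1e-6 mm).
#' @param baseline a [baseline_spec()].
#' @return An object of class `origin_spec` with elements `origin`,
#'   `right_baseline_RB`, `midline_ratio_r` and the `baseline`.
#' @export
origin_spec <- function(origin, baseline) {
  stopifnot(inherits(baseline, "baseline_spec"))
  o <- as_point(origin, "origin")
  l <- baseline$left_terminus; r <- baseline$right_terminus
  B <- baseline$length_B
  u <- (r - l) / B
  proj <- sum((o - l) * u)
  perp <- abs(cross2(u[1], u[2], o[1] - l[1], o[2] - l[2]))
  if (perp > TOL_ANCHOR || proj < -TOL_ANCHOR || proj > B + TOL_ANCHOR) {
    tdm_geometry_error("origin does not lie on the baseline segment")
  }
  RB <- sqrt(sum((r - o)^2))
  structure(list(origin = o, right_baseline_RB = RB,
                 midline_ratio_r = RB / B, baseline = baseline),
            class = "origin_spec")
}

#' @export
print.origin_spec <- function(x, ...) {
  cat(sprintf("Origin (%.3f, %.3f): RB = %.4f mm, midline ratio r = %.4f\n",
              x$origin[1], x$origin[2], x$right_baseline_RB, x$midline_ratio_r))
  invisible(x)
}

#' Traced sinus outline
#'
#' An ordered open arc of vertices tracing the lateral and superior sinus
#' border from the left baseline terminus to the right one. The baseline
#' itself implicitly closes the region, which guarantees that every ray from
#' an interior origin meets the arc.
#'
#' @param vertices n x 2 numeric matrix (columns x, y) in millimetres, first
#'   row at the left terminus, last row at the right terminus.
#' @param id character label for the outline.
#' @param scale_mm_per_px calibration used to produce the coordinates
#'   (1 if natively in mm); retained as provenance only.
#' @return Object of class `sinus_outline`.
#' @export
sinus_outline <- function(vertices, id = "outline", scale_mm_per_px = 1) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L) {
    tdm_config_error("outline needs an n x 2 vertex matrix with n >= 3")
  }
  if (!all(is.finite(v))) tdm_config_error("outline vertices must be finite")
  storage.mode(v) <- "double"
  dup <- sqrt(rowSums((v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2)) == 0
  if (any(dup)) tdm_config_error("consecutive outline vertices must be distinct")
  if (!is.numeric(scale_mm_per_px) || scale_mm_per_px <= 0) {
    tdm_config_error("scale_mm_per_px must be positive")
  }
  dimnames(v) <- list(NULL, c("x", "y"))
  structure(list(vertices = v, id = as.character(id),
                 scale_mm_per_px = scale_mm_per_px),
            class = "sinus_outline")
}

#' @export
print.sinus_outline <- function(x, ...) {
  cat(sprintf("Sinus outline '%s': %d vertices, x [%.2f, %.2f] mm, y [%.2f, %.2f] mm\n",
              x$id, nrow(x$vertices),
              min(x$vertices[, 1]), max(x$vertices[, 1]),
              min(x$vertices[, 2]), max(x$vertices[, 2])))
  invisible(x)
}

#' Measurement-ray angles
#'
#' The Total Difference Method measures the outline along rays at 3-degree
#' intervals swept counter-clockwise from 3 to 177 degrees, giving 59 lines.
#'
#' @param start_deg,step_deg,end_deg fan parameters in degrees; the default
#'   (3, 3, 177) is the standard 59-ray fan.
#' @return Numeric vector of angles in ascending order.
#' @export
#' @examples
#' length(ray_angles())  # 59
ray_angles <- function(start_deg = 3, step_deg = 3, end_deg = 177) {
  if (!is.finite(start_deg) || !is.finite(step_deg) || !is.finite(end_deg)) {
    tdm_config_error("ray angles must be finite")
  }
  if (start_deg <= 0 || end_deg >= 180) {
    tdm_config_error("ray angles must lie strictly inside (0, 180) degrees")
  }
  if (step_deg <= 0 || start_deg > end_deg) {
    tdm_config_error("need step_deg > 0 and start_deg <= end_deg")
  }
  n_steps <- (end_deg - start_deg) / step_deg
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    tdm_config_error("(end_deg - start_deg) must be divisible by step_deg")
  }
  start_deg + step_deg * seq(0L, round(n_steps))
}

# direction of the theta-degree ray: theta measured CCW from the
# origin -> right-terminus axis
ray_direction <- function(origin, baseline, theta_deg) {
  u <- baseline$right_terminus - origin
  nu <- sqrt(sum(u^2))
  if (nu <= 0) tdm_geometry_error("origin coincides with the right terminus")
  drop(rot2(theta_deg) %*% (u / nu))
}

#' Cast one measurement ray against the outline
#'
#' Intersects the half-line from the origin at `theta_deg` (counter-clockwise
#' from the origin-to-right-terminus direction) with every outline segment.
#' When the ray crosses the outline more than once, the outermost crossing
#' (maximal distance from the origin) is used; crossings closer together than
#' 1e-9 mm (e.g. exact vertex hits shared by two segments) are merged.
#'
#' @param origin an [origin_spec()] (preferred), or a numeric (x, y) point if
#'   `baseline` is supplied separately.
#' @param theta_deg angle in (0, 180) degrees.
#' @param outline a [sinus_outline()].
#' @param baseline a [baseline_spec()]; ignored when `origin` is an
#'   `origin_spec`.
#' @return A one-row data.frame (class `ray_measurement`) with columns
#'   `angle_theta`, `x`, `y` (intersection), `line_length_L` (mm),
#'   `n_crossings`, `outermost_used`.
#' @export
cast_ray <- function(origin, theta_deg, outline, baseline = NULL) {
  if (inherits(origin, "origin_spec")) {
    baseline <- origin$baseline
    o <- origin$origin
  } else {
    if (is.null(baseline)) tdm_config_error("baseline required when origin is a bare point")
    o <- as_point(origin, "origin")
  }
  if (theta_deg <= 0 || theta_deg >= 180) {
    tdm_config_error("ray angle must lie strictly inside (0, 180) degrees")
  }
  d <- ray_direction(o, baseline, theta_deg)
  v <- outline$vertices
  p1 <- v[-nrow(v), , drop = FALSE]
  e  <- v[-1L, , drop = FALSE] - p1
  wx <- p1[, 1] - o[1]; wy <- p1[, 2] - o[2]
  denom <- cross2(d[1], d[2], e[, 1], e[, 2])
  ok <- abs(denom) > .Machine$double.eps
  t_hit <- cross2(wx, wy, e[, 1], e[, 2]) / denom
  s_hit <- cross2(wx, wy, d[1], d[2]) / denom
  seg_len <- sqrt(rowSums(e^2))
  s_tol <- TOL_GEOM / seg_len
  keep <- ok & t_hit >= -TOL_GEOM & s_hit >= -s_tol & s_hit <= 1 + s_tol
  t_all <- sort(pmax(t_hit[keep], 0))
  if (length(t_all) == 0L) {
    tdm_geometry_error(sprintf("ray at %g degrees does not intersect the outline", theta_deg))
  }
  # merge crossings within 1e-9 mm (vertex-exact hits appear once per segment)
  merged <- t_all[c(TRUE, diff(t_all) > TOL_GEOM)]
  L <- merged[length(merged)]
  structure(
    data.frame(angle_theta = theta_deg,
               x = o[1] + L * d[1], y = o[2] + L * d[2],
               line_length_L = L,
               n_crossings = length(merged),
               outermost_used = length(merged) > 1L),
    class = c("ray_measurement", "data.frame"))
}

#' Measure the full ray profile of an outline
#'
#' Collects one ray measurement per angle (by default the 59 angles from 3 to
#' 177 degrees) from the origin to the outline, applying the outermost-
#' crossing rule at every angle.
#'
#' @param outline a [sinus_outline()].
#' @param baseline a [baseline_spec()]; may be omitted when `origin` carries it.
#' @param origin an [origin_spec()].
#' @param angles ascending angles in degrees; default [ray_angles()].
#' @param check if `TRUE` (default) the outline is checked for eligibility
#'   first and an ineligible outline is an error.
#' @return Object of class `sinus_profile`: list with `outline_id`,
#'   `baseline`, `origin`, `measurements` (data.frame, one row per angle),
#'   and optional `area` / `perimeter` (mm^2 / mm, filled by the raster path).
#' @export
measure_profile <- function(outline, baseline = origin$baseline, origin,
                            angles = ray_angles(), check = TRUE) {
  stopifnot(inherits(outline, "sinus_outline"), inherits(origin, "origin_spec"))
  if (is.unsorted(angles, strictly = TRUE)) {
    tdm_config_error("angles must be strictly ascending")
  }
  if (check) {
    elig <- check_eligibility(outline, baseline, origin)
    if (!elig$eligible) {
      tdm_geometry_error(paste0("outline fails eligibility: ",
                                paste(elig$failed, collapse = ", ")))
    }
  }
  rows <- lapply(angles, function(a) {
    tryCatch(cast_ray(origin, a, outline, baseline),
             tdm_geometry_error = function(e) {
               tdm_geometry_error(sprintf("measurement failed at %g degrees: %s",
                                          a, conditionMessage(e)))
             })
  })
  meas <- do.call(rbind, rows)
  rownames(meas) <- NULL
  structure(list(outline_id = outline$id, baseline = baseline, origin = origin,
                 measurements = meas, area = NA_real_, perimeter = NA_real_),
            class = "sinus_profile")
}

#' @export
print.sinus_profile <- function(x, ...) {
  cat(sprintf("Sinus profile '%s': %d rays, L in [%.3f, %.3f] mm, B = %.3f mm, r = %.3f\n",
              x$outline_id, nrow(x$measurements),
              min(x$measurements$line_length_L), max(x$measurements$line_length_L),
              x$baseline$length_B, x$origin$midline_ratio_r))
  invisible(x)
}

#' Place the origin from a facial midline
#'
#' The origin is the intersection of the facial midline (given by two points
#' on it) with the baseline segment.
#'
#' @param midline_a,midline_b two distinct (x, y) points on the facial
#'   midline.
#' @param baseline a [baseline_spec()].
#' @return An [origin_spec()].
#' @export
#' @examples
#' b <- baseline_spec(c(-10, 0), c(10, 0))
#' place_origin(c(0, -5), c(0, 5), b)  # origin at (0,0), r = 0.5
place_origin <- function(midline_a, midline_b, baseline) {
  stopifnot(inherits(baseline, "baseline_spec"))
  a <- as_point(midline_a, "midline_a"); b <- as_point(midline_b, "midline_b")
  if (identical(a, b)) tdm_config_error("midline points must be distinct")
  l <- baseline$left_terminus; r <- baseline$right_terminus
  dm <- b - a          # midline direction
  db <- r - l          # baseline direction
  denom <- cross2(dm[1], dm[2], db[1], db[2])
  if (abs(denom) < .Machine$double.eps * max(abs(c(dm, db)), 1)) {
    tdm_geometry_error("midline is parallel to the baseline; origin undefined")
  }
  # l + s*db = a + t*dm  ->  s = cross(a - l, dm) / cross(db, dm)
  s <- cross2(a[1] - l[1], a[2] - l[2], dm[1], dm[2]) /
       cross2(db[1], db[2], dm[1], dm[2])
  if (s < -TOL_ANCHOR / baseline$length_B || s > 1 + TOL_ANCHOR / baseline$length_B) {
    tdm_geometry_error("midline meets the baseline outside the baseline segment")
  }
  origin_spec(l + pmin(pmax(s, 0), 1) * db, baseline)
}

#' Midline ratio of an origin
#'
#' Right baseline length divided by total baseline length; dimensionless,
#' scale-invariant, about 0.5 for a centred origin.
#'
#' @param origin an [origin_spec()].
#' @return The ratio in \[0, 1\].
#' @export
midline_ratio <- function(origin) {
  stopifnot(inherits(origin, "origin_spec"))
  origin$midline_ratio_r
}

#' Line length from an angle-tool perimeter
#'
#' ImageJ's angle tool reports the combined length of both arms of the angle:
#' the fixed arm (the right baseline, origin to right terminus) plus the
#' movable arm (origin to the outline). The line length used by the method is
#' the perimeter minus the right baseline.
#'
#' @param angle_perimeter_P combined arm length, mm.
#' @param right_baseline_RB fixed-arm length, mm.
#' @return Movable-arm (line) length, mm.
#' @export
line_length_from_perimeter <- function(angle_perimeter_P, right_baseline_RB) {
  if (any(!is.finite(angle_perimeter_P)) || any(!is.finite(right_baseline_RB))) {
    tdm_config_error("perimeter and right baseline must be finite")
  }
  if (any(right_baseline_RB < 0) || any(angle_perimeter_P < right_baseline_RB)) {
    tdm_data_error("angle perimeter smaller than the right baseline: inconsistent export")
  }
  angle_perimeter_P - right_baseline_RB
}

#' Rotate outline, baseline and origin rigidly about the origin
#'
#' Used to level a tilted radiograph: rotating by minus the baseline's
#' inclination makes the supraorbital line horizontal. All pairwise distances
#' (hence B, RB and every ray length, which are measured relative to the
#' baseline direction) are preserved.
#'
#' @param outline a [sinus_outline()].
#' @param baseline a [baseline_spec()]; defaults to the one in `origin`.
#' @param origin an [origin_spec()].
#' @param angle_deg rotation angle (counter-clockwise, degrees). The default
#'   levels the baseline to 0 degrees.
#' @return List with rotated `outline`, `baseline`, `origin`.
#' @export
rotate_to_level <- function(outline, baseline = origin$baseline, origin,
                            angle_deg = NULL) {
  stopifnot(inherits(outline, "sinus_outline"), inherits(origin, "origin_spec"))
  if (is.null(angle_deg)) {
    db <- baseline$right_terminus - baseline$left_terminus
    angle_deg <- -atan2(db[2], db[1]) * 180 / pi
  }
  if (!is.finite(angle_deg)) tdm_config_error("rotation angle must be finite")
  R <- rot2(angle_deg)
  o <- origin$origin
  rot_pt <- function(p) drop(R %*% (p - o)) + o
  v <- t(R %*% (t(outline$vertices) - o)) + rep(o, each = nrow(outline$vertices))
  new_outline <- sinus_outline(v, id = outline$id,
                               scale_mm_per_px = outline$scale_mm_per_px)
  new_baseline <- baseline_spec(rot_pt(baseline$left_terminus),
                                rot_pt(baseline$right_terminus))
  list(outline = new_outline, baseline = new_baseline,
       origin = origin_spec(o, new_baseline))
}

#' Check outline eligibility for the Total Difference Method
#'
#' The method requires a sinus that rises above the supraorbital baseline, is
#' localized over the midline (the origin falls strictly between the baseline
#' termini), and whose lobes touch (the traced arc is a single connected
#' chain anchored on both termini). Eligibility guarantees that every
#' measurement ray in (0, 180) degrees meets the arc.
#'
#' @param outline a [sinus_outline()].
#' @param baseline a [baseline_spec()]; defaults to the one in `origin`.
#' @param origin an [origin_spec()].
#' @return List (class `eligibility_report`) with logical flags
#'   `above_baseline`, `midline_spanned`, `arc_continuous`, the overall
#'   `eligible`, and `failed` (names of failed flags).
#' @export
check_eligibility <- function(outline, baseline = origin$baseline, origin) {
  stopifnot(inherits(outline, "sinus_outline"),
            inherits(baseline, "baseline_spec"),
            inherits(origin, "origin_spec"))
  l <- baseline$left_terminus; r <- baseline$right_terminus
  B <- baseline$length_B
  u <- (r - l) / B
  v <- outline$vertices
  # signed height of each vertex above the baseline line (left-handed: CCW
  # positive means "superior" given x toward the right terminus)
  h <- cross2(u[1], u[2], v[, 1] - l[1], v[, 2] - l[2])
  above_baseline <- any(h > TOL_ANCHOR) && all(h >= -TOL_ANCHOR)
  proj <- sum((origin$origin - l) * u)
  midline_spanned <- proj > TOL_ANCHOR && proj < B - TOL_ANCHOR
  d_first <- sqrt(sum((v[1L, ] - l)^2))
  d_last  <- sqrt(sum((v[nrow(v), ] - r)^2))
  arc_continuous <- d_first <= TOL_ANCHOR && d_last <= TOL_ANCHOR
  flags <- c(above_baseline = above_baseline,
             midline_spanned = midline_spanned,
             arc_continuous = arc_continuous)
  structure(list(above_baseline = above_baseline,
                 midline_spanned = midline_spanned,
                 arc_continuous = arc_continuous,
                 eligible = all(flags),
                 failed = names(flags)[!flags]),
            class = "eligibility_report")
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat(sprintf("Eligibility: %s (above_baseline=%s, midline_spanned=%s, arc_continuous=%s)\n",
              if (x$eligible) "ELIGIBLE" else "INELIGIBLE",
              x$above_baseline, x$midline_spanned, x$arc_continuous))
  invisible(x)
}
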