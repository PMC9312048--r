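# Measurement-aid overlay: the fan of 3-degree rays on a level baseline that
# observers align over a sinus outline to guide line placement. The overlay
# is produced both as a vector description (exact segment endpoints, also
# exportable as SVG) and as a rasterized PNG for visual use.

#' Build a measurement-aid overlay
#'
#' One ray per angle emanates from a marked origin on a horizontal baseline;
#' the default fan is the 59 rays from 3 to 177 degrees. Rays are clipped to
#' the canvas.
#'
#' @param angles ray angles in degrees, default [ray_angles()]; all must lie
#'   strictly inside (0, 180).
#' @param baseline_length_px canvas width = baseline length, pixels.
#' @param origin_ratio position of the origin along the baseline, as the
#'   right-baseline fraction (0.5 = centred).
#' @param height_px canvas height; default 60 percent of the width.
#' @return Object of class `tdm_overlay`: list with `segments` (data.frame
#'   `angle`, `x0`, `y0`, `x1`, `y1` in pixel y-up coordinates with the
#'   origin of axes at the baseline's left end), `origin` (x, y), `width`,
#'   `height`.
#' @export
render_overlay <- function(angles = ray_angles(), baseline_length_px = 1000,
                           origin_ratio = 0.5,
                           height_px = round(0.6 * baseline_length_px)) {
  if (any(angles <= 0 | angles >= 180)) {
    tdm_config_error("overlay rays must lie strictly inside (0, 180) degrees")
  }
  if (baseline_length_px <= 0 || height_px <= 0) {
    tdm_config_error("canvas dimensions must be positive")
  }
  if (origin_ratio <= 0 || origin_ratio >= 1) {
    tdm_config_error("origin_ratio must be strictly inside (0, 1)")
  }
  ox <- (1 - origin_ratio) * baseline_length_px
  th <- angles * pi / 180
  dx <- cos(th); dy <- sin(th)
  # clip each ray to the canvas [0, W] x [0, H]
  t_x <- ifelse(dx > 0, (baseline_length_px - ox) / dx,
                ifelse(dx < 0, -ox / dx, Inf))
  t_y <- height_px / dy
  t_end <- pmin(t_x, t_y)
  segments <- data.frame(angle = angles, x0 = ox, y0 = 0,
                         x1 = ox + t_end * dx, y1 = t_end * dy)
  structure(list(segments = segments, origin = c(ox, 0),
                 width = baseline_length_px, height = height_px),
            class = "tdm_overlay")
}

#' @export
print.tdm_overlay <- function(x, ...) {
  cat(sprintf("Measurement overlay: %d rays (%g to %g degrees), %d x %d px, origin at x = %.1f\n",
              nrow(x$segments), min(x$segments$angle), max(x$segments$angle),
              x$width, x$height, x$origin[1]))
  invisible(x)
}

#' Write an overlay as SVG
#'
#' @param overlay a [render_overlay()] result.
#' @param path output .svg path.
#' @param stroke stroke colour of rays and baseline.
#' @return `path`, invisibly.
#' @export
write_overlay_svg <- function(overlay, path, stroke = "#d4b106") {
  stopifnot(inherits(overlay, "tdm_overlay"))
  W <- overlay$width; H <- overlay$height
  flip <- function(y) H - y  # SVG is y-down
  seg <- overlay$segments
  lines <- sprintf(
    '  <line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="%s" stroke-width="1"/>',
    seg$x0, flip(seg$y0), seg$x1, flip(seg$y1), stroke)
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">', W, H),
           sprintf('  <line x1="0" y1="%.2f" x2="%d" y2="%.2f" stroke="%s" stroke-width="2"/>',
                   flip(0), W, flip(0), stroke),
           lines,
           sprintf('  <circle cx="%.2f" cy="%.2f" r="4" fill="%s"/>',
                   overlay$origin[1], flip(overlay$origin[2]), stroke),
           '</svg>')
  writeLines(svg, path)
  invisible(path)
}

#' Write an overlay as a raster PNG
#'
#' White canvas with dark rays, baseline and origin marker; suitable for
#' semi-transparent placement over a radiograph.
#'
#' @param overlay a [render_overlay()] result.
#' @param path output .png path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(overlay, path) {
  stopifnot(inherits(overlay, "tdm_overlay"))
  W <- ceiling(overlay$width); H <- ceiling(overlay$height)
  canvas <- matrix(1, H, W)
  draw_segment <- function(canvas, x0, y0, x1, y1) {
    len <- max(abs(x1 - x0), abs(y1 - y0))
    t <- seq(0, 1, length.out = max(2L, 2L * ceiling(len)))
    xs <- pmin(pmax(round(x0 + t * (x1 - x0)), 1L), W)
    ys <- pmin(pmax(round(H - (y0 + t * (y1 - y0))), 1L), H)  # y-up -> row
    canvas[cbind(ys, xs)] <- 0
    canvas
  }
  seg <- overlay$segments
  for (i in seq_len(nrow(seg))) {
    canvas <- draw_segment(canvas, seg$x0[i], seg$y0[i], seg$x1[i], seg$y1[i])
  }
  canvas <- draw_segment(canvas, 1, 0, W, 0)
  ox <- overlay$origin[1]
  canvas <- draw_segment(canvas, ox - 4, 4, ox + 4, 4)
  png::writePNG(canvas, path)
  invisible(path)
}
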