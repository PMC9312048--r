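# Raster interoperability: orbital-breadth scale calibration, binary-mask
# outer-contour extraction (area, perimeter, and the above-baseline arc),
# and rasterization of vector outlines for round-trip validation.
#
# Raster pixels are indexed (row, col) with row 1 at the top (y-down, as in
# PNG/TIFF). All conversion to the package's y-up millimetre frame happens
# in this file and nowhere else: a corner point (x_px, y_px) of the pixel
# grid maps to (x_px * s, (H - y_px) * s) mm, where H is the image height in
# pixels and s the calibration in mm/px.

#' Calibrated raster image
#'
#' @param pixels numeric or logical matrix, row 1 at the top; nonzero /
#'   `TRUE` is foreground for binary masks.
#' @param mm_per_px calibration, millimetres per pixel (> 0).
#' @return Object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, mm_per_px = 1) {
  if (!is.matrix(pixels)) tdm_config_error("pixels must be a matrix")
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1L || !is.finite(mm_per_px) ||
      mm_per_px <= 0) {
    tdm_config_error("mm_per_px must be a positive scalar")
  }
  structure(list(pixels = pixels, mm_per_px = mm_per_px),
            class = "calibrated_image")
}

#' Scale calibration from an orbital-breadth landmark pair
#'
#' Radiographs carry no physical scale, so every image is calibrated by
#' setting the left orbital breadth (dacryon to ectoconchion) to a reference
#' value; the default 39.49 mm is the grand mean orbital breadth of the
#' Howells craniometric dataset.
#'
#' @param p_dacryon,p_ectoconchion landmark positions in pixels (x, y).
#' @param target_mm known physical length of the segment, mm.
#' @return Calibration in mm per pixel.
#' @export
#' @examples
#' calibrate_scale(c(0, 0), c(200, 0))  # 39.49 / 200
calibrate_scale <- function(p_dacryon, p_ectoconchion, target_mm = 39.49) {
  a <- as_point(p_dacryon, "p_dacryon")
  b <- as_point(p_ectoconchion, "p_ectoconchion")
  if (!is.finite(target_mm) || target_mm <= 0) {
    tdm_config_error("target_mm must be positive")
  }
  d <- sqrt(sum((b - a)^2))
  if (d == 0) tdm_geometry_error("landmark points coincide; scale undefined")
  target_mm / d
}

#' Read a binary mask from PNG or TIFF
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param mm_per_px calibration to attach, e.g. from [calibrate_scale()].
#' @param threshold values > threshold (after averaging channels) are
#'   foreground.
#' @return A [calibrated_image()] with logical pixels.
#' @export
read_mask <- function(path, mm_per_px = 1, threshold = 0.5) {
  if (!file.exists(path)) tdm_data_error(paste("file not found:", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    tdm_data_error(paste("unsupported mask format:", ext)))
  if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE], c(1, 2), mean)
  calibrated_image(img > threshold, mm_per_px)
}

#' Write a binary mask as PNG
#'
#' @param image a [calibrated_image()] (logical or numeric pixels).
#' @param path output .png path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  storage.mode(px) <- "double"
  png::writePNG(pmin(pmax(px, 0), 1), path)
  invisible(path)
}

# 8-connected foreground labeling by iterative flood fill (vectorized
# frontier expansion); masks here are modest so this stays fast.
label_components <- function(fg) {
  H <- nrow(fg); W <- ncol(fg)
  lab <- matrix(0L, H, W)
  nlab <- 0L
  todo <- which(fg)
  while (length(todo)) {
    nlab <- nlab + 1L
    frontier <- todo[1L]
    lab[frontier] <- nlab
    while (length(frontier)) {
      i <- (frontier - 1L) %% H + 1L
      j <- (frontier - 1L) %/% H + 1L
      nb_i <- rep(i, each = 8L) + c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
      nb_j <- rep(j, each = 8L) + c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
      ok <- nb_i >= 1L & nb_i <= H & nb_j >= 1L & nb_j <= W
      idx <- unique((nb_j[ok] - 1L) * H + nb_i[ok])
      idx <- idx[fg[idx] & lab[idx] == 0L]
      lab[idx] <- nlab
      frontier <- idx
    }
    todo <- todo[lab[todo] == 0L]
  }
  list(labels = lab, n = nlab)
}

# Crack-boundary trace of the single foreground component: returns the
# closed polygon through pixel corners (x_px in 0..W, y_px in 0..H, y-down),
# walked with the foreground on the right-hand side.
trace_crack_boundary <- function(fg) {
  H <- nrow(fg); W <- ncol(fg)
  at <- function(i, j) i >= 1L && i <= H && j >= 1L && j <= W && fg[i, j]
  start_idx <- which(fg)
  if (!length(start_idx)) tdm_data_error("empty mask: nothing to trace")
  i0 <- min((start_idx - 1L) %% H + 1L)
  j0 <- min((which(fg[i0, ])))
  # start at the top-left corner of the topmost-leftmost pixel, heading east
  sx <- j0 - 1L; sy <- i0 - 1L
  dirs <- matrix(c(1L, 0L, 0L, 1L, -1L, 0L, 0L, -1L), 2L)  # E S W N (y-down)
  d <- 1L
  x <- sx; y <- sy
  pts_x <- integer(0); pts_y <- integer(0)
  repeat {
    pts_x <- c(pts_x, x); pts_y <- c(pts_y, y)
    x <- x + dirs[1L, d]; y <- y + dirs[2L, d]
    # pixels ahead of the new corner, right and left of the travel direction
    ar <- switch(d, at(y + 1L, x + 1L), at(y + 1L, x),     at(y, x),      at(y, x + 1L))
    al <- switch(d, at(y, x + 1L),      at(y + 1L, x + 1L), at(y + 1L, x), at(y, x))
    if (!ar)      d <- d %% 4L + 1L          # turn right
    else if (al)  d <- (d + 2L) %% 4L + 1L   # turn left
    if (x == sx && y == sy && d == 1L) break
    if (length(pts_x) > 4L * (H + 2L) * (W + 2L)) {
      tdm_data_error("boundary trace failed to close")  # defensive; unreachable
    }
  }
  cbind(x = pts_x, y = pts_y)
}

#' Region area and perimeter
#'
#' @param area region area, mm^2.
#' @param perimeter boundary length, mm.
#' @return Object of class `region_stats`.
#' @export
region_stats <- function(area, perimeter) {
  if (area <= 0) tdm_data_error("area must be > 0 for a nonempty region")
  structure(list(area = area, perimeter = perimeter), class = "region_stats")
}

#' Extract the outer sinus contour from a binary mask
#'
#' Identifies the single 8-connected foreground component, measures its area
#' (foreground pixel count times mm_per_px^2) and perimeter (length of the
#' crack-boundary polygon, i.e. the edges separating foreground from
#' background pixels), and extracts the above-baseline portion of the outer
#' boundary as a left-to-right [sinus_outline()] anchored at its baseline
#' crossings. Holes and internal septa are ignored: only the outer boundary
#' is traced.
#'
#' @param image a [calibrated_image()] binary mask.
#' @param baseline_row pixel row whose lower edge carries the supraorbital
#'   baseline; boundary at or below this line is discarded.
#' @param id label for the resulting outline.
#' @param smooth_window width (in crack corners, i.e. pixels) of the moving
#'   average applied to the extracted arc for sub-pixel accuracy. The crack
#'   boundary is a staircase of unit edges; rays that run nearly parallel to
#'   the local boundary would otherwise snag on staircase corners. The
#'   default 5 removes the staircase while rounding genuine corners by only
#'   about 2 px. Use 1 to keep the raw crack polygon.
#' @return List with `outline` ([sinus_outline()]), `baseline`
#'   ([baseline_spec()] spanning the arc's baseline crossings), and `stats`
#'   ([region_stats()]).
#' @export
extract_outer_contour <- function(image, baseline_row, id = "mask",
                                  smooth_window = 5L) {
  stopifnot(inherits(image, "calibrated_image"))
  fg <- image$pixels
  if (!is.logical(fg)) fg <- fg > 0
  s <- image$mm_per_px
  H <- nrow(fg)
  if (!any(fg)) tdm_data_error("empty mask: no foreground component")
  comp <- label_components(fg)
  if (comp$n > 1L) {
    tdm_data_error(sprintf(
      "mask has %d foreground components; lobes must touch (single component required)",
      comp$n))
  }
  area <- sum(fg) * s^2
  poly <- trace_crack_boundary(fg)
  perim <- nrow(poly) * s  # unit-length crack edges
  if (!is.numeric(baseline_row) || baseline_row < 1 || baseline_row > H) {
    tdm_config_error("baseline_row must index a pixel row of the mask")
  }
  yb <- baseline_row  # baseline = lower edge of this row, corner coords
  above <- poly[, "y"] < yb
  if (!any(above)) tdm_data_error("no boundary above the baseline row")
  # longest cyclic run of above-baseline corners
  n <- nrow(poly)
  r <- rle(above[c(seq_len(n), seq_len(n))])
  ends <- cumsum(r$lengths)
  runs <- which(r$values & r$lengths < 2L * n)
  best <- runs[which.max(r$lengths[runs])]
  i1 <- ends[best] - r$lengths[best] + 1L
  idx <- ((i1 - 1L):(ends[best] - 1L)) %% n + 1L
  arc <- poly[idx, , drop = FALSE]
  # clip the entering and leaving edges to the baseline level (crack edges
  # are axis-aligned, so the crossings sit at integer x on the baseline)
  arc <- rbind(c(arc[1L, "x"], yb), arc, c(arc[nrow(arc), "x"], yb))
  same_as_prev <- c(FALSE, rowSums(abs(arc[-1L, , drop = FALSE] -
                                       arc[-nrow(arc), , drop = FALSE])) == 0)
  arc <- arc[!same_as_prev, , drop = FALSE]
  if (arc[1L, "x"] > arc[nrow(arc), "x"]) arc <- arc[rev(seq_len(nrow(arc))), ]
  if (smooth_window > 1L) {
    arc <- smooth_open_polyline(arc, smooth_window)
  } else {
    arc <- simplify_collinear_open(arc)
  }
  # to mm, y-up
  v <- cbind(arc[, 1] * s, (H - arc[, 2]) * s)
  outline <- sinus_outline(v, id = id, scale_mm_per_px = s)
  baseline <- baseline_spec(v[1L, ], v[nrow(v), ])
  list(outline = outline, baseline = baseline,
       stats = region_stats(area, perim))
}

# centred moving average along an open polyline; endpoints stay pinned
# (padded with themselves), so baseline anchoring is preserved exactly
smooth_open_polyline <- function(p, window) {
  w <- as.integer(window)
  if (w %% 2L == 0L) w <- w + 1L
  n <- nrow(p)
  if (n <= w) return(p)
  h <- (w - 1L) %/% 2L
  pad <- rbind(p[rep(1L, h), , drop = FALSE], p, p[rep(n, h), , drop = FALSE])
  sm <- apply(pad, 2L, function(col) as.numeric(stats::filter(col, rep(1 / w, w))))
  sm <- sm[(h + 1L):(h + n), , drop = FALSE]
  sm[1L, ] <- p[1L, ]; sm[n, ] <- p[n, ]
  # drop any vertices collapsed by the averaging
  same <- c(FALSE, rowSums(abs(sm[-1L, , drop = FALSE] -
                               sm[-n, , drop = FALSE])) == 0)
  sm[!same, , drop = FALSE]
}

# collinear simplification for an open polyline, endpoints always kept
simplify_collinear_open <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(p)
  prev <- p[-c(n - 1L, n), , drop = FALSE]
  cur <- p[-c(1L, n), , drop = FALSE]
  nxt <- p[-c(1L, 2L), , drop = FALSE]
  col_x <- prev[, 1] == cur[, 1] & nxt[, 1] == cur[, 1]
  col_y <- prev[, 2] == cur[, 2] & nxt[, 2] == cur[, 2]
  p[c(TRUE, !(col_x | col_y), TRUE), , drop = FALSE]
}

#' Rasterize an outline into a binary mask
#'
#' Fills the region enclosed by the arc and its baseline on a pixel grid
#' (even-odd scanline fill; a pixel is foreground when its centre falls
#' inside). The outline must be leveled with its baseline horizontal (use
#' [rotate_to_level()] first); the baseline becomes the bottom edge of the
#' image's last row.
#'
#' @param outline a [sinus_outline()].
#' @param baseline its [baseline_spec()].
#' @param mm_per_px pixel size of the target grid.
#' @param margin_px background margin added left, right and above.
#' @return List with `image` ([calibrated_image()]), `baseline_row` (pixel
#'   row whose lower edge is the baseline), and `x0_mm` (mm x-coordinate of
#'   the image's left edge), suitable for [extract_outer_contour()].
#' @export
rasterize_outline <- function(outline, baseline, mm_per_px, margin_px = 2L) {
  stopifnot(inherits(outline, "sinus_outline"), inherits(baseline, "baseline_spec"))
  v <- outline$vertices
  yb <- baseline$left_terminus[2]
  if (abs(baseline$right_terminus[2] - yb) > TOL_ANCHOR) {
    tdm_geometry_error("outline must be leveled before rasterization")
  }
  s <- mm_per_px
  x0 <- min(v[, 1]) - margin_px * s
  W <- ceiling((max(v[, 1]) - x0) / s) + margin_px
  Hpx <- ceiling((max(v[, 2]) - yb) / s) + margin_px
  # closed polygon: arc plus the baseline return edge
  px <- (v[, 1] - x0) / s
  py <- Hpx - (v[, 2] - yb) / s
  px <- c(px, px[1L]); py <- c(py, py[1L])
  # edges
  ex1 <- px[-length(px)]; ey1 <- py[-length(py)]
  ex2 <- px[-1L]; ey2 <- py[-1L]
  fg <- matrix(FALSE, Hpx, W)
  for (i in seq_len(Hpx)) {
    yc <- i - 0.5
    cross <- (ey1 <= yc & ey2 > yc) | (ey2 <= yc & ey1 > yc)
    if (!any(cross)) next
    xc <- ex1[cross] + (yc - ey1[cross]) / (ey2[cross] - ey1[cross]) *
      (ex2[cross] - ex1[cross])
    xc <- sort(xc)
    for (k in seq(1L, length(xc) - 1L, by = 2L)) {
      j1 <- ceiling(xc[k] + 0.5); j2 <- floor(xc[k + 1L] + 0.5)
      if (j2 >= j1) fg[i, max(1L, j1):min(W, j2)] <- TRUE
    }
  }
  list(image = calibrated_image(fg, s), baseline_row = Hpx, x0_mm = x0)
}
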