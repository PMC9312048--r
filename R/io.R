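# Plain-text serialization: outlines as CSV (one vertex per row), baseline/
# origin/calibration as a JSON sidecar, profiles and rankings as CSV/TSV.

#' Write sinus outlines as CSV
#'
#' Columns: `id`, `vertex_index` (1-based, left terminus first), `x_mm`,
#' `y_mm`.
#'
#' @param outlines a [sinus_outline()] or a list of them.
#' @param path output .csv path.
#' @return `path`, invisibly.
#' @export
write_outline_csv <- function(outlines, path) {
  if (inherits(outlines, "sinus_outline")) outlines <- list(outlines)
  rows <- lapply(outlines, function(o) {
    stopifnot(inherits(o, "sinus_outline"))
    data.frame(id = o$id, vertex_index = seq_len(nrow(o$vertices)),
               x_mm = o$vertices[, 1], y_mm = o$vertices[, 2],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read sinus outlines from CSV
#'
#' @param path CSV with columns `id`, `vertex_index`, `x_mm`, `y_mm`.
#' @param scale_mm_per_px calibration to attach to the outlines.
#' @return Named list of [sinus_outline()]s.
#' @export
read_outline_csv <- function(path, scale_mm_per_px = 1) {
  if (!file.exists(path)) tdm_data_error(paste("file not found:", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "vertex_index", "x_mm", "y_mm")
  if (!all(need %in% names(d))) {
    tdm_data_error(paste("outline CSV must have columns:", paste(need, collapse = ", ")))
  }
  by_id <- split(d, d$id)
  lapply(by_id, function(g) {
    g <- g[order(g$vertex_index), ]
    sinus_outline(cbind(g$x_mm, g$y_mm), id = g$id[1L],
                  scale_mm_per_px = scale_mm_per_px)
  })
}

#' Write the baseline/origin/calibration sidecar
#'
#' @param path output .json path.
#' @param baseline a [baseline_spec()].
#' @param origin an [origin_spec()] (optional).
#' @param mm_per_px calibration (optional).
#' @return `path`, invisibly.
#' @export
write_sidecar_json <- function(path, baseline, origin = NULL, mm_per_px = 1) {
  stopifnot(inherits(baseline, "baseline_spec"))
  obj <- list(baseline = list(left_terminus = baseline$left_terminus,
                              right_terminus = baseline$right_terminus,
                              length_B = baseline$length_B),
              calibration = list(mm_per_px = mm_per_px))
  if (!is.null(origin)) {
    stopifnot(inherits(origin, "origin_spec"))
    obj$origin <- list(point = origin$origin,
                       right_baseline_RB = origin$right_baseline_RB,
                       midline_ratio_r = origin$midline_ratio_r)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a baseline/origin/calibration sidecar
#'
#' @param path .json path written by [write_sidecar_json()].
#' @return List with `baseline`, `origin` (or `NULL`), `mm_per_px`.
#' @export
read_sidecar_json <- function(path) {
  if (!file.exists(path)) tdm_data_error(paste("file not found:", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$baseline)) tdm_data_error("sidecar JSON lacks a baseline block")
  baseline <- baseline_spec(obj$baseline$left_terminus, obj$baseline$right_terminus)
  origin <- if (!is.null(obj$origin)) origin_spec(obj$origin$point, baseline)
  list(baseline = baseline, origin = origin,
       mm_per_px = if (!is.null(obj$calibration$mm_per_px)) obj$calibration$mm_per_px else 1)
}

#' Write a measured profile as CSV
#'
#' One row per angle with the raw and baseline-standardized lengths.
#'
#' @param profile a [measure_profile()] result.
#' @param path output .csv path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "sinus_profile"))
  m <- profile$measurements
  out <- data.frame(outline_id = profile$outline_id,
                    angle_theta = m$angle_theta,
                    line_length_L_mm = m$line_length_L,
                    standardized_s = m$line_length_L / profile$baseline$length_B,
                    n_crossings = m$n_crossings,
                    outermost_used = m$outermost_used,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a standardized profile from a profile CSV
#'
#' @param path CSV written by [write_profile_csv()].
#' @param use_standardized read the baseline-standardized column (default)
#'   rather than raw mm.
#' @return A `standardized_profile`.
#' @export
read_profile_csv <- function(path, use_standardized = TRUE) {
  if (!file.exists(path)) tdm_data_error(paste("file not found:", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("outline_id", "angle_theta",
            if (use_standardized) "standardized_s" else "line_length_L_mm")
  if (!all(need %in% names(d))) {
    tdm_data_error(paste("profile CSV must have columns:", paste(need, collapse = ", ")))
  }
  d <- d[order(d$angle_theta), ]
  s <- if (use_standardized) d$standardized_s else d$line_length_L_mm
  new_standardized_profile(d$outline_id[1L], d$angle_theta, s,
                           B = NA_real_, standardized = use_standardized)
}
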