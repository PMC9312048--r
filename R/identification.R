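# Baseline standardization and Total Difference scoring. Profiles are made
# dimensionless by dividing every ray length by the baseline length B, so two
# radiographs of the same sinus taken at different magnifications remain
# comparable; the Total Difference between two standardized profiles is the
# L1 distance over the 59 angles, and the candidate with the lowest TD in an
# antemortem array proposes the match.

#' Standardize a sinus profile by its baseline length
#'
#' @param profile a [measure_profile()] result.
#' @param standardize divide by the baseline length (default). With
#'   `FALSE` the raw millimetre lengths are kept; exposed because the
#'   comparison can also be run on raw lengths when all images share one
#'   calibration.
#' @return Object of class `standardized_profile`: list with `outline_id`,
#'   `angles`, `s` (ordered dimensionless lengths), `baseline_length_B`,
#'   `standardized` flag.
#' @export
standardize_profile <- function(profile, standardize = TRUE) {
  stopifnot(inherits(profile, "sinus_profile"))
  B <- profile$baseline$length_B
  if (!is.finite(B) || B <= 0) tdm_geometry_error("degenerate baseline: B must be > 0")
  L <- profile$measurements$line_length_L
  structure(list(outline_id = profile$outline_id,
                 angles = profile$measurements$angle_theta,
                 s = if (standardize) L / B else L,
                 baseline_length_B = B,
                 standardized = standardize),
            class = "standardized_profile")
}

#' @export
print.standardized_profile <- function(x, ...) {
  cat(sprintf("Standardized profile '%s': %d angles, s in [%.4f, %.4f]%s\n",
              x$outline_id, length(x$s), min(x$s), max(x$s),
              if (x$standardized) "" else " (raw mm)"))
  invisible(x)
}

check_comparable <- function(a, b) {
  stopifnot(inherits(a, "standardized_profile"), inherits(b, "standardized_profile"))
  if (length(a$s) != length(b$s) || !isTRUE(all.equal(a$angles, b$angles))) {
    tdm_data_error("profiles cover different angle sets and cannot be compared")
  }
  if (!identical(a$standardized, b$standardized)) {
    tdm_data_error("cannot compare a standardized profile with a raw one")
  }
}

#' Total Difference between two profiles
#'
#' Sum over all angles of the absolute difference between the standardized
#' line lengths of two outlines. Zero for identical profiles; for a true
#' antemortem/postmortem match the value approaches zero, while non-matches
#' accumulate differences at every angle.
#'
#' @param a,b [standardize_profile()] results over the same angle set.
#' @return Object of class `total_difference`: list with `id_A`, `id_B`,
#'   `angles`, `per_angle_abs_diff`, and the scalar `TD`.
#' @export
total_difference <- function(a, b) {
  check_comparable(a, b)
  d <- abs(a$s - b$s)
  structure(list(id_A = a$outline_id, id_B = b$outline_id,
                 angles = a$angles, per_angle_abs_diff = d, TD = sum(d)),
            class = "total_difference")
}

#' @export
print.total_difference <- function(x, ...) {
  cat(sprintf("Total Difference %s vs %s: TD = %.6f over %d angles (max per-angle %.6f)\n",
              x$id_A, x$id_B, x$TD, length(x$angles), max(x$per_angle_abs_diff)))
  invisible(x)
}

#' Rank antemortem candidates against a postmortem profile
#'
#' Computes the Total Difference between the postmortem profile and every
#' antemortem candidate and sorts ascending: the rank-1 candidate (lowest
#' TD) is the proposed identification. Ties are broken by input order
#' (stable sort), so the earlier candidate keeps the better rank.
#'
#' @param pm a [standardize_profile()] result for the postmortem image.
#' @param am_list list of candidate antemortem standardized profiles.
#' @return data.frame (class `td_ranking`) with columns `candidate_id`,
#'   `TD`, `rank`, ordered by rank.
#' @export
rank_candidates <- function(pm, am_list) {
  if (!is.list(am_list) || length(am_list) == 0L ||
      inherits(am_list, "standardized_profile")) {
    tdm_config_error("am_list must be a nonempty list of standardized profiles")
  }
  td <- vapply(am_list, function(am) total_difference(pm, am)$TD, numeric(1))
  ids <- vapply(am_list, function(am) am$outline_id, character(1))
  ord <- order(td)  # stable: ties keep input order
  out <- data.frame(candidate_id = ids[ord], TD = td[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  class(out) <- c("td_ranking", "data.frame")
  out
}
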