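#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can map failures to categories:
#   config  - bad parameters / unknown options
#   data    - unreadable or inconsistent inputs (files, formats, designs)
#   geometry- geometric impossibilities (degenerate baseline, no intersection,
#             ineligible outline)
tdm_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "tdm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

tdm_config_error   <- function(msg) tdm_stop(msg, "tdm_config_error")
tdm_data_error     <- function(msg) tdm_stop(msg, "tdm_data_error")
tdm_geometry_error <- function(msg) tdm_stop(msg, "tdm_geometry_error")

is_finite_point <- function(p) {
  is.numeric(p) && length(p) == 2L && all(is.finite(p))
}

as_point <- function(p, what = "point") {
  p <- as.numeric(p)
  if (!is_finite_point(p)) {
    tdm_config_error(sprintf("%s must be a finite numeric (x, y) pair", what))
  }
  unname(p)
}
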