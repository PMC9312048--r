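# Validation statistics for the measurement technique: bias (signed
# observed - expected error), inaccuracy (its absolute value, i.e. lack of
# precision), a signed cube-root transform for skewed error distributions
# that include negative values, extreme-outlier filtering at 3x the
# interquartile range, grouped summaries, within-subject (repeated-measures)
# ANOVA, and Holm-corrected pairwise p-values.

#' Bias and inaccuracy of an observation
#'
#' Bias is the signed difference observed minus expected and measures how far
#' an estimate sits from the true value; inaccuracy is its absolute value and
#' reflects precision. Vectorized.
#'
#' @param observed,expected finite numeric vectors.
#' @return List with `bias` and `inaccuracy`.
#' @export
#' @examples
#' compute_error(92.5, 90)  # bias 2.5, inaccuracy 2.5
compute_error <- function(observed, expected) {
  if (any(!is.finite(observed)) || any(!is.finite(expected))) {
    tdm_config_error("observed and expected values must be finite")
  }
  bias <- observed - expected
  list(bias = bias, inaccuracy = abs(bias))
}

#' Signed cube-root transform
#'
#' `sign(x) * |x|^(1/3)`: monotone, sign-preserving, defined for negative
#' values, which makes it suitable for transforming skewed bias distributions
#' (signed errors) ahead of parametric testing.
#'
#' @param x numeric vector.
#' @return Transformed vector of the same length.
#' @export
cube_root_transform <- function(x) {
  if (any(!is.finite(x))) tdm_config_error("input must be finite")
  sign(x) * abs(x)^(1 / 3)
}

#' Remove extreme outliers by the 3 x IQR rule
#'
#' Values outside `[Q1 - k*IQR, Q3 + k*IQR]` are removed; with the default
#' `k = 3` these are "extreme" outliers. Quartiles use linear interpolation
#' between order statistics (`stats::quantile` type 7).
#'
#' @param values numeric vector, length >= 4.
#' @param k fence multiplier, default 3.
#' @return List with `kept`, `removed`, and the `fences` used.
#' @export
#' @examples
#' remove_extreme_outliers(c(1, 2, 3, 4, 100))$removed  # 100
remove_extreme_outliers <- function(values, k = 3) {
  if (length(values) < 4L) tdm_data_error("need at least 4 values for quartile fences")
  if (any(!is.finite(values))) tdm_config_error("values must be finite")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
  out <- values < fences[1] | values > fences[2]
  list(kept = values[!out], removed = values[out], fences = fences)
}

#' Grouped summary statistics of error records
#'
#' One row per group with n, mean and sd (sd is `NA` for singleton groups,
#' sample sd with n-1 denominator otherwise).
#'
#' @param records a data.frame (e.g. the `records` of [simulate_study()]).
#' @param variable name of the numeric column to summarize.
#' @param group_by character vector of grouping column names, e.g.
#'   `c("mode", "round")`.
#' @return data.frame with the grouping columns plus `n`, `mean`, `sd`.
#' @export
summarize_errors <- function(records, variable, group_by = "mode") {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    tdm_data_error("records must be a nonempty data.frame")
  }
  missing_cols <- setdiff(c(variable, group_by), names(records))
  if (length(missing_cols)) {
    tdm_config_error(paste("unknown columns:", paste(missing_cols, collapse = ", ")))
  }
  groups <- records[group_by]
  agg <- function(f) stats::aggregate(records[[variable]], groups, f)
  n_tab <- agg(length)
  out <- n_tab[group_by]
  out$n <- n_tab$x
  out$mean <- agg(mean)$x
  out$sd <- ifelse(out$n > 1L, agg(stats::sd)$x, NA_real_)
  out[do.call(order, out[group_by]), , drop = FALSE]
}

#' Repeated-measures ANOVA (fully within-subject)
#'
#' Univariate within-subject ANOVA for one or two within factors on a
#' complete balanced design (each subject observed exactly once per factor
#' cell). Each effect is tested against its own effect-by-subject error
#' stratum; no sphericity correction is applied. Model fitting is delegated
#' to `stats::aov` with an `Error(subject/...)` term.
#'
#' @param values numeric response.
#' @param subject subject identifier (factor-coercible), the repeated unit.
#' @param f1 first within-subject factor.
#' @param f2 optional second within-subject factor (two-way with interaction).
#' @return data.frame (class `rm_anova`) with one row per effect: `effect`,
#'   `df1`, `df2`, `F`, `p`.
#' @export
rm_anova <- function(values, subject, f1, f2 = NULL) {
  d <- data.frame(y = as.numeric(values), subject = factor(subject),
                  f1 = factor(f1))
  two_way <- !is.null(f2)
  if (two_way) d$f2 <- factor(f2)
  if (any(!is.finite(d$y))) tdm_config_error("values must be finite")
  cells <- if (two_way) interaction(d$f1, d$f2) else d$f1
  counts <- table(d$subject, cells)
  if (any(counts != 1L)) {
    tdm_data_error("design must be complete and balanced: one observation per subject per cell")
  }
  fml <- if (two_way) y ~ f1 * f2 + Error(subject / (f1 * f2))
         else y ~ f1 + Error(subject / f1)
  fit <- stats::aov(fml, data = d)
  sm <- summary(fit)
  ss_floor <- 1e-12 * max(sum((d$y - mean(d$y))^2), 1)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1L]]
    terms <- trimws(rownames(tab))
    for (i in which(terms != "Residuals")) {
      res <- which(terms == "Residuals")
      Fv <- tab$`F value`[i]; pv <- tab$`Pr(>F)`[i]
      if (tab$`Sum Sq`[i] <= ss_floor) {  # no effect variance at all: F := 0
        Fv <- 0; pv <- 1
      }
      rows[[length(rows) + 1L]] <- data.frame(
        effect = terms[i], df1 = tab$Df[i], df2 = tab$Df[res],
        F = Fv, p = pv, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$effect <- sub("^f1$", "factor1", sub("^f2$", "factor2",
                sub("^f1:f2$", "factor1:factor2", out$effect)))
  rownames(out) <- NULL
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' Holm step-down adjusted p-values
#'
#' Family-wise error rate control for post hoc pairwise comparisons: sort the
#' p-values ascending, multiply the i-th by (m - i + 1), enforce monotone
#' nondecreasing adjusted values, cap at 1, and return in the input order.
#' Delegates to `stats::p.adjust(method = "holm")`.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
#' @examples
#' pairwise_holm(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
pairwise_holm <- function(p_values) {
  if (length(p_values) == 0L) tdm_config_error("need at least one p-value")
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    tdm_config_error("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "holm")
}
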