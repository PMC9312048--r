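# Synthetic data: eligible bilobed, scalloped sinus outlines plus a Gaussian
# observer-noise model, so the whole measurement and validation workflow runs
# with no radiographs. The generator emulates the morphology the method is
# restricted to: a sinus rising above the supraorbital baseline, spanning the
# midline, left and right lobes touching, with a scalloped ("arcade")
# superior border. Shapes are parametric inventions calibrated to adult
# frontal-sinus scale, not renderings of real anatomy.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Parameters for the synthetic outline generator
#'
#' Defaults describe a typical adult frontal sinus on a scaled
#' posterior-anterior radiograph: a baseline of 60 mm, lobes rising roughly
#' 22 and 26 mm above it, 2-3 rounded arcades per lobe of a few millimetres'
#' amplitude, and an origin placed slightly right of centre (midline ratio
#' near 0.52).
#'
#' @param baseline_width total baseline length B, mm.
#' @param lobe_heights (left, right) peak lobe heights above the baseline, mm.
#' @param n_arcades arcades (scallops) per lobe; length 1 or 2 (left, right).
#' @param arcade_amplitude nominal scallop amplitude, mm.
#' @param asymmetry shift of the midline ratio away from 0.5 (dimensionless);
#'   the origin lands at ratio `0.5 + asymmetry`.
#' @param n_vertices vertices in the traced arc.
#' @return Object of class `outline_params`.
#' @export
outline_params <- function(baseline_width = 60, lobe_heights = c(22, 26),
                           n_arcades = c(2, 3), arcade_amplitude = 3,
                           asymmetry = 0.02, n_vertices = 241) {
  if (baseline_width <= 0) tdm_config_error("baseline_width must be > 0")
  if (length(lobe_heights) == 1L) lobe_heights <- rep(lobe_heights, 2L)
  if (any(lobe_heights <= 0)) tdm_config_error("lobe heights must be > 0")
  if (length(n_arcades) == 1L) n_arcades <- rep(n_arcades, 2L)
  if (any(n_arcades < 1)) tdm_config_error("need at least one arcade per lobe")
  if (arcade_amplitude < 0) tdm_config_error("arcade_amplitude must be >= 0")
  if (abs(asymmetry) >= 0.45) tdm_config_error("asymmetry too large: origin must stay inside the baseline")
  if (n_vertices < 11) tdm_config_error("need at least 11 vertices")
  structure(list(baseline_width = baseline_width, lobe_heights = lobe_heights,
                 n_arcades = as.integer(n_arcades),
                 arcade_amplitude = arcade_amplitude,
                 asymmetry = asymmetry, n_vertices = as.integer(n_vertices)),
            class = "outline_params")
}

raised_cosine <- function(x, centre, width, amplitude) {
  z <- (x - centre) / width
  ifelse(abs(z) < 0.5, amplitude * 0.5 * (1 + cos(2 * pi * z)), 0)
}

#' Generate a synthetic eligible sinus outline
#'
#' Builds a bilobed height profile over the baseline: two smooth lobe
#' envelopes (Gaussian bumps windowed to vanish at the termini) joined over
#' the midline so the lobes touch, with raised-cosine arcades superimposed on
#' each lobe. Lobe heights, arcade placement and amplitudes are jittered
#' reproducibly from `seed`, so each seed yields one distinct individual.
#'
#' @param params an [outline_params()].
#' @param seed integer; identical seeds reproduce identical outlines.
#' @return List with `outline` ([sinus_outline()]), `baseline`
#'   ([baseline_spec()]), `origin` ([origin_spec()]), and `params`.
#' @export
#' @examples
#' g <- generate_outline(seed = 1)
#' check_eligibility(g$outline, g$baseline, g$origin)$eligible
generate_outline <- function(params = outline_params(), seed = 1L) {
  stopifnot(inherits(params, "outline_params"))
  W <- params$baseline_width
  with_seed(seed, {
    h  <- params$lobe_heights * stats::runif(2, 0.85, 1.15)
    cL <- W * stats::runif(1, 0.24, 0.30)
    cR <- W * stats::runif(1, 0.70, 0.76)
    wL <- W * stats::runif(1, 0.16, 0.20)
    wR <- W * stats::runif(1, 0.16, 0.20)
    x <- seq(0, W, length.out = params$n_vertices)
    window <- sin(pi * x / W)^0.8
    env <- window * (h[1] * exp(-((x - cL) / wL)^2) +
                     h[2] * exp(-((x - cR) / wR)^2))
    y <- env
    lobes <- list(c(0.05 * W, 0.5 * W), c(0.5 * W, 0.95 * W))
    for (side in 1:2) {
      k <- params$n_arcades[side]
      span <- lobes[[side]]
      centres <- seq(span[1], span[2], length.out = k + 2L)[2:(k + 1L)] +
        stats::rnorm(k, 0, 0.02 * W)
      widths <- (span[2] - span[1]) / k * stats::runif(k, 0.7, 1.1)
      amps <- params$arcade_amplitude * stats::runif(k, 0.6, 1.4)
      for (j in seq_len(k)) {
        y <- y + window * raised_cosine(x, centres[j], widths[j], amps[j]) /
          max(window[2:(length(x) - 1L)])
      }
    }
    y[1L] <- 0; y[length(y)] <- 0
    y[-c(1L, length(y))] <- pmax(y[-c(1L, length(y))], 1e-3)
  })
  baseline <- baseline_spec(c(0, 0), c(W, 0))
  outline <- sinus_outline(cbind(x, y), id = sprintf("synthetic_%d", seed))
  r_target <- 0.5 + params$asymmetry
  origin <- origin_spec(c((1 - r_target) * W, 0), baseline)
  elig <- check_eligibility(outline, baseline, origin)
  if (!elig$eligible) {
    tdm_geometry_error(paste0("generated outline is ineligible: ",
                              paste(elig$failed, collapse = ", ")))
  }
  list(outline = outline, baseline = baseline, origin = origin, params = params)
}

#' Observer noise model
#'
#' Gaussian perturbations of the three manual steps of the measurement
#' technique: positioning each ray's angle, extending the line to the outline
#' (length), and placing the origin on the baseline. Per-mode defaults (see
#' [mode_noise_defaults()]) encode the expectation that a tracing overlay and
#' a guided macro reduce placement error relative to freehand work; the
#' magnitudes are package conventions, configurable per study.
#'
#' @param sigma_angle sd of angle placement error, degrees.
#' @param sigma_length sd of line-length error as a fraction of the baseline
#'   length B.
#' @param sigma_origin sd of origin placement error along the baseline, mm.
#' @param mode_label label for the collection mode.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma_angle = 0.3, sigma_length = 0.008,
                        sigma_origin = 0.3, mode_label = "custom") {
  if (any(c(sigma_angle, sigma_length, sigma_origin) < 0)) {
    tdm_config_error("noise sds must be >= 0")
  }
  structure(list(sigma_angle = sigma_angle, sigma_length = sigma_length,
                 sigma_origin = sigma_origin, mode_label = mode_label),
            class = "noise_model")
}

#' Default per-mode noise models
#'
#' Three collection modes in decreasing order of expected observer error:
#' freehand (no measurement aid), overlay (3-degree tracing overlay), and
#' semi-automated (overlay plus guided macro).
#'
#' @return Named list of [noise_model()]s: `freehand`, `overlay`, `semi_auto`.
#' @export
mode_noise_defaults <- function() {
  list(freehand  = noise_model(0.8, 0.015, 0.5, "freehand"),
       overlay   = noise_model(0.3, 0.008, 0.3, "overlay"),
       semi_auto = noise_model(0.2, 0.005, 0.2, "semi_auto"))
}

# internal constructor used when a profile's lengths come from simulation
new_standardized_profile <- function(id, angles, s, B, standardized = TRUE) {
  structure(list(outline_id = id, angles = angles, s = s,
                 baseline_length_B = B, standardized = standardized),
            class = "standardized_profile")
}

#' Simulate one observer measuring an outline
#'
#' Re-measures a ground-truth outline under a [noise_model()]: the origin is
#' jittered along the baseline, each nominal angle receives Gaussian angle
#' error, and the resulting ray length receives Gaussian length error. The
#' returned error records pair every observation with its noiseless expected
#' value (the nominal angle, and the true ray length at the nominal angle
#' from the true origin), the reference used throughout the synthetic
#' validation.
#'
#' @param truth a [generate_outline()] result (or any list with `outline`,
#'   `baseline`, `origin`).
#' @param noise a [noise_model()].
#' @param seed integer seed for the observation's noise draws.
#' @param angles nominal angles, default [ray_angles()].
#' @param image_id,observer,round labels copied into the records.
#' @return List with `records` (data.frame, one row per angle: identifiers,
#'   observed/expected angle and length, bias and inaccuracy for both),
#'   `profile` (the noisy measurement as a `standardized_profile`), and
#'   `observed_midline_ratio`.
#' @export
simulate_observer <- function(truth, noise = noise_model(), seed = 1L,
                              angles = ray_angles(), image_id = truth$outline$id,
                              observer = 1L, round = 1L) {
  stopifnot(inherits(noise, "noise_model"))
  outline <- truth$outline; baseline <- truth$baseline; origin <- truth$origin
  elig <- check_eligibility(outline, baseline, origin)
  if (!elig$eligible) tdm_geometry_error("truth outline is not eligible")
  B <- baseline$length_B
  n <- length(angles)
  draws <- with_seed(seed, list(
    d_origin = stats::rnorm(1, 0, noise$sigma_origin),
    d_angle  = stats::rnorm(n, 0, noise$sigma_angle),
    d_length = stats::rnorm(n, 0, noise$sigma_length * B)
  ))
  u <- (baseline$right_terminus - baseline$left_terminus) / B
  proj <- sum((origin$origin - baseline$left_terminus) * u)
  proj_obs <- min(max(proj + draws$d_origin, 1e-3), B - 1e-3)
  origin_obs <- origin_spec(baseline$left_terminus + proj_obs * u, baseline)

  expected_length <- vapply(angles, function(a)
    cast_ray(origin, a, outline)$line_length_L, numeric(1))
  angle_obs <- pmin(pmax(angles + draws$d_angle, 1e-3), 180 - 1e-3)
  observed_length <- vapply(seq_len(n), function(i)
    cast_ray(origin_obs, angle_obs[i], outline)$line_length_L, numeric(1)) +
    draws$d_length
  observed_length <- pmax(observed_length, 0)

  err_a <- compute_error(angle_obs, angles)
  err_l <- compute_error(observed_length, expected_length)
  records <- data.frame(
    image_id = image_id, mode = noise$mode_label,
    observer = as.integer(observer), round = as.integer(round),
    angle_theta = angles,
    observed_angle = angle_obs, expected_angle = angles,
    observed_length = observed_length, expected_length = expected_length,
    bias_angle = err_a$bias, inaccuracy_angle = err_a$inaccuracy,
    bias_length = err_l$bias, inaccuracy_length = err_l$inaccuracy,
    stringsAsFactors = FALSE)
  list(records = records,
       profile = new_standardized_profile(image_id, angles, observed_length / B, B),
       observed_midline_ratio = origin_obs$midline_ratio_r)
}

# observer/round tags for successive measurement events of one image x mode:
# event 1 = observer 1 round 1, event 2 = observer 1 round 2 (intraobserver),
# event 3 = observer 2 round 1 (interobserver); further events extend the
# grid observer-major.
event_tags <- function(n_events) {
  base <- data.frame(observer = c(1L, 1L, 2L), round = c(1L, 2L, 1L))
  if (n_events <= 3L) return(base[seq_len(n_events), , drop = FALSE])
  extra <- expand.grid(round = seq_len(ceiling(n_events / 2)), observer = 3:4)[, 2:1]
  rbind(base, stats::setNames(extra, c("observer", "round")))[seq_len(n_events), ]
}

#' Simulate a full technical-error study
#'
#' Generates `n_images` synthetic outlines and re-measures each one under
#' every collection mode for `events_per_image_mode` observation events
#' (observer 1 round 1, observer 1 round 2, observer 2 round 1 by default),
#' producing one error record per measured line. The default design of 10
#' images, 3 modes and 3 events yields 10 x 3 x 3 x 59 = 5310 line records.
#'
#' @param n_images number of synthetic individuals.
#' @param modes named list of [noise_model()]s, default [mode_noise_defaults()].
#' @param events_per_image_mode observation events per image and mode.
#' @param seed master seed; fans out to per-image and per-event streams.
#' @param params [outline_params()] shared by all generated individuals.
#' @param angles nominal angles, default [ray_angles()].
#' @return Object of class `study_dataset`: list with `records` (all per-line
#'   rows), `summaries` (one row per image x mode x event: observed midline
#'   ratio and tags), and the design dimensions.
#' @export
simulate_study <- function(n_images = 10, modes = mode_noise_defaults(),
                           events_per_image_mode = 3, seed = 1L,
                           params = outline_params(), angles = ray_angles()) {
  if (n_images < 0) tdm_config_error("n_images must be >= 0")
  n_modes <- length(modes)
  n_events <- events_per_image_mode
  if (n_images == 0L || n_modes == 0L || n_events == 0L) {
    empty_rec <- simulate_observer(generate_outline(seed = 1L),
                                   noise_model(0, 0, 0, "none"),
                                   seed = 1L, angles = angles)$records[0L, ]
    return(structure(list(records = empty_rec,
                          summaries = data.frame(),
                          n_images = n_images, n_modes = n_modes,
                          n_events = n_events),
                     class = "study_dataset"))
  }
  tags <- event_tags(n_events)
  seeds <- with_seed(seed, {
    list(outline = sample.int(.Machine$integer.max - 1L, n_images),
         event = array(sample.int(.Machine$integer.max - 1L,
                                  n_images * n_modes * n_events),
                       dim = c(n_images, n_modes, n_events)))
  })
  rec_list <- list(); sum_list <- list()
  for (i in seq_len(n_images)) {
    truth <- generate_outline(params, seed = seeds$outline[i])
    truth$outline$id <- sprintf("img%02d", i)
    for (m in seq_len(n_modes)) {
      for (e in seq_len(n_events)) {
        obs <- simulate_observer(truth, modes[[m]], seed = seeds$event[i, m, e],
                                 angles = angles, image_id = truth$outline$id,
                                 observer = tags$observer[e], round = tags$round[e])
        rec_list[[length(rec_list) + 1L]] <- obs$records
        sum_list[[length(sum_list) + 1L]] <- data.frame(
          image_id = truth$outline$id, mode = modes[[m]]$mode_label,
          observer = tags$observer[e], round = tags$round[e],
          observed_midline_ratio = obs$observed_midline_ratio,
          expected_midline_ratio = truth$origin$midline_ratio_r,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(records = do.call(rbind, rec_list),
                 summaries = do.call(rbind, sum_list),
                 n_images = n_images, n_modes = n_modes, n_events = n_events),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("Simulated study: %d images x %d modes x %d events = %d line records\n",
              x$n_images, x$n_modes, x$n_events, nrow(x$records)))
  invisible(x)
}

#' Simulate an identification trial
#'
#' Generates `n_individuals` synthetic sinuses as the antemortem array, then
#' re-measures each one under observer noise as its postmortem profile and
#' ranks it against all antemortem candidates by Total Difference. Reports
#' the percentage of postmortem profiles whose true source attains rank 1
#' (lowest TD).
#'
#' @param n_individuals number of simulated individuals (>= 2).
#' @param noise a [noise_model()] applied to the postmortem re-measurement.
#' @param seed master seed for the noise streams.
#' @param outline_seeds optional integer vector of per-individual shape
#'   seeds (default `1:n_individuals`, giving a fixed reference population).
#' @param params [outline_params()] for the shape population.
#' @return Object of class `identification_result`: list with `match_rate`
#'   (percent), `n_individuals`, and `rankings` (data.frame: individual,
#'   rank of the true source, top-candidate id, TD to the true source).
#' @export
simulate_identification <- function(n_individuals = 20, noise = noise_model(),
                                    seed = 1L, outline_seeds = NULL,
                                    params = outline_params()) {
  if (n_individuals < 2) tdm_config_error("need at least 2 individuals to rank")
  n_individuals <- as.integer(n_individuals)
  if (is.null(outline_seeds)) outline_seeds <- seq_len(n_individuals)
  if (length(outline_seeds) != n_individuals) {
    tdm_config_error("outline_seeds must have one seed per individual")
  }
  truths <- lapply(seq_len(n_individuals), function(i) {
    tr <- generate_outline(params, seed = outline_seeds[i])
    tr$outline$id <- sprintf("indiv%02d", i)
    tr
  })
  am <- lapply(truths, function(tr)
    standardize_profile(measure_profile(tr$outline, tr$baseline, tr$origin)))
  pm_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_individuals))
  rows <- lapply(seq_len(n_individuals), function(i) {
    pm <- simulate_observer(truths[[i]], noise, seed = pm_seeds[i])$profile
    rk <- rank_candidates(pm, am)
    true_rank <- rk$rank[rk$candidate_id == truths[[i]]$outline$id]
    data.frame(individual = truths[[i]]$outline$id,
               true_source_rank = true_rank,
               top_candidate = rk$candidate_id[1L],
               TD_true = rk$TD[rk$candidate_id == truths[[i]]$outline$id],
               stringsAsFactors = FALSE)
  })
  rankings <- do.call(rbind, rows)
  structure(list(match_rate = 100 * mean(rankings$true_source_rank == 1L),
                 n_individuals = n_individuals, rankings = rankings),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("Identification trial: %d individuals, true source ranked first in %.1f%%\n",
              x$n_individuals, x$match_rate))
  invisible(x)
}
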