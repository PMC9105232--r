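#' Configuration for a synthetic stem population
#'
#' Defaults emulate the destructive-sampling study the models come from:
#' per-species sample sizes and stem-base diameter distributions match the
#' reported population statistics, trees follow the packaged allometries,
#' and additive Gaussian noise on each response defaults to the square root
#' of the model's printed mean squared error (so simulated scatter matches
#' the fitted residual variance). Height is the exception: the printed MSE
#' of the height model is not on the metre scale of its response, so the
#' height noise SD defaults to the share of the reported population height
#' SD left unexplained by the model, `height_sd * sqrt(1 - R^2)`.
#'
#' @param species One of [bark_species()].
#' @param n_trees Number of trees; default = the study's per-species count.
#' @param d0_mean,d0_sd Mean and SD (mm) of the stem-base diameter
#'   distribution; defaults from the study population.
#' @param d0_min Lower truncation (mm) of the diameter distribution;
#'   diameters are drawn from a normal truncated below at this value.
#' @param noise Named numeric vector of additive noise SDs on each
#'   response's original scale: `height_m`, `dbh_mm`, `radius_cm`,
#'   `thickness_mm`. Values given here override the sqrt-MSE defaults;
#'   set all to 0 for noiseless populations.
#' @param generating_models A [species_model_library()] supplying the
#'   generating truth; defaults to the packaged models for `species`.
#' @param seed Integer seed; identical configurations (including the seed)
#'   reproduce populations exactly.
#'
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(species, n_trees = NULL, d0_mean = NULL,
                              d0_sd = NULL, d0_min = 5, noise = NULL,
                              generating_models = NULL, seed = 1L) {
  lib <- generating_models %||% species_model_library(species)
  pop <- .population_defaults(species)
  noise_default <- c(
    height_m = pop$height_sd_m * sqrt(1 - lib$models$height$r_squared),
    dbh_mm = sqrt(lib$models$dbh$mse),
    radius_cm = sqrt(lib$models$radius$mse),
    thickness_mm = sqrt(lib$models$thickness$mse)
  )
  if (!is.null(noise)) {
    if (is.null(names(noise)) && length(noise) == 1L) {
      noise <- setNames(rep(noise, 4), names(noise_default))
    }
    bad <- setdiff(names(noise), names(noise_default))
    if (length(bad)) abort(sprintf("unknown noise component(s): %s", paste(bad, collapse = ", ")))
    noise_default[names(noise)] <- noise
  }
  if (any(noise_default < 0)) abort("noise SDs must be >= 0")
  cfg <- list(
    species = species,
    n_trees = as.integer(n_trees %||% pop$n_trees),
    d0_mean = d0_mean %||% pop$d0_mean_mm,
    d0_sd = d0_sd %||% pop$d0_sd_mm,
    d0_min = d0_min,
    noise = noise_default,
    generating_models = lib,
    seed = as.integer(seed)
  )
  if (cfg$n_trees <= 0L) abort("n_trees must be positive")
  if (cfg$d0_min <= 0) abort("d0_min must be positive")
  structure(cfg, class = "simulation_config")
}

# normal truncated below at `lower`, by rejection (acceptance is high for
# the study's distributions, where lower sits ~1.3 SD below the mean)
.rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(max(n, 100L), mean, sd)
    out <- c(out, draw[draw >= lower])
  }
  out[seq_len(n)]
}

#' Simulate a stem population with section measurements
#'
#' Generates trees (stem-base diameter, height, DBH) and caliper-style
#' section measurements following the sectioning protocol: each whole stem
#' is cut into at least 4 equal-length sections no longer than 1 m, with
#' over- and under-bark diameters recorded at the lower end, middle and
#' upper end of every section. Measurement heights at the ground line are
#' taken 1 cm above it, where the taper and thickness power models are
#' defined. Positions above 250 cm are generated from the same curves
#' (the stem is cut whole) but are excluded from the fitting tables by
#' [to_observation_tables()], mirroring how the models are restricted to
#' the bottom 2.5 m of the stem.
#'
#' Noise-perturbed measurements are kept physical: heights are floored at
#' 0.3 m, DBH at 1 mm, over-bark diameters at 0.2 mm, and the over/under
#' diameter gap at 0.2 mm (the floors never bind when the noise SDs are 0).
#'
#' @param config A [simulation_config()].
#' @return A list of class `"bark_population"` with tibbles `trees`
#'   (`tree_id`, `species`, `d0_mm`, `height_m`, `dbh_mm` -- `NA` for trees
#'   not reaching breast height) and `sections` (`tree_id`, `section`,
#'   `lower_cm`, `upper_cm`, `position`, `hg_cm`, `d_over_mm`,
#'   `d_under_mm`), plus the `config`.
#' @examples
#' pop <- simulate_bark_population(simulation_config("rowan", n_trees = 5, seed = 7))
#' pop$trees
#' @export
simulate_bark_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  lib <- config$generating_models
  set.seed(config$seed)

  d0 <- .rtruncnorm_lower(config$n_trees, config$d0_mean, config$d0_sd, config$d0_min)
  h_true <- predict_height(lib, d0)
  height <- pmax(h_true + rnorm(config$n_trees, 0, config$noise[["height_m"]]),
                 pmin(0.3, h_true))
  dbh_true <- predict_dbh(lib, d0)
  dbh <- ifelse(height > 1.3,
                pmax(dbh_true + rnorm(config$n_trees, 0, config$noise[["dbh_mm"]]), 1),
                NA_real_)
  trees <- tibble::tibble(
    tree_id = sprintf("%s_%04d", config$species, seq_len(config$n_trees)),
    species = config$species,
    d0_mm = d0,
    height_m = height,
    dbh_mm = dbh
  )
  sections <- purrr::map_dfr(seq_len(config$n_trees), function(i) {
    simulate_sections(trees[i, ], config)
  })
  structure(list(trees = trees, sections = sections, config = config),
            class = "bark_population")
}

#' Simulate section measurements for one tree
#'
#' Applies the sectioning rules to a single tree row: the stem of length
#' `height` is cut into `max(4, ceiling(length_cm / 100))` equal sections,
#' with over- and under-bark diameters at three positions per section.
#' Normally called via [simulate_bark_population()], which controls the
#' random seed.
#'
#' @param tree A one-row data frame with `tree_id`, `species`, `d0_mm`,
#'   `height_m`.
#' @param config The [simulation_config()] supplying models and noise.
#' @return A tibble of section measurements (see
#'   [simulate_bark_population()]).
#' @export
simulate_sections <- function(tree, config) {
  stopifnot(nrow(tree) == 1L)
  lib <- config$generating_models
  stem_cm <- tree$height_m * 100
  n_sec <- max(4L, as.integer(ceiling(stem_cm / 100)))
  ls <- stem_cm / n_sec
  bounds <- tibble::tibble(
    section = seq_len(n_sec),
    lower_cm = (seq_len(n_sec) - 1) * ls,
    upper_cm = seq_len(n_sec) * ls
  )
  pos <- bounds |>
    dplyr::cross_join(tibble::tibble(position = c("lower", "middle", "upper"))) |>
    dplyr::mutate(
      hg_cm = pmax(.data$lower_cm + (match(.data$position, c("lower", "middle", "upper")) - 1) / 2 *
                     (.data$upper_cm - .data$lower_cm), 1)
    )
  # extrapolation warnings are intentional here: stems taller than 2.5 m (and
  # the occasional d0 draw above 100 mm) are measured whole, and only the
  # observation tables are restricted to the fitted domain
  r_true <- suppressWarnings(predict_stem_radius(lib, tree$d0_mm, pos$hg_cm))
  t_true <- suppressWarnings(predict_bark_thickness(lib, tree$d0_mm, pos$hg_cm))
  d_over <- pmax(20 * (r_true + rnorm(nrow(pos), 0, config$noise[["radius_cm"]])), 0.2)
  gap <- pmax(2 * (t_true + rnorm(nrow(pos), 0, config$noise[["thickness_mm"]])), 0.2)
  tibble::tibble(
    tree_id = tree$tree_id,
    pos,
    d_over_mm = d_over,
    d_under_mm = d_over - gap
  )
}

#' Flatten a population into observation tables for fitting
#'
#' Bridges the generator to the fitting functions: returns one observation
#' table per response kind, in the common long format (`tree_id`,
#' `species`, `d0_mm`, `hg_cm`, `response`, `response_kind`).
#'
#' Height has one row per tree; DBH one row per tree taller than breast
#' height; radius and thickness one row per measurement position within the
#' modeled stem domain (`hg <= 250` cm; higher positions on tall stems are
#' measured but not used for fitting), with the radius taken from the
#' over-bark diameter (`d_over / 20` cm) and the thickness from the
#' over/under diameter difference -- halved under the default `"radial"`
#' convention, matching how [section_bark_volume()] consumes modeled
#' thickness.
#'
#' @param population A `"bark_population"` from [simulate_bark_population()].
#' @param thickness_convention `"radial"` (thickness = diameter
#'   difference / 2) or `"diameter"` (the difference itself).
#' @return A named list of tibbles: `height`, `dbh`, `radius`, `thickness`.
#' @export
to_observation_tables <- function(population,
                                  thickness_convention = c("radial", "diameter")) {
  stopifnot(inherits(population, "bark_population"))
  mult <- switch(match.arg(thickness_convention), radial = 0.5, diameter = 1)
  trees <- population$trees
  sec <- population$sections |>
    dplyr::filter(.data$hg_cm <= 250) |>
    dplyr::left_join(trees[, c("tree_id", "species", "d0_mm")], by = "tree_id")
  list(
    height = trees |>
      dplyr::transmute(.data$tree_id, .data$species, .data$d0_mm,
                       hg_cm = NA_real_, response = .data$height_m,
                       response_kind = "height_m"),
    dbh = trees |>
      dplyr::filter(!is.na(.data$dbh_mm)) |>
      dplyr::transmute(.data$tree_id, .data$species, .data$d0_mm,
                       hg_cm = NA_real_, response = .data$dbh_mm,
                       response_kind = "dbh_mm"),
    radius = sec |>
      dplyr::transmute(.data$tree_id, .data$species, .data$d0_mm, .data$hg_cm,
                       response = .data$d_over_mm / 20,
                       response_kind = "radius_cm"),
    thickness = sec |>
      dplyr::transmute(.data$tree_id, .data$species, .data$d0_mm, .data$hg_cm,
                       response = (.data$d_over_mm - .data$d_under_mm) * mult,
                       response_kind = "thickness_mm")
  )
}

#' @export
print.bark_population <- function(x, ...) {
  cat(sprintf("<bark_population: %s, %d trees, %d section measurements, seed %d>\n",
              x$config$species, nrow(x$trees), nrow(x$sections), x$config$seed))
  invisible(x)
}

#' Generate a seeded dataset for a parameter-recovery study
#'
#' Builds one observation table under the recovery-study design: stem-base
#' diameters drawn from the species' truncated-normal population, heights
#' above ground uniform on [1, 250] cm for the two-predictor models, and
#' additive Gaussian noise with SD equal to the square root of the model's
#' printed mean squared error. For `"dbh"` the diameters are restricted to
#' trees predicted taller than breast height (1.3 m) before the linear
#' model is applied. Noise draws that would leave a measurement
#' non-physical are floored the same way as in
#' [simulate_bark_population()] (radius at 0.01 cm, thickness at 0.1 mm,
#' DBH at 1 mm).
#'
#' @param species One of [bark_species()].
#' @param response `"radius"`, `"thickness"` or `"dbh"`.
#' @param n Number of observations.
#' @param seed Integer seed.
#' @return An observation table ready for the matching fitter.
#' @examples
#' tab <- simulate_recovery_dataset("common_aspen", "radius", n = 100, seed = 1)
#' fit_power_model(tab, "radius_cm")
#' @export
simulate_recovery_dataset <- function(species,
                                      response = c("radius", "thickness", "dbh"),
                                      n = 600, seed = 1L) {
  response <- match.arg(response)
  lib <- species_model_library(species)
  pop <- .population_defaults(species)
  set.seed(as.integer(seed))
  if (response == "dbh") {
    # keep only trees above breast height, judged on the height model
    d0 <- numeric(0)
    while (length(d0) < n) {
      cand <- .rtruncnorm_lower(2L * n, pop$d0_mean_mm, pop$d0_sd_mm, 5)
      d0 <- c(d0, cand[predict_height(lib, cand) > 1.3])
    }
    d0 <- d0[seq_len(n)]
    y <- pmax(predict_dbh(lib, d0) + rnorm(n, 0, sqrt(lib$models$dbh$mse)), 1)
    return(tibble::tibble(tree_id = as.character(seq_len(n)), species = species,
                          d0_mm = d0, hg_cm = NA_real_, response = y,
                          response_kind = "dbh_mm"))
  }
  d0 <- .rtruncnorm_lower(n, pop$d0_mean_mm, pop$d0_sd_mm, 5)
  hg <- runif(n, 1, 250)
  # rare diameter draws above 100 mm would emit extrapolation warnings; they
  # are part of the population being emulated
  if (response == "radius") {
    mu <- suppressWarnings(predict_stem_radius(lib, d0, hg))
    y <- pmax(mu + rnorm(n, 0, sqrt(lib$models$radius$mse)), 0.01)
    kind <- "radius_cm"
  } else {
    mu <- suppressWarnings(predict_bark_thickness(lib, d0, hg))
    y <- pmax(mu + rnorm(n, 0, sqrt(lib$models$thickness$mse)), 0.1)
    kind <- "thickness_mm"
  }
  tibble::tibble(tree_id = as.character(seq_len(n)), species = species,
                 d0_mm = d0, hg_cm = hg, response = y, response_kind = kind)
}
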