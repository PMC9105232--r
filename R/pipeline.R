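#' Standard stem sections for the lower-stem bark profile
#'
#' The five half-metre sections 0--50, 50--100, 100--150, 150--200 and
#' 200--250 cm above ground over which bark properties are summarised.
#'
#' @return A tibble with columns `lower` and `upper` (cm).
#' @export
standard_sections <- function() {
  tibble::tibble(lower = seq(0, 200, by = 50), upper = seq(50, 250, by = 50))
}

.check_section <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper) || anyNA(lower) || anyNA(upper)) {
    abort("section bounds must be numeric")
  }
  if (any(lower < 0) || any(upper > 250) || any(lower >= upper)) {
    abort("sections must satisfy 0 <= lower < upper <= 250 cm")
  }
}

# factor applied to the modeled thickness to obtain the radial bark depth:
# under the "radial" reading of the thickness model the modeled value is the
# one-side depth itself; under the "diameter" reading it is the over/under
# diameter difference, i.e. twice the radial depth
.thickness_factor <- function(thickness_convention = c("radial", "diameter")) {
  switch(match.arg(thickness_convention), radial = 1, diameter = 0.5)
}

#' Bark surface of a stem section
#'
#' Lateral surface of the frustum spanned by the modeled stem radii at the
#' section's lower and upper heights (the ground-line radius uses the
#' `d0/20` base convention of [predict_stem_radius()]).
#'
#' @param lib A [species_model_library()] (or species code).
#' @param d0 Stem-base diameter, mm. Vectorised.
#' @param lower,upper Section bounds, cm, with `0 <= lower < upper <= 250`.
#' @return Bark surface in cm^2.
#' @examples
#' section_bark_surface("common_aspen", d0 = 100, lower = 50, upper = 100)
#' @export
section_bark_surface <- function(lib, d0, lower = 0, upper = 50) {
  .check_section(lower, upper)
  r1 <- predict_stem_radius(lib, d0, lower)
  r2 <- predict_stem_radius(lib, d0, upper)
  frustum_surface(r1, r2, upper - lower)
}

#' Bark volume of a stem section
#'
#' Difference between the over-bark and under-bark frustum volumes of the
#' section. Under-bark radii are the modeled over-bark radii minus the
#' radial bark depth from the thickness model (evaluated at the section
#' bounds, floored at `hg = 1` cm where the power law is undefined).
#'
#' @inheritParams section_bark_surface
#' @param thickness_convention How to read the modeled bark thickness:
#'   `"radial"` (default; the modeled value is the one-side depth) or
#'   `"diameter"` (the modeled value is the diameter difference, so half of
#'   it is the radial depth).
#' @return Bark volume in cm^3.
#' @export
section_bark_volume <- function(lib, d0, lower = 0, upper = 50,
                                thickness_convention = c("radial", "diameter")) {
  .check_section(lower, upper)
  fac <- .thickness_factor(thickness_convention)
  r1 <- predict_stem_radius(lib, d0, lower)
  r2 <- predict_stem_radius(lib, d0, upper)
  t1 <- predict_bark_thickness(lib, d0, pmax(lower, 1))
  t2 <- predict_bark_thickness(lib, d0, pmax(upper, 1))
  r1_in <- r1 - fac * t1 / 10   # mm -> cm
  r2_in <- r2 - fac * t2 / 10
  if (any(r1_in <= 0) || any(r2_in <= 0)) {
    abort("under-bark radius is non-positive: bark thicker than the stem (model misuse)")
  }
  ls <- upper - lower
  frustum_volume(r1, r2, ls) - frustum_volume(r1_in, r2_in, ls)
}

#' Bark mass of a stem section
#'
#' `W_b = V_b * rho_b`, assuming bark density constant along the 0--250 cm
#' profile; with the volume in cm^3 and the density in kg m^-3 the mass in
#' grams is `V_b * rho_b / 1000`.
#'
#' @inheritParams section_bark_volume
#' @return Bark mass in grams.
#' @export
section_bark_mass <- function(lib, d0, lower = 0, upper = 50,
                              thickness_convention = c("radial", "diameter")) {
  lib <- if (is.character(lib)) species_model_library(lib) else lib
  if (is.null(lib$bark_density)) {
    abort(paste(
      "bark density is unset: supply it via species_model_library(species,",
      "bark_density = ...) in kg m^-3 (oven-dry mass per fresh volume, from a",
      "local density reference)"
    ))
  }
  vb <- section_bark_volume(lib, d0, lower, upper, thickness_convention)
  vb * lib$bark_density * 1e-3
}

#' Specific surface mass of bark
#'
#' Dry bark mass per unit of outer stem surface, `SPH = W_b / S_b` in
#' g dm^-2 -- the forage-relevant bark indicator. The surface argument is in
#' cm^2 (as produced by [section_bark_surface()]) and is converted to dm^2.
#'
#' @param mass_g Bark mass in grams.
#' @param surface_cm2 Bark surface in cm^2, > 0.
#' @return Specific surface mass in g dm^-2.
#' @examples
#' specific_surface_mass(50, 1000)  # 50 g over 10 dm^2 -> 5 g/dm^2
#' @export
specific_surface_mass <- function(mass_g, surface_cm2) {
  stopifnot(is.numeric(mass_g), is.numeric(surface_cm2))
  if (any(surface_cm2 <= 0)) abort("surface must be positive")
  mass_g / convert_units(surface_cm2, "cm2", "dm2")
}

#' Bark profile along the lower stem
#'
#' The central pipeline verb: for each tree (row of `data`), composes the
#' species' allometric models with frustum geometry over the standard stem
#' sections and returns one row per tree and section with bark surface,
#' bark volume and -- when a bark density is available -- bark mass and
#' specific surface mass. Sections above the predicted tree height are
#' truncated to the height (emitted as partial sections) or dropped.
#'
#' @param data A data frame with columns `species` and `d0_mm` (and any
#'   others, which are carried through).
#' @param density Bark density in kg m^-3: a single value, or a named vector
#'   per species (e.g. `c(common_aspen = 480, sycamore = 560)`). With
#'   `NULL` (default) the mass and SPH columns are omitted with a warning.
#' @param sections A tibble of section bounds as from [standard_sections()].
#' @param thickness_convention See [section_bark_volume()].
#'
#' @return A tibble of class `"bark_profile"`: the carried-through tree
#'   columns plus `height_m`, `section_lower_cm`, `section_upper_cm`,
#'   `length_cm`, `partial`, `thickness_mm` (at the section's lower bound,
#'   floored at 1 cm), `surface_cm2`, `volume_cm3` and, with density,
#'   `mass_g`, `sph_g_dm2`.
#' @examples
#' trees <- tibble::tibble(species = "common_aspen", d0_mm = c(50, 100))
#' bark_profile(trees, density = 480)
#' @export
bark_profile <- function(data, density = NULL, sections = standard_sections(),
                         thickness_convention = c("radial", "diameter")) {
  stopifnot(is.data.frame(data), all(c("species", "d0_mm") %in% names(data)))
  thickness_convention <- match.arg(thickness_convention)
  .check_section(sections$lower, sections$upper)
  data <- tibble::as_tibble(data)
  if (is.null(density)) {
    warn("no bark density supplied: mass and specific-surface-mass columns omitted")
  }

  rows <- purrr::map_dfr(seq_len(nrow(data)), function(i) {
    tree <- data[i, ]
    dens <- .density_for(density, tree$species)
    lib <- species_model_library(tree$species, bark_density = dens)
    height_cm <- predict_height(lib, tree$d0_mm) * 100
    sec <- sections |>
      dplyr::filter(.data$lower < height_cm) |>
      dplyr::mutate(
        partial = .data$upper > height_cm,
        upper = pmin(.data$upper, height_cm)
      )
    if (nrow(sec) == 0L) return(tibble::tibble())
    out <- tree |>
      dplyr::mutate(height_m = height_cm / 100) |>
      dplyr::cross_join(sec) |>
      dplyr::rename(section_lower_cm = "lower", section_upper_cm = "upper") |>
      dplyr::mutate(
        length_cm = .data$section_upper_cm - .data$section_lower_cm,
        thickness_mm = predict_bark_thickness(lib, tree$d0_mm,
                                              pmax(.data$section_lower_cm, 1)),
        surface_cm2 = section_bark_surface(lib, tree$d0_mm,
                                           .data$section_lower_cm,
                                           .data$section_upper_cm),
        volume_cm3 = section_bark_volume(lib, tree$d0_mm,
                                         .data$section_lower_cm,
                                         .data$section_upper_cm,
                                         thickness_convention)
      )
    if (!is.null(dens)) {
      out <- out |>
        dplyr::mutate(
          mass_g = .data$volume_cm3 * dens * 1e-3,
          sph_g_dm2 = specific_surface_mass(.data$mass_g, .data$surface_cm2)
        )
    }
    out
  })
  class(rows) <- c("bark_profile", class(rows))
  rows
}

.density_for <- function(density, species) {
  if (is.null(density)) return(NULL)
  stopifnot(is.numeric(density))
  if (is.null(names(density))) {
    if (length(density) != 1L) abort("unnamed density must be a single value")
    return(unname(density))
  }
  if (!species %in% names(density)) {
    abort(sprintf("no bark density supplied for species '%s'", species))
  }
  unname(density[[species]])
}
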