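#' Species covered by the packaged bark models
#'
#' @return Character vector of the four species codes understood everywhere a
#'   `species` argument appears: `"common_aspen"` (*Populus tremula*),
#'   `"goat_willow"` (*Salix caprea*), `"rowan"` (*Sorbus aucuparia*) and
#'   `"sycamore"` (*Acer pseudoplatanus*).
#' @export
bark_species <- function() {
  c("common_aspen", "goat_willow", "rowan", "sycamore")
}

# single session cache for the packaged coefficient document
.stembark_cache <- new.env(parent = emptyenv())

.packaged_document <- function() {
  if (is.null(.stembark_cache$doc)) {
    path <- system.file("extdata", "bark_model_coefficients.json",
                        package = "stembark", mustWork = TRUE)
    .stembark_cache$doc <- read_coefficient_document(path)
  }
  .stembark_cache$doc
}

#' Read and validate a coefficient document
#'
#' Parses the JSON interchange format used for model coefficients: a
#' `species` map whose entries hold, per model (`dbh`, `height`, `radius`,
#' `thickness`), the regression coefficients, their standard errors,
#' printed p-values, R^2 and mean squared error. The packaged document
#' shipped with the package uses the same schema, so refitted coefficients
#' written by [write_model_library()] can be re-loaded interchangeably.
#'
#' @param path Path to a JSON file.
#' @return The validated document as a nested list (invisibly classed
#'   `"bark_coefficient_document"`).
#' @export
read_coefficient_document <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  .validate_coefficient_document(doc, path)
  class(doc) <- "bark_coefficient_document"
  doc
}

.validate_coefficient_document <- function(doc, path = "<document>") {
  fail <- function(msg) abort(sprintf("invalid coefficient document '%s': %s", path, msg))
  if (!is.list(doc$species) || length(doc$species) == 0L) {
    fail("missing or empty 'species' map")
  }
  required_terms <- list(
    dbh = c("b0", "b1"),
    height = c("b0", "b1", "b2"),
    radius = c("b0", "b1", "b2"),
    thickness = c("b0", "b1", "b2")
  )
  for (sp in names(doc$species)) {
    entry <- doc$species[[sp]]
    for (model in names(required_terms)) {
      m <- entry[[model]]
      if (is.null(m)) fail(sprintf("species '%s' lacks model '%s'", sp, model))
      cf <- m$coefficients
      terms <- required_terms[[model]]
      if (!all(terms %in% names(cf))) {
        fail(sprintf("model '%s' of '%s' must have coefficients %s",
                     model, sp, paste(terms, collapse = ", ")))
      }
      if (!all(vapply(cf[terms], is.numeric, logical(1)))) {
        fail(sprintf("non-numeric coefficient in model '%s' of '%s'", model, sp))
      }
      se <- m$se
      if (!is.null(se) && any(unlist(se) <= 0)) {
        fail(sprintf("standard errors in model '%s' of '%s' must be > 0", model, sp))
      }
      if (!is.null(m$r_squared) && (m$r_squared < 0 || m$r_squared > 1)) {
        fail(sprintf("r_squared out of [0, 1] in model '%s' of '%s'", model, sp))
      }
      if (!is.null(m$mse) && m$mse < 0) {
        fail(sprintf("negative mse in model '%s' of '%s'", model, sp))
      }
      # structural constraints on the power models: positive scale, taper signs
      if (identical(m$form, "power_two_predictor") && cf$b0 <= 0) {
        fail(sprintf("power model '%s' of '%s' needs b0 > 0", model, sp))
      }
      if (identical(m$form, "rational_height") && cf$b2 <= 0) {
        fail(sprintf("height model of '%s' needs b2 > 0 for a finite asymptote", sp))
      }
    }
  }
  invisible(doc)
}

.new_bark_model <- function(entry, model, response_unit) {
  structure(
    list(
      form = entry$form,
      coefficients = vapply(entry$coefficients, as.numeric, numeric(1)),
      se = if (!is.null(entry$se)) vapply(entry$se, as.numeric, numeric(1)),
      p = if (!is.null(entry$p)) vapply(entry$p, as.character, character(1)),
      r_squared = entry$r_squared,
      mse = entry$mse,
      response = model,
      response_unit = response_unit
    ),
    class = c(paste0("bark_model_", entry$form), "bark_model")
  )
}

#' Assemble the model library for one species
#'
#' Bundles the four packaged regressions for a species -- the linear
#' DBH-on-D0 model, the rational height model, the stem-radius power model
#' and the bark-thickness power model -- together with an optional bark
#' density. Bark density is deliberately *not* packaged: it must come from
#' the user (e.g. from a local wood/bark density reference) before bark mass
#' or specific surface mass can be computed.
#'
#' @param species One of [bark_species()].
#' @param bark_density Optional oven-dry bark density in kg m^-3; plausible
#'   values lie in (50, 1500).
#' @param document A coefficient document from [read_coefficient_document()];
#'   defaults to the packaged one.
#'
#' @return An object of class `"species_model_library"`: a list with elements
#'   `species`, `latin`, `models` (named list of `bark_model` objects:
#'   `dbh`, `height`, `radius`, `thickness`) and `bark_density`.
#' @examples
#' lib <- species_model_library("common_aspen")
#' predict_bark_thickness(lib, d0 = 100, hg = 50)
#' @export
species_model_library <- function(species, bark_density = NULL, document = NULL) {
  doc <- document %||% .packaged_document()
  if (length(species) != 1L || !species %in% names(doc$species)) {
    abort(sprintf("unknown species '%s'; valid species: %s",
                  paste(species, collapse = ", "),
                  paste(names(doc$species), collapse = ", ")))
  }
  if (!is.null(bark_density)) {
    stopifnot(is.numeric(bark_density), length(bark_density) == 1L)
    if (bark_density <= 50 || bark_density >= 1500) {
      abort("bark_density must be in (50, 1500) kg m^-3")
    }
  }
  entry <- doc$species[[species]]
  units <- c(dbh = "mm", height = "m", radius = "cm", thickness = "mm")
  models <- lapply(names(units), function(m) .new_bark_model(entry[[m]], m, units[[m]]))
  names(models) <- names(units)
  structure(
    list(
      species = species,
      latin = entry$latin %||% NA_character_,
      n_trees = entry$n_trees %||% NA_integer_,
      models = models,
      bark_density = bark_density
    ),
    class = "species_model_library"
  )
}

#' @export
print.species_model_library <- function(x, ...) {
  cat(sprintf("<species_model_library: %s (%s)>\n", x$species, x$latin))
  cat(sprintf("  bark density: %s\n",
              if (is.null(x$bark_density)) "unset (required for mass/SPH)"
              else sprintf("%g kg m^-3", x$bark_density)))
  print(tidy(x))
  invisible(x)
}

#' Tidy the coefficients of a species model library
#'
#' @param x A [species_model_library()].
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @method tidy species_model_library
#' @export
tidy.species_model_library <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    tibble::tibble(
      species = x$species,
      model = m$response,
      term = names(m$coefficients),
      estimate = unname(m$coefficients),
      std.error = if (is.null(m$se)) NA_real_ else unname(m$se[names(m$coefficients)]),
      p.printed = if (is.null(m$p)) NA_character_ else unname(m$p[names(m$coefficients)])
    )
  })
}

#' Fit statistics of the packaged models for one species
#'
#' @param x A [species_model_library()].
#' @param ... Unused.
#' @return A tibble with one row per model: `r.squared`, `mse`.
#' @method glance species_model_library
#' @export
glance.species_model_library <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    tibble::tibble(
      species = x$species,
      model = m$response,
      r.squared = m$r_squared %||% NA_real_,
      mse = m$mse %||% NA_real_
    )
  })
}

#' Packaged coefficients as a tidy table
#'
#' @param species Species to include; defaults to all four.
#' @return A tibble with one row per species x model x coefficient:
#'   `species`, `model`, `term`, `estimate`, `std.error`, `p.printed`.
#' @export
bark_coefficients <- function(species = bark_species()) {
  purrr::map_dfr(species, function(sp) tidy(species_model_library(sp)))
}

# Table of reported per-species population statistics used as simulation
# defaults (sample sizes, D0 and height moments).
.population_defaults <- function(species) {
  doc <- .packaged_document()
  entry <- doc$population[[species]]
  if (is.null(entry)) abort(sprintf("no population defaults for species '%s'", species))
  entry
}

`%||%` <- function(x, y) if (is.null(x)) y else x
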