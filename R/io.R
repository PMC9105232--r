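#' Write and read observation tables as CSV
#'
#' Observation tables travel as RFC-4180 CSV with the documented header
#' `tree_id, species, d0_mm, hg_cm, response, response_kind`.
#'
#' @param data An observation table (see [validate_observations()]).
#' @param path File path.
#' @return `write_observation_table()` returns `path` invisibly;
#'   `read_observation_table()` returns a tibble.
#' @export
write_observation_table <- function(data, path) {
  stopifnot(is.data.frame(data))
  cols <- c("tree_id", "species", "d0_mm", "hg_cm", "response", "response_kind")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("observation table lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(data[cols], path)
  invisible(path)
}

#' @rdname write_observation_table
#' @export
read_observation_table <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      tree_id = readr::col_character(),
      species = readr::col_character(),
      d0_mm = readr::col_double(),
      hg_cm = readr::col_double(),
      response = readr::col_double(),
      response_kind = readr::col_character()
    )
  )
}

#' Export fitted models to the coefficient JSON schema
#'
#' Serialises a set of fitted models in the same JSON schema as the
#' packaged coefficient document, so the output can be re-loaded with
#' [read_coefficient_document()] and used via [species_model_library()].
#'
#' @param fits A named list: species -> named list with elements `dbh`,
#'   `height`, `radius`, `thickness`, each an `"allo_fit"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_library <- function(fits, path) {
  stopifnot(is.list(fits), !is.null(names(fits)))
  doc <- list(
    schema = "stembark-coefficients-v1",
    species = purrr::map(fits, function(models) {
      stopifnot(all(c("dbh", "height", "radius", "thickness") %in% names(models)))
      purrr::map(models, function(f) {
        stopifnot(inherits(f, "allo_fit"))
        list(
          form = f$model_form,
          coefficients = as.list(setNames(f$coefficients$estimate, f$coefficients$term)),
          se = as.list(setNames(f$coefficients$std.error, f$coefficients$term)),
          p = as.list(setNames(
            ifelse(f$coefficients$p.value < 0.001, "<0.001",
                   formatC(f$coefficients$p.value, digits = 3, format = "g")),
            f$coefficients$term)),
          r_squared = f$stats$r_squared,
          mse = f$stats$mse,
          n = f$stats$n
        )
      })
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate populations and write them to disk
#'
#' Front-end over [simulate_bark_population()]: simulates one population
#' per requested species, concatenates them, and writes `trees.csv`,
#' `sections.csv` and a `config.json` echo (species, sample sizes, noise
#' SDs and the per-species seeds derived from `seed`).
#'
#' @param species Character vector of species codes.
#' @param n_trees Optional named (or single) override of trees per species;
#'   a species with 0 trees is omitted with a warning.
#' @param noise Optional noise override passed to [simulation_config()].
#' @param seed Top-level integer seed; species `i` uses `seed + i - 1`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the populations and the file paths.
#' @export
run_simulate <- function(species = bark_species(), n_trees = NULL, noise = NULL,
                         seed = 1L, dir = ".") {
  stopifnot(all(species %in% bark_species()))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_for <- function(sp) {
    if (is.null(n_trees)) return(NULL)
    if (is.null(names(n_trees))) return(n_trees[[1]])
    if (sp %in% names(n_trees)) n_trees[[sp]] else NULL
  }
  pops <- list()
  for (i in seq_along(species)) {
    sp <- species[[i]]
    n_sp <- n_for(sp)
    if (!is.null(n_sp) && n_sp == 0) {
      warn(sprintf("species '%s' requested with 0 trees: omitted", sp))
      next
    }
    cfg <- simulation_config(sp, n_trees = n_sp, noise = noise, seed = seed + i - 1L)
    pops[[sp]] <- simulate_bark_population(cfg)
    message(sprintf("simulated %s: %d trees, %d measurements (seed %d)",
                    sp, nrow(pops[[sp]]$trees), nrow(pops[[sp]]$sections), cfg$seed))
  }
  if (!length(pops)) abort("no species left to simulate")
  trees <- purrr::map_dfr(pops, "trees")
  sections <- purrr::map_dfr(pops, "sections")
  paths <- list(
    trees = file.path(dir, "trees.csv"),
    sections = file.path(dir, "sections.csv"),
    config = file.path(dir, "config.json")
  )
  readr::write_csv(trees, paths$trees)
  readr::write_csv(sections, paths$sections)
  echo <- purrr::map(pops, function(p) {
    cfg <- p$config
    list(species = cfg$species, n_trees = cfg$n_trees, d0_mean = cfg$d0_mean,
         d0_sd = cfg$d0_sd, d0_min = cfg$d0_min, noise = as.list(cfg$noise),
         seed = cfg$seed)
  })
  jsonlite::write_json(list(top_seed = seed, populations = echo), paths$config,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(populations = pops, paths = paths))
}

#' Read a simulated population back from disk
#'
#' @param dir Directory holding `trees.csv` and `sections.csv` as written
#'   by [run_simulate()].
#' @return A list with tibbles `trees` and `sections`.
#' @export
read_population_csv <- function(dir) {
  trees <- readr::read_csv(file.path(dir, "trees.csv"),
                           col_types = readr::cols(tree_id = readr::col_character(),
                                                   species = readr::col_character(),
                                                   .default = readr::col_double()))
  sections <- readr::read_csv(file.path(dir, "sections.csv"),
                              col_types = readr::cols(tree_id = readr::col_character(),
                                                      position = readr::col_character(),
                                                      .default = readr::col_double()))
  list(trees = trees, sections = sections)
}

#' Fit all model forms to a simulated or measured population
#'
#' Drives the fitting stage over every species present in the data: the
#' linear DBH model, the rational height model and the two power models are
#' fitted per species, a coefficient-table-shaped summary is returned, and
#' the estimates can be written to the shared JSON schema.
#'
#' @param trees,sections Tibbles in the layout written by [run_simulate()];
#'   alternatively `trees` may be a directory path containing the CSVs.
#' @param out_json Optional path: write fitted coefficients via
#'   [write_model_library()].
#' @param thickness_convention Passed to [to_observation_tables()].
#' @return A tibble with one row per species x model x term (estimate,
#'   std.error, p.value, r.squared, mse, n), with the fits in attribute
#'   `"fits"`. Species whose fits fail are reported with a warning and
#'   skipped.
#' @export
run_fit <- function(trees, sections = NULL, out_json = NULL,
                    thickness_convention = c("radial", "diameter")) {
  if (is.character(trees) && length(trees) == 1L) {
    pop <- read_population_csv(trees)
    trees <- pop$trees
    sections <- pop$sections
  }
  stopifnot(is.data.frame(trees), is.data.frame(sections))
  fits <- list()
  for (sp in unique(trees$species)) {
    pop <- structure(
      list(trees = dplyr::filter(trees, .data$species == sp),
           sections = dplyr::semi_join(sections,
                                       dplyr::filter(trees, .data$species == sp),
                                       by = "tree_id")),
      class = "bark_population"
    )
    tabs <- to_observation_tables(pop, thickness_convention)
    res <- tryCatch(
      list(
        dbh = fit_dbh_linear(tabs$dbh),
        height = fit_height_rational(tabs$height),
        radius = fit_power_model(tabs$radius, "radius_cm"),
        thickness = fit_power_model(tabs$thickness, "thickness_mm")
      ),
      error = function(e) {
        warn(sprintf("fit failed for species '%s': %s", sp, conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(res)) fits[[sp]] <- res
  }
  if (!length(fits)) abort("all species failed to fit")
  summary_tbl <- purrr::map_dfr(names(fits), function(sp) {
    purrr::map_dfr(names(fits[[sp]]), function(m) {
      f <- fits[[sp]][[m]]
      dplyr::mutate(tidy(f), species = sp, model = m,
                    r.squared = f$stats$r_squared, mse = f$stats$mse,
                    n = f$stats$n, .before = 1)
    })
  })
  if (!is.null(out_json)) write_model_library(fits, out_json)
  attr(summary_tbl, "fits") <- fits
  summary_tbl
}

#' Tabulate bark profiles over a diameter grid
#'
#' Produces the per-section bark summaries behind profile curves as a tidy
#' table: one row per species x stem-base diameter x section.
#'
#' @param species Character vector of species codes.
#' @param d0 Vector of stem-base diameters (mm).
#' @param density `NULL`, a single density, or a named per-species vector
#'   (kg m^-3); without it the mass/SPH columns are omitted with a warning.
#' @param out_csv Optional path to also write the table as CSV.
#' @return A `bark_profile` tibble (see [bark_profile()]).
#' @export
run_profile <- function(species = bark_species(), d0 = seq(5, 100, by = 5),
                        density = NULL, out_csv = NULL) {
  grid <- tidyr::expand_grid(species = species, d0_mm = d0)
  prof <- bark_profile(grid, density = density)
  if (!is.null(out_csv)) readr::write_csv(prof, out_csv)
  prof
}
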