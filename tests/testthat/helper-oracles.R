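# Independent numerical oracles: every geometric closed form is checked
# against quadrature over the solid of revolution with a linear radius
# profile r(h) = r1 + (r2 - r1) * h / ls.

oracle_lateral_surface <- function(r1, r2, ls) {
  slope <- (r2 - r1) / ls
  f <- function(h) 2 * pi * (r1 + slope * h) * sqrt(1 + slope^2)
  stats::integrate(f, 0, ls, rel.tol = 1e-12, abs.tol = 0)$value
}

oracle_volume <- function(r1, r2, ls) {
  slope <- (r2 - r1) / ls
  f <- function(h) pi * (r1 + slope * h)^2
  stats::integrate(f, 0, ls, rel.tol = 1e-12, abs.tol = 0)$value
}

# annular solid between two linear radius profiles (outer minus inner)
oracle_annular_volume <- function(r1_out, r2_out, r1_in, r2_in, ls) {
  oracle_volume(r1_out, r2_out, ls) - oracle_volume(r1_in, r2_in, ls)
}

# quadrature over the modeled power-law taper r(h) = b0 d0^b1 h^b2:
# the exact surface/volume that the frustum approximation discretises
oracle_power_surface <- function(lib, d0, lower, upper) {
  b <- lib$models$radius$coefficients
  r <- function(h) b[["b0"]] * d0^b[["b1"]] * h^b[["b2"]]
  dr <- function(h) b[["b0"]] * d0^b[["b1"]] * b[["b2"]] * h^(b[["b2"]] - 1)
  stats::integrate(function(h) 2 * pi * r(h) * sqrt(1 + dr(h)^2),
                   lower, upper, rel.tol = 1e-10)$value
}

# mean of a normal truncated below at `lower` (closed form)
truncnorm_mean <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# construct an in-memory coefficient document / model library with arbitrary
# coefficients, for limit-case tests (cylinders, identity maps, collapses)
make_custom_lib <- function(dbh = c(b0 = 0, b1 = 1),
                            height = c(b0 = 0, b1 = 0, b2 = 0.25),
                            radius = c(b0 = 0.05, b1 = 1, b2 = -0.1),
                            thickness = c(b0 = 0.1, b1 = 1, b2 = -0.1),
                            bark_density = NULL,
                            species = "custom") {
  entry <- list(
    dbh = list(form = "linear_dbh", coefficients = as.list(dbh)),
    height = list(form = "rational_height", coefficients = as.list(height)),
    radius = list(form = "power_two_predictor", coefficients = as.list(radius)),
    thickness = list(form = "power_two_predictor", coefficients = as.list(thickness))
  )
  doc <- list(schema = "stembark-coefficients-v1",
              species = setNames(list(entry), species))
  species_model_library(species, bark_density = bark_density, document = doc)
}

# exact observation tables lying on a library's generating curves
exact_power_table <- function(lib, which = c("radius", "thickness"),
                              d0 = seq(10, 90, by = 10), hg = c(5, 25, 75, 150, 240)) {
  which <- match.arg(which)
  grid <- expand.grid(d0_mm = d0, hg_cm = hg)
  response <- if (which == "radius") {
    predict_stem_radius(lib, grid$d0_mm, grid$hg_cm)
  } else {
    predict_bark_thickness(lib, grid$d0_mm, grid$hg_cm)
  }
  tibble::tibble(
    tree_id = as.character(seq_len(nrow(grid))), species = lib$species,
    d0_mm = grid$d0_mm, hg_cm = grid$hg_cm, response = response,
    response_kind = if (which == "radius") "radius_cm" else "thickness_mm"
  )
}
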