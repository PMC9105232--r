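test_that("packaged coefficients match the transcribed table values exactly", {
  aspen <- species_model_library("common_aspen")
  expect_identical(unname(aspen$models$thickness$coefficients["b2"]), -0.144)
  expect_identical(unname(aspen$models$radius$coefficients["b1"]), 1.076)
  expect_identical(unname(aspen$models$dbh$coefficients["b0"]), -3.422)
  expect_identical(unname(species_model_library("goat_willow")$models$radius$coefficients["b1"]), 0.847)
  expect_identical(unname(species_model_library("rowan")$models$dbh$coefficients["b1"]), 0.665)
  expect_identical(unname(species_model_library("sycamore")$models$height$coefficients["b0"]), 84.237)
  # every packaged power model tapers: positive diameter exponent, negative height exponent
  for (sp in bark_species()) {
    lib <- species_model_library(sp)
    for (m in c("radius", "thickness")) {
      expect_gt(lib$models[[m]]$coefficients[["b0"]], 0)
      expect_gt(lib$models[[m]]$coefficients[["b1"]], 0)
      expect_lt(lib$models[[m]]$coefficients[["b2"]], 0)
    }
    expect_gt(lib$models$height$coefficients[["b2"]], 0)
  }
  expect_error(species_model_library("oak"), "common_aspen")
})

test_that("height predictions follow the rational curve and its asymptote", {
  lib <- species_model_library("common_aspen")
  d0 <- 31.9
  expect_equal(predict_height(lib, d0),
               d0^2 / (8.221 + 7.077 * d0 + 0.021 * d0^2))
  expect_equal(predict_height(lib, d0), 3.985, tolerance = 1e-3)
  # saturates at 1/b2
  expect_equal(predict_height(lib, 1e9), 1 / 0.021, tolerance = 1e-4)
  for (sp in bark_species()) {
    l <- species_model_library(sp)
    expect_lt(max(predict_height(l, seq(5, 100, 5))), 1 / l$models$height$coefficients[["b2"]])
  }
  # identity collapse b0 = b1 = 0, b2 = 1
  custom <- make_custom_lib(height = c(b0 = 0, b1 = 0, b2 = 1))
  expect_equal(predict_height(custom, c(3, 42)), c(1, 1))
  # invalid denominator
  neg <- make_custom_lib(height = c(b0 = -100, b1 = 0, b2 = 0.01))
  expect_error(predict_height(neg, 5), "denominator")
})

test_that("DBH predictions follow the fitted line, including its zero crossing", {
  lib <- species_model_library("common_aspen")
  expect_equal(predict_dbh(lib, 100), -3.422 + 0.763 * 100)
  expect_equal(predict_dbh(lib, 3.422 / 0.763), 0, tolerance = 1e-12)
  identity_lib <- make_custom_lib(dbh = c(b0 = 0, b1 = 1))
  expect_equal(predict_dbh(identity_lib, c(1, 5, 80)), c(1, 5, 80))
  expect_error(predict_dbh(lib, -5), "positive")
})

test_that("bark thickness follows the power model with its domain guard", {
  aspen <- species_model_library("common_aspen")
  expect_equal(predict_bark_thickness(aspen, 100, 50),
               0.092 * 100^0.968 * 50^-0.144)
  expect_equal(round(predict_bark_thickness(aspen, 100, 50), 1), 4.5)
  syc <- predict_bark_thickness("sycamore", 100, 50)
  expect_equal(syc, 0.098 * 100^0.659 * 50^-0.072)
  expect_equal(predict_bark_thickness(aspen, 100, 50) / syc, 2.9, tolerance = 0.02)
  # degenerate exponents reduce to the diameter itself
  flat <- make_custom_lib(thickness = c(b0 = 1, b1 = 1, b2 = 0))
  expect_equal(predict_bark_thickness(flat, c(5, 60), 10), c(5, 60))
  expect_error(predict_bark_thickness(aspen, 100, 0.5), "hg")
  expect_warning(predict_bark_thickness(aspen, 150, 50), "extrapolation")
  expect_warning(predict_bark_thickness(aspen, 50, 300), "extrapolation")
})

test_that("stem radius follows the taper model with the base convention", {
  aspen <- species_model_library("common_aspen")
  expect_equal(predict_stem_radius(aspen, 100, 50), 0.038 * 100^1.076 * 50^-0.092)
  expect_equal(predict_stem_radius(aspen, 100, 50), 3.77, tolerance = 1e-2)
  # ground line: half the measured base diameter, mm -> cm
  expect_equal(predict_stem_radius(aspen, 100, 0), 5)
  expect_equal(predict_stem_radius(aspen, c(40, 100), c(0, 50)),
               c(2, 0.038 * 100^1.076 * 50^-0.092))
  scaled <- make_custom_lib(radius = c(b0 = 0.05, b1 = 1, b2 = 0))
  expect_equal(predict_stem_radius(scaled, 60, 123), 3)
})

test_that("thickness is monotone in both predictors and radius declines with height", {
  d0 <- seq(5, 100, by = 5)
  hg <- seq(1, 250, by = 10)
  for (sp in bark_species()) {
    lib <- species_model_library(sp)
    tb <- outer(d0, hg, function(d, h) predict_bark_thickness(lib, d, h))
    expect_true(all(diff(tb) > 0))        # increasing in d0 down columns
    expect_true(all(t(diff(t(tb))) < 0))  # decreasing in hg along rows
    expect_true(all(predict_stem_radius(lib, d0, 250) < predict_stem_radius(lib, d0, 50)))
  }
})

test_that("species rank by bark thickness as reported", {
  th <- vapply(bark_species(), function(sp) predict_bark_thickness(sp, 100, 50), 1)
  expect_identical(names(sort(th, decreasing = TRUE)),
                   c("common_aspen", "goat_willow", "rowan", "sycamore"))
})

test_that("coefficient documents are validated on load", {
  doc <- jsonlite::read_json(system.file("extdata", "bark_model_coefficients.json",
                                         package = "stembark"))
  broken <- doc
  broken$species$rowan$radius$coefficients$b0 <- -1
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(broken, tmp, auto_unbox = TRUE, digits = NA)
  expect_error(read_coefficient_document(tmp), "b0 > 0")
  broken2 <- doc
  broken2$species$rowan$height <- NULL
  jsonlite::write_json(broken2, tmp, auto_unbox = TRUE, digits = NA)
  expect_error(read_coefficient_document(tmp), "lacks model")
  # the packaged document itself round-trips
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA)
  reloaded <- read_coefficient_document(tmp)
  expect_equal(tidy(species_model_library("rowan", document = reloaded)),
               tidy(species_model_library("rowan")))
})

test_that("bark_coefficients returns the full tidy table", {
  tbl <- bark_coefficients()
  expect_s3_class(tbl, "tbl_df")
  # 4 species x (2 + 3 + 3 + 3) terms
  expect_identical(nrow(tbl), 44L)
  expect_identical(unique(tbl$species), bark_species())
  expect_true(all(tbl$std.error > 0))
})
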