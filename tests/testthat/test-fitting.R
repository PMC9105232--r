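test_that("noiseless data refit every packaged model form exactly", {
  for (sp in bark_species()) {
    lib <- species_model_library(sp)
    d0 <- seq(6, 96, by = 6)

    dbh_tab <- tibble::tibble(
      tree_id = as.character(seq_along(d0)), species = sp, d0_mm = d0,
      hg_cm = NA_real_, response = predict_dbh(lib, d0), response_kind = "dbh_mm"
    )
    f <- fit_dbh_linear(dbh_tab)
    expect_equal(tidy(f)$estimate, unname(lib$models$dbh$coefficients),
                 tolerance = 1e-10)

    h_tab <- dbh_tab |>
      dplyr::mutate(response = predict_height(lib, d0), response_kind = "height_m")
    f <- fit_height_rational(h_tab)
    expect_equal(tidy(f)$estimate, unname(lib$models$height$coefficients),
                 tolerance = 1e-6)
    expect_true(glance(f)$converged)

    for (which in c("radius", "thickness")) {
      tab <- exact_power_table(lib, which)
      f <- fit_power_model(tab, unique(tab$response_kind))
      expect_equal(tidy(f)$estimate, unname(lib$models[[which]]$coefficients),
                   tolerance = 1e-6)
      expect_equal(glance(f)$r.squared, 1, tolerance = 1e-9)
    }
  }
})

test_that("degenerate designs are handled: two-point line and constant height", {
  two <- tibble::tibble(tree_id = c("a", "b", "c"), species = "x",
                        d0_mm = c(1e-9, 1, 2), hg_cm = NA_real_,
                        response = c(0, 1, 2), response_kind = "dbh_mm")
  f <- fit_dbh_linear(two)
  expect_equal(tidy(f)$estimate, c(0, 1), tolerance = 1e-8)

  # constant response: H = 2 m for all d0 is reached with b0 = b1 = 0, b2 = 0.5
  const <- tibble::tibble(tree_id = as.character(1:8), species = "x",
                          d0_mm = seq(10, 80, by = 10), hg_cm = NA_real_,
                          response = 2, response_kind = "height_m")
  f <- fit_height_rational(const)
  est <- setNames(tidy(f)$estimate, tidy(f)$term)
  expect_equal(est[["b2"]], 0.5, tolerance = 1e-6)
  expect_lt(abs(est[["b0"]]), 1e-4)
  expect_lt(abs(est[["b1"]]), 1e-5)
})

test_that("goodness_of_fit computes R2 and MSE on residual degrees of freedom", {
  gof <- goodness_of_fit(c(1, 2, 3), c(1, 2, 4), n_params = 1)
  expect_equal(gof$sse, 1)
  expect_equal(gof$mse, 0.5)
  expect_equal(gof$r.squared, 0.5)
  expect_equal(goodness_of_fit(1:5, 1:5, 1)$r.squared, 1)
  expect_equal(goodness_of_fit(1:5, 1:5, 1)$mse, 0)
  obs <- c(4, 6, 8, 2)
  expect_equal(goodness_of_fit(obs, rep(mean(obs), 4), 1)$r.squared, 0)
  expect_error(goodness_of_fit(rep(1, 4), rep(1, 4), 1), "zero total variance")
  expect_error(goodness_of_fit(1:3, 1:3, 3), "more observations")
})

test_that("estimates are invariant to row order; duplication shrinks errors only", {
  lib <- species_model_library("goat_willow")
  set.seed(11)
  tab <- exact_power_table(lib, "radius")
  tab$response <- tab$response + rnorm(nrow(tab), 0, 0.1)
  f1 <- fit_power_model(tab, "radius_cm")
  f2 <- fit_power_model(tab[sample(nrow(tab)), ], "radius_cm")
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-8)
  f3 <- fit_power_model(dplyr::bind_rows(tab, tab), "radius_cm")
  expect_equal(tidy(f3)$estimate, tidy(f1)$estimate, tolerance = 1e-8)
  expect_true(all(tidy(f3)$std.error < tidy(f1)$std.error))
})

test_that("input validation rejects unusable observation tables", {
  lib <- species_model_library("rowan")
  tab <- exact_power_table(lib, "thickness")
  bad <- tab; bad$response[3] <- -1
  expect_error(fit_power_model(bad, "thickness_mm"), "positive")
  expect_error(fit_power_model(dplyr::select(tab, -hg_cm), "thickness_mm"), "hg_cm")
  expect_error(fit_power_model(tab, "radius_cm"), "response_kind")
  const <- tibble::tibble(tree_id = "1", species = "x", d0_mm = rep(10, 5),
                          hg_cm = NA_real_, response = 1:5, response_kind = "dbh_mm")
  expect_error(fit_dbh_linear(const), "identical")
})

test_that("coefficient estimates are unbiased at the study's scale", {
  lib <- species_model_library("common_aspen")
  b_dbh <- lib$models$dbh$coefficients
  sd_dbh <- sqrt(lib$models$dbh$mse)
  b_rad <- lib$models$radius$coefficients
  sd_rad <- sqrt(lib$models$radius$mse)
  set.seed(321)
  reps <- 200
  slope <- numeric(reps)
  b1_rad <- numeric(reps)
  for (r in seq_len(reps)) {
    d0 <- rnorm(180, 31.9, 21.1); d0 <- d0[d0 >= 10][1:120]
    tab <- tibble::tibble(tree_id = as.character(seq_along(d0)), species = "common_aspen",
                          d0_mm = d0, hg_cm = NA_real_,
                          response = b_dbh[["b0"]] + b_dbh[["b1"]] * d0 + rnorm(length(d0), 0, sd_dbh),
                          response_kind = "dbh_mm")
    slope[r] <- tidy(fit_dbh_linear(tab))$estimate[2]

    d0r <- abs(rnorm(150, 31.9, 21.1)) + 5
    hg <- runif(150, 1, 250)
    rtab <- tibble::tibble(tree_id = as.character(1:150), species = "common_aspen",
                           d0_mm = d0r, hg_cm = hg,
                           response = pmax(b_rad[["b0"]] * d0r^b_rad[["b1"]] * hg^b_rad[["b2"]] +
                                             rnorm(150, 0, sd_rad), 0.01),
                           response_kind = "radius_cm")
    b1_rad[r] <- tidy(fit_power_model(rtab, "radius_cm"))$estimate[2]
  }
  # mean estimates within one printed standard error of the generating truth
  expect_lt(abs(mean(slope) - 0.763), 0.022)
  expect_lt(abs(mean(b1_rad) - 1.076), 0.010)
})

test_that("p-values of a truly-zero coefficient are uniform", {
  set.seed(99)
  reps <- 200
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    d0 <- runif(25, 5, 100)
    tab <- tibble::tibble(tree_id = as.character(1:25), species = "x",
                          d0_mm = d0, hg_cm = NA_real_,
                          response = 0.7 * d0 + rnorm(25, 0, 4),  # true intercept 0
                          response_kind = "dbh_mm")
    pvals[r] <- tidy(fit_dbh_linear(tab))$p.value[1]
  }
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("fits expose broom verbs and loadable bark models", {
  lib <- species_model_library("sycamore")
  tab <- exact_power_table(lib, "thickness")
  f <- fit_power_model(tab, "thickness_mm")
  expect_named(tidy(f), c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_identical(nrow(glance(f)), 1L)
  aug <- augment(f)
  expect_equal(aug$.fitted + aug$.resid, aug$response)
  expect_equal(predict(f, tibble::tibble(d0_mm = 50, hg_cm = 50)),
               predict_bark_thickness(lib, 50, 50), tolerance = 1e-6)
  m <- as_bark_model(f)
  expect_s3_class(m, "bark_model")
  expect_equal(unname(m$coefficients), unname(lib$models$thickness$coefficients),
               tolerance = 1e-6)
})
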