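.resolve_model <- function(object, which) {
  if (inherits(object, "species_model_library")) return(object$models[[which]])
  if (inherits(object, "bark_model")) return(object)
  if (is.character(object) && length(object) == 1L) {
    return(species_model_library(object)$models[[which]])
  }
  abort("expected a species code, a species_model_library or a bark_model")
}

.check_d0 <- function(d0) {
  if (!is.numeric(d0) || anyNA(d0) || any(d0 <= 0)) {
    abort("d0 must be a positive stem-base diameter in mm")
  }
}

# the power models were fitted on trees up to d0 = 100 mm and stem heights
# up to 250 cm; beyond that they extrapolate
.warn_extrapolation <- function(d0, hg) {
  if (any(d0 > 100)) {
    warn("d0 > 100 mm lies beyond the fitted range; predictions are extrapolations")
  }
  if (any(hg > 250)) {
    warn("hg > 250 cm lies above the modeled stem profile; predictions are extrapolations")
  }
}

#' Predict tree height from stem-base diameter
#'
#' Evaluates the rational height model
#' \deqn{H = D_0^2 / (b_0 + b_1 D_0 + b_2 D_0^2),}
#' with `H` in metres and `D0` in millimetres. Because `b2 > 0` for every
#' packaged species, the curve saturates at the asymptote `1/b2` for large
#' trees.
#'
#' @param object A species code, a [species_model_library()] or the height
#'   `bark_model` itself.
#' @param d0 Stem-base diameter in mm (> 0). Vectorised.
#' @return Predicted height in metres.
#' @examples
#' predict_height("common_aspen", d0 = 31.9)
#' @export
predict_height <- function(object, d0) {
  m <- .resolve_model(object, "height")
  .check_d0(d0)
  b <- m$coefficients
  denom <- b[["b0"]] + b[["b1"]] * d0 + b[["b2"]] * d0^2
  if (any(denom <= 0)) {
    abort("height model denominator b0 + b1*d0 + b2*d0^2 is non-positive: model invalid at this d0")
  }
  d0^2 / denom
}

#' Predict diameter at breast height from stem-base diameter
#'
#' Evaluates the linear model `DBH = b0 + b1 * D0` (both in mm). The fitted
#' lines cross zero near d0 of 5--8 mm, so predictions for very small trees
#' can be negative; callers needing physical diameters must clamp or filter.
#'
#' @inheritParams predict_height
#' @return Predicted DBH in mm (possibly negative for small `d0`).
#' @export
predict_dbh <- function(object, d0) {
  m <- .resolve_model(object, "dbh")
  .check_d0(d0)
  b <- m$coefficients
  b[["b0"]] + b[["b1"]] * d0
}

#' Predict bark thickness at a height on the stem
#'
#' Evaluates the two-predictor power model
#' \deqn{T_b = b_0 D_0^{b_1} H_g^{b_2},}
#' with thickness in mm, `D0` in mm and `Hg` (height above ground) in cm.
#' With `b2 < 0` the model diverges as `hg` approaches 0, and it was fitted
#' from section measurements whose lowest positions sit above the ground, so
#' evaluation below `hg = 1` cm is rejected rather than extrapolated.
#'
#' @inheritParams predict_height
#' @param hg Height above ground in cm, >= 1. Vectorised; recycled
#'   against `d0`.
#' @return Bark thickness in mm.
#' @examples
#' predict_bark_thickness("common_aspen", d0 = 100, hg = 50)  # ~4.5 mm
#' @export
predict_bark_thickness <- function(object, d0, hg) {
  m <- .resolve_model(object, "thickness")
  .check_d0(d0)
  if (!is.numeric(hg) || anyNA(hg) || any(hg < 1)) {
    abort("hg must be >= 1 cm: the thickness power law diverges at the ground line")
  }
  .warn_extrapolation(d0, hg)
  b <- m$coefficients
  b[["b0"]] * d0^b[["b1"]] * hg^b[["b2"]]
}

#' Predict stem radius (over bark) at a height on the stem
#'
#' Evaluates the stem-taper power model
#' \deqn{r = b_0 D_0^{b_1} H_g^{b_2},}
#' with the radius in cm, `D0` in mm and `Hg` in cm. At the ground line
#' (`hg = 0`), where the power law diverges, the radius is taken as half the
#' measured stem-base diameter, `d0 / 20` cm (mm to cm conversion included);
#' the fitted curves already approach this value a few cm above ground.
#'
#' @inheritParams predict_bark_thickness
#' @param hg Height above ground in cm, >= 0.
#' @return Stem radius in cm.
#' @examples
#' predict_stem_radius("common_aspen", d0 = 100, hg = 50)  # ~3.77 cm
#' predict_stem_radius("common_aspen", d0 = 100, hg = 0)   # 5 cm by convention
#' @export
predict_stem_radius <- function(object, d0, hg) {
  m <- .resolve_model(object, "radius")
  .check_d0(d0)
  if (!is.numeric(hg) || anyNA(hg) || any(hg < 0)) {
    abort("hg must be >= 0 cm")
  }
  .warn_extrapolation(d0, hg)
  b <- m$coefficients
  n <- max(length(d0), length(hg))
  d0 <- rep_len(d0, n)
  hg <- rep_len(hg, n)
  out <- numeric(n)
  at_base <- hg == 0
  out[at_base] <- d0[at_base] / 20
  out[!at_base] <- b[["b0"]] * d0[!at_base]^b[["b1"]] * hg[!at_base]^b[["b2"]]
  out
}

#' Evaluate all four allometries over a grid of trees
#'
#' Data-frame-first convenience wrapper: takes a tibble of trees with
#' `species` and `d0_mm` columns and appends predicted height, DBH, and --
#' at a reference height `hg` -- bark thickness and stem radius.
#'
#' @param data A data frame with columns `species` and `d0_mm`.
#' @param hg Reference height above ground (cm) for thickness and radius.
#' @return The input as a tibble with columns `height_m`, `dbh_mm`,
#'   `thickness_mm`, `radius_cm` added.
#' @export
predict_allometries <- function(data, hg = 50) {
  stopifnot(is.data.frame(data), all(c("species", "d0_mm") %in% names(data)))
  data |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(
      height_m = predict_height(.data$species[[1]], .data$d0_mm),
      dbh_mm = predict_dbh(.data$species[[1]], .data$d0_mm),
      thickness_mm = predict_bark_thickness(.data$species[[1]], .data$d0_mm, .env$hg),
      radius_cm = predict_stem_radius(.data$species[[1]], .data$d0_mm, .env$hg)
    ) |>
    dplyr::ungroup()
}
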