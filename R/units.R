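#' Convert between metric length and area units
#'
#' Exact power-of-ten rescaling between the units that appear throughout the
#' bark models: millimetres (stem diameters, bark thickness), centimetres
#' (heights above ground, radii, section lengths), decimetres (specific
#' surface mass is reported per dm^2) and metres (tree height). Squared units
#' (`"mm2"`, `"cm2"`, `"dm2"`, `"m2"`) are supported for areas.
#'
#' @param x Numeric vector of values to convert.
#' @param from,to Unit symbols: one of `"mm"`, `"cm"`, `"dm"`, `"m"` or their
#'   squares `"mm2"`, `"cm2"`, `"dm2"`, `"m2"`. `from` and `to` must both be
#'   lengths or both be areas.
#'
#' @return A numeric vector of the same length as `x`.
#' @examples
#' convert_units(100, "mm", "cm")   # 10
#' convert_units(1256.6, "cm2", "dm2")
#' @export
convert_units <- function(x, from, to) {
  stopifnot(is.numeric(x))
  exp_from <- .unit_exponent(from)
  exp_to <- .unit_exponent(to)
  if (attr(exp_from, "kind") != attr(exp_to, "kind")) {
    abort(sprintf("cannot convert between '%s' and '%s': different dimensions", from, to))
  }
  x * 10^(as.numeric(exp_from) - as.numeric(exp_to))
}

# decimal exponent relative to the metre (mm = -3, cm = -2, ...), doubled for areas
.unit_exponent <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L) {
    abort("unit must be a single character string")
  }
  base <- c(mm = -3, cm = -2, dm = -1, m = 0)
  squared <- grepl("2$", unit)
  stem <- sub("2$", "", unit)
  if (!stem %in% names(base)) {
    abort(sprintf("unknown unit '%s'; expected mm, cm, dm, m or their squares", unit))
  }
  out <- unname(base[[stem]]) * (if (squared) 2L else 1L)
  attr(out, "kind") <- if (squared) "area" else "length"
  out
}
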