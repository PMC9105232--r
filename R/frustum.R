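#' Lateral surface area of a truncated cone
#'
#' A stem section between two heights is approximated by a frustum (truncated
#' cone) with end radii `r1` and `r2` and length `ls`. Its lateral (bark)
#' surface, omitting the base and top circles, is
#' \deqn{S = \pi (r_1 + r_2) \sqrt{(r_1 - r_2)^2 + l_s^2}.}
#'
#' All arguments are in centimetres; the result is in cm^2. The radii are
#' positional, not sorted: `r1` and `r2` may come in either order and the
#' result is symmetric under swapping them. Zero radii are allowed (a full
#' cone); a non-positive section length is rejected.
#'
#' @param r1,r2 End radii (cm), each >= 0. Vectorised, recycled against `ls`.
#' @param ls Section length (cm), > 0.
#'
#' @return Lateral surface area (cm^2), strictly positive.
#' @seealso [frustum_volume()]
#' @examples
#' frustum_surface(2, 2, 10)        # cylinder: 2*pi*2*10
#' frustum_surface(4, 1, 4)         # 3-4-5 slant: pi*5*5
#' @export
frustum_surface <- function(r1, r2, ls) {
  .check_frustum(r1, r2, ls)
  pi * (r1 + r2) * sqrt((r1 - r2)^2 + ls^2)
}

#' Volume of a truncated cone
#'
#' Volume of the frustum approximating a stem section,
#' \deqn{V = \tfrac{1}{3} \pi l_s (r_1^2 + r_1 r_2 + r_2^2),}
#' in cm^3 with all arguments in centimetres. Symmetric in `r1`, `r2`;
#' `r2 = 0` gives the full cone and `r1 = r2` the cylinder.
#'
#' @inheritParams frustum_surface
#' @return Volume (cm^3), strictly positive (radii not both zero).
#' @seealso [frustum_surface()]
#' @examples
#' frustum_volume(2, 1, 3)   # 7 * pi
#' @export
frustum_volume <- function(r1, r2, ls) {
  .check_frustum(r1, r2, ls)
  pi / 3 * ls * (r1^2 + r1 * r2 + r2^2)
}

.check_frustum <- function(r1, r2, ls) {
  for (nm in c("r1", "r2", "ls")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v)) {
      abort(sprintf("frustum field '%s' must be numeric and non-missing", nm))
    }
  }
  if (any(r1 < 0)) abort("frustum field 'r1' must be >= 0")
  if (any(r2 < 0)) abort("frustum field 'r2' must be >= 0")
  if (any(ls <= 0)) abort("frustum field 'ls' must be > 0")
  invisible(NULL)
}
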