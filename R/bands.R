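#' Assign elevations to 100-m elevational bands
#'
#' Sites and occurrences are stratified into elevational bands of fixed width
#' (100 m by default).  A band is the half-open interval
#' \eqn{[\mathrm{lower}, \mathrm{lower} + w)} and is keyed by its lower bound,
#' so a site at 1650 m a.s.l. belongs to, and is referred to as, the 1600-m
#' band.
#'
#' @param elevation numeric vector of elevations in metres a.s.l.;
#'   must be finite and non-negative.
#' @param width band width in metres (default 100).
#' @return numeric vector of band lower bounds (multiples of `width`).
#' @examples
#' assign_band(c(1650, 1600, 2599))
#' @export
assign_band <- function(elevation, width = 100) {
  if (!is.numeric(elevation)) {
    stop("`elevation` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(elevation)) || any(elevation < 0)) {
    stop("`elevation` must be finite and non-negative", call. = FALSE)
  }
  floor(elevation / width) * width
}
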