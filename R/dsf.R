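# nanoDSF melting-curve operations: melting-temperature extraction from the
# 350/330 nm intrinsic-fluorescence ratio along a thermal ramp.

#' Extract the melting temperature from a nanoDSF ratio curve
#'
#' Smooths the 350/330 nm fluorescence ratio versus temperature with a
#' cubic smoothing spline and locates the melting temperature Tm as the
#' extremum of the first derivative (the inflection of the two-state
#' unfolding transition). A curve with no resolvable transition — flat, or
#' with its steepest slope on the ramp boundary — raises a
#' `"peptherm_no_transition"` error rather than returning a spurious Tm.
#'
#' @param curve Data frame with columns `temp_C` and `ratio`.
#' @param spar Smoothing parameter passed to [stats::smooth.spline()];
#'   `NULL` lets generalised cross-validation choose it.
#' @param min_amplitude Minimum ratio change across the ramp, as a multiple
#'   of the residual noise level, below which the curve is declared
#'   transition-free.
#' @return List of class `"tm_fit"`: `Tm` (degC), `slope_at_Tm`
#'   (ratio/degC), `amplitude`, `direction` (+1 ratio rises on unfolding,
#'   -1 falls).
#' @examples
#' d <- generate_scenario("dsf_melt", seed = 1)
#' extract_tm(d$data)$Tm
#' @export
extract_tm <- function(curve, spar = NULL, min_amplitude = 5) {
  stopifnot(all(c("temp_C", "ratio") %in% names(curve)))
  curve <- curve[order(curve$temp_C), , drop = FALSE]
  if (nrow(curve) < 10) stop("melting curve needs at least 10 points")
  sp <- if (is.null(spar))
    stats::smooth.spline(curve$temp_C, curve$ratio)
  else
    stats::smooth.spline(curve$temp_C, curve$ratio, spar = spar)
  noise <- stats::sd(curve$ratio - stats::predict(sp, curve$temp_C)$y)
  grid <- seq(min(curve$temp_C), max(curve$temp_C), length.out = 1000)
  d1 <- stats::predict(sp, grid, deriv = 1)$y
  amp <- diff(range(stats::predict(sp, grid)$y))
  if (amp < min_amplitude * max(noise, .Machine$double.eps))
    stop(structure(class = c("peptherm_no_transition", "error", "condition"),
                   list(message = "no unfolding transition detected (flat curve)",
                        call = sys.call())))
  i <- which.max(abs(d1))
  # an extremum on the boundary means the transition is not resolved in-ramp
  if (i <= 2 || i >= length(grid) - 1)
    stop(structure(class = c("peptherm_no_transition", "error", "condition"),
                   list(message = "no interior unfolding transition in the ramp",
                        call = sys.call())))
  structure(list(Tm = grid[i], slope_at_Tm = d1[i], amplitude = amp,
                 direction = sign(d1[i])), class = "tm_fit")
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("Tm = %.2f degC (slope %.3g per degC, %s transition)\n",
              x$Tm, x$slope_at_Tm,
              if (x$direction > 0) "rising" else "falling"))
  invisible(x)
}
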