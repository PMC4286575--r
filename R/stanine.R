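#' Stanine cut-point presets
#'
#' The stanine ("standard nine") scale maps a normally distributed score to
#' integers 1--9 with population mean 5 and standard deviation 2. The
#' `"classical"` preset uses the textbook z-boundaries at
#' \eqn{\pm 0.25, \pm 0.75, \pm 1.25, \pm 1.75}, which place 4% of the
#' population in the top category. The `"top5"` preset raises only the upper
#' boundary to \eqn{\Phi^{-1}(0.95) = 1.6449} so that 5% of the population
#' reaches stanine 9, matching cohorts where the observed top fraction is 5%.
#'
#' @param preset `"classical"` or `"top5"`.
#' @return Numeric vector of 8 strictly ascending z-boundaries.
#' @export
#' @examples
#' stanine_cutpoints()
#' stanine_cutpoints("top5")
stanine_cutpoints <- function(preset = c("classical", "top5")) {
  preset <- match.arg(preset)
  cp <- c(-1.75, -1.25, -0.75, -0.25, 0.25, 0.75, 1.25, 1.75)
  if (preset == "top5") cp[8] <- stats::qnorm(0.95)
  cp
}

# avoids the argument of the same name shadowing the function in defaults
default_stanine_cutpoints <- function() stanine_cutpoints("top5")

#' Discretise standardized scores onto the stanine scale
#'
#' Assigns score `k` when the z-value lies in the half-open interval
#' `(cutpoints[k-1], cutpoints[k]]`, with the outer categories open-ended.
#' On standard-normal input with the classical cut-points the resulting
#' integer scale has mean ~5 and SD ~2.
#'
#' @param z Numeric vector of standardized scores.
#' @param cutpoints 8 strictly ascending z-boundaries.
#' @return Integer vector of stanine scores in 1..9.
#' @export
#' @examples
#' stanine_transform(c(-3, 0, 2.5))
stanine_transform <- function(z, cutpoints = stanine_cutpoints()) {
  if (length(cutpoints) != 8L || any(diff(cutpoints) <= 0)) {
    stop("`cutpoints` must be 8 strictly ascending z-boundaries", call. = FALSE)
  }
  findInterval(z, cutpoints, left.open = TRUE) + 1L
}
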