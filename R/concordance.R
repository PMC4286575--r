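#' Pairwise and probandwise concordance
#'
#' Pairwise concordance is the proportion of proband-containing pairs in
#' which both members are probands, `c / (c + d)`. Probandwise concordance
#' is the proportion of probands whose partner is also a proband,
#' `2c / (2c + d)`; it estimates the morbidity risk to the relative of a
#' proband and is always at least the pairwise value. Both use only pairs
#' containing at least one proband in the denominator.
#'
#' @param t A [contingency2x2()].
#' @return A proportion in [0, 1].
#' @export
#' @examples
#' pairwise_concordance(contingency2x2(3302, 25037, 0))    # 0.117
#' probandwise_concordance(contingency2x2(3302, 25037, 0)) # 0.209
pairwise_concordance <- function(t) {
  stopifnot(inherits(t, "contingency2x2"))
  denom <- t$n_concordant_high + t$n_discordant
  if (denom == 0) stop("no proband-containing pairs: concordance undefined", call. = FALSE)
  t$n_concordant_high / denom
}

#' @rdname pairwise_concordance
#' @export
probandwise_concordance <- function(t) {
  stopifnot(inherits(t, "contingency2x2"))
  if (t$n_concordant_high + t$n_discordant == 0) {
    stop("no proband-containing pairs: concordance undefined", call. = FALSE)
  }
  2 * t$n_concordant_high / (2 * t$n_concordant_high + t$n_discordant)
}

#' Rough heritability from the MZ-DZ concordance difference
#'
#' Doubles the difference between the MZ and DZ probandwise concordances.
#' Because concordances ignore the population base rate this is only a
#' rough screen, not a liability-scale estimate; values outside [0, 1)
#' trigger a warning rather than being clipped.
#'
#' @param probandwise_mz,probandwise_dz Probandwise concordances.
#' @return Numeric estimate, attribute `rough = TRUE`.
#' @export
#' @examples
#' concordance_h2(0.45, 0.25)  # 0.40
concordance_h2 <- function(probandwise_mz, probandwise_dz) {
  h2 <- 2 * (probandwise_mz - probandwise_dz)
  if (h2 < 0 || h2 >= 1) {
    warning(sprintf("concordance-difference heritability %.3f is outside [0, 1)", h2),
            call. = FALSE)
  }
  structure(h2, rough = TRUE)
}

#' Concordance summary for each relationship class
#'
#' @param tables Named list of [contingency2x2()] objects.
#' @return Data frame with totals, concordant/discordant counts and both
#'   concordance measures, one row per relationship class.
#' @export
concordance_table <- function(tables) {
  rows <- lapply(tables, function(t) {
    data.frame(relationship = t$relationship,
               n_pairs = t$n_concordant_high + t$n_discordant,
               n_concordant = t$n_concordant_high,
               n_discordant = t$n_discordant,
               pairwise = pairwise_concordance(t),
               probandwise = probandwise_concordance(t),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
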