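#' Remove the birth-year trend and standardize scores
#'
#' Stacks both members of every pair (each individual entering once),
#' regresses the score on birth year by ordinary least squares, and divides
#' the residuals by their sample SD, so the adjusted population has mean 0
#' and SD 1. With a single birth year in the data the regression is skipped
#' and plain standardization applied.
#'
#' @param pairs A pair table.
#' @param score Which score pair to adjust: `"stanine"` (the registry-style
#'   integer score; the default, as only stanines exist in the cohorts this
#'   emulates) or `"latent"` (the continuous simulated score).
#' @return The pair table with `score_1`, `score_2` replaced by adjusted
#'   z-scores; class `std_pair_table`.
#' @export
adjust_and_standardize <- function(pairs, score = c("stanine", "latent")) {
  score <- match.arg(score)
  cols <- if (score == "stanine" && "stanine_1" %in% names(pairs)) {
    c("stanine_1", "stanine_2")
  } else {
    c("score_1", "score_2")
  }
  y <- c(pairs[[cols[1]]], pairs[[cols[2]]])
  x <- c(pairs$birth_year_1, pairs$birth_year_2)
  if (stats::sd(y) == 0) stop("scores are constant: cannot standardize", call. = FALSE)
  res <- if (length(unique(x)) > 1L) stats::lm.fit(cbind(1, x), y)$residuals else y - mean(y)
  z <- res / stats::sd(res)
  n <- nrow(pairs)
  pairs$score_1 <- z[seq_len(n)]
  pairs$score_2 <- z[n + seq_len(n)]
  class(pairs) <- unique(c("std_pair_table", class(pairs)))
  pairs
}

#' Flag probands (extreme-group members)
#'
#' @param pairs A standardized pair table.
#' @param rule `"top-stanine"` (proband iff stanine = 9, requires stanine
#'   columns) or `list(quantile = q)` flagging individuals at or above the
#'   empirical `(1 - q)` quantile of the adjusted score (ties included).
#' @return The table with logical columns `proband_1`, `proband_2`.
#' @export
flag_probands <- function(pairs, rule = "top-stanine") {
  if (is.list(rule)) {
    q <- rule$quantile
    if (is.null(q) || q <= 0 || q >= 1) stop("quantile rule needs 0 < q < 1", call. = FALSE)
    all_scores <- c(pairs$score_1, pairs$score_2)
    if (stats::sd(all_scores) == 0) {
      stop("scores are constant: proband threshold undefined", call. = FALSE)
    }
    thr <- stats::quantile(all_scores, 1 - q, names = FALSE)
    pairs$proband_1 <- pairs$score_1 >= thr
    pairs$proband_2 <- pairs$score_2 >= thr
  } else if (identical(rule, "top-stanine")) {
    if (!all(c("stanine_1", "stanine_2") %in% names(pairs))) {
      stop("top-stanine rule requires stanine_1/stanine_2 columns", call. = FALSE)
    }
    pairs$proband_1 <- pairs$stanine_1 == 9L
    pairs$proband_2 <- pairs$stanine_2 == 9L
  } else {
    stop("rule must be \"top-stanine\" or list(quantile = q)", call. = FALSE)
  }
  if (!any(pairs$proband_1 | pairs$proband_2)) {
    stop("no probands under this rule", call. = FALSE)
  }
  pairs
}

#' Construct a symmetric 2x2 pair contingency table
#'
#' Pair members are exchangeable, so the table is stored in collapsed
#' symmetric form: both-proband, exactly-one-proband (discordant), and
#' neither-proband counts.
#'
#' @param n_concordant_high,n_discordant,n_concordant_low Non-negative
#'   pair counts.
#' @param relationship Optional relationship label (MZ/DZ/SIB).
#' @return A `contingency2x2` object.
#' @export
#' @examples
#' contingency2x2(54, 131, 2854, "MZ")
contingency2x2 <- function(n_concordant_high, n_discordant, n_concordant_low,
                           relationship = NA_character_) {
  counts <- unname(c(n_concordant_high, n_discordant, n_concordant_low))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(
    list(relationship = relationship,
         n_concordant_high = counts[1],
         n_discordant = counts[2],
         n_concordant_low = counts[3],
         n_total = sum(counts)),
    class = "contingency2x2"
  )
}

#' @export
print.contingency2x2 <- function(x, ...) {
  cat(sprintf("2x2 pair table (%s): both-high %d, discordant %d, both-low %d (total %d)\n",
              x$relationship, x$n_concordant_high, x$n_discordant,
              x$n_concordant_low, x$n_total))
  invisible(x)
}

#' Reduce flagged pairs to a 2x2 contingency table
#'
#' @param pairs A pair table with proband flags.
#' @param relationship Relationship class to tabulate (MZ, DZ or SIB).
#' @return A [contingency2x2()] for that class.
#' @export
to_contingency <- function(pairs, relationship) {
  if (!all(c("proband_1", "proband_2") %in% names(pairs))) {
    stop("proband flags missing: run flag_probands() first", call. = FALSE)
  }
  sub <- pairs[pairs$relationship == relationship, ]
  k <- sub$proband_1 + sub$proband_2
  contingency2x2(sum(k == 2L), sum(k == 1L), sum(k == 0L), relationship)
}

#' Mean adjusted scores of probands and their pair partners
#'
#' Concordant pairs are double-entered: each proband contributes once, with
#' the other member as partner, so the number of proband-partner
#' observations equals `2 * n_concordant_high + n_discordant`.
#'
#' @param pairs A standardized, flagged pair table.
#' @param relationship Relationship class to summarize.
#' @return List with `relationship`, `proband_mean`, `cotwin_mean`,
#'   `population_mean` (0 by construction upstream), `n_probands`.
#' @export
summarize_extreme_group <- function(pairs, relationship) {
  sub <- pairs[pairs$relationship == relationship, ]
  p <- c(sub$score_1[sub$proband_1], sub$score_2[sub$proband_2])
  co <- c(sub$score_2[sub$proband_1], sub$score_1[sub$proband_2])
  if (!length(p)) stop("no probands in relationship class ", relationship, call. = FALSE)
  list(relationship = relationship,
       proband_mean = mean(p),
       cotwin_mean = mean(co),
       population_mean = 0,
       n_probands = length(p))
}
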