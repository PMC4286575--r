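#' Group correlation of an extreme group and its relatives
#'
#' The ratio of the relatives' mean deviation from the population mean to
#' the probands' mean deviation: the fraction of the proband-population
#' gap retained after regression to the mean (in selection terms, response
#' over selection differential).
#'
#' @param proband_mean,cotwin_mean,population_mean Group means on a common
#'   scale.
#' @return A proportion (1 = no regression to the mean, 0 = complete).
#' @export
#' @examples
#' group_correlation(1.98, 1.39)  # 0.70
#' group_correlation(1.98, 0.81)  # 0.41
group_correlation <- function(proband_mean, cotwin_mean, population_mean = 0) {
  if (proband_mean == population_mean) {
    stop("proband mean equals population mean: group correlation undefined",
         call. = FALSE)
  }
  (cotwin_mean - population_mean) / (proband_mean - population_mean)
}

#' Group ACE components by doubling the MZ-DZ group-correlation gap
#'
#' Group heritability is \eqn{2 (g_{MZ} - g_{DZ})}; the companion shared
#' and non-shared components are \eqn{g_{MZ} - h^2_g} and \eqn{1 - g_{MZ}},
#' so the triple sums to 1. These describe the proband-population *mean
#' difference*, not individual differences.
#'
#' @param g_mz,g_dz MZ and DZ/sibling group correlations.
#' @return Named vector `(group_h2, group_c2, group_e2)`.
#' @export
#' @examples
#' group_h2_doubling(0.70, 0.48)  # group h2 = 0.44
group_h2_doubling <- function(g_mz, g_dz) {
  h2 <- 2 * (g_mz - g_dz)
  c(group_h2 = h2, group_c2 = g_mz - h2, group_e2 = 1 - g_mz)
}

#' Transform flagged pairs into DF regression rows
#'
#' Builds one row per proband (concordant pairs double-entered: each member
#' once as proband with the other as co-twin). Scores are expressed as
#' deviations from the population mean divided by the relationship-specific
#' proband mean deviation, so transformed proband means are 1 in every
#' class, MZ/DZ proband mean differences are absorbed, and the partial
#' regression on relatedness estimates group heritability directly.
#'
#' @param pairs A standardized, flagged pair table.
#' @param population_mean Population mean of the adjusted score (0 by
#'   construction upstream).
#' @param pooled_divisor Use one pooled proband mean deviation for all
#'   classes (the basic DF transform) instead of class-specific divisors.
#' @return Data frame with `proband`, `cotwin`, `R` (1 for MZ, 0.5 for
#'   DZ/SIB), `relationship`, `family_id`.
#' @export
df_transform <- function(pairs, population_mean = 0, pooled_divisor = FALSE) {
  if (!all(c("proband_1", "proband_2") %in% names(pairs))) {
    stop("proband flags missing: run flag_probands() first", call. = FALSE)
  }
  rows <- lapply(split(pairs, pairs$relationship), function(sub) {
    p <- c(sub$score_1[sub$proband_1], sub$score_2[sub$proband_2]) - population_mean
    co <- c(sub$score_2[sub$proband_1], sub$score_1[sub$proband_2]) - population_mean
    fam <- c(sub$family_id[sub$proband_1], sub$family_id[sub$proband_2])
    if (!length(p)) {
      stop("no probands in relationship class ", sub$relationship[1], call. = FALSE)
    }
    data.frame(relationship = sub$relationship[1], family_id = fam,
               proband = p, cotwin = co, divisor = mean(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  div <- if (pooled_divisor) mean(out$proband) else out$divisor
  out$proband <- out$proband / div
  out$cotwin <- out$cotwin / div
  out$divisor <- NULL
  out$R <- ifelse(out$relationship == "MZ", 1, 0.5)
  out[c("proband", "cotwin", "R", "relationship", "family_id")]
}

#' Fit the DF extremes regression
#'
#' Ordinary least squares of the co-twin score C on the proband score P and
#' the coefficient of genetic relatedness R (1 for MZ, 0.5 for DZ and
#' non-twin siblings): `C = b1 P + b2 R + A`. On [df_transform()]ed scores
#' `b2` is the group heritability; `b1` is the average twin resemblance
#' independent of R. Group correlations are the class means of the
#' transformed co-twin scores, and the group ACE triple
#' (`b2`, `g_MZ - b2`, `1 - g_MZ`) sums to 1. Confidence intervals come
#' from a nonparametric bootstrap over probands' families, which respects
#' the dependence introduced by double entry.
#'
#' @param rows Output of [df_transform()].
#' @param n_boot Bootstrap resamples (0 to skip CIs).
#' @param seed Seed for the bootstrap resampling.
#' @param level Confidence level.
#' @return A `df_fit` with coefficients, group correlations, group ACE
#'   components and percentile bootstrap CIs.
#' @export
fit_df <- function(rows, n_boot = 2000, seed = 1L, level = 0.95) {
  if (length(unique(rows$R)) < 2L) {
    stop("both relatedness levels (1 and 0.5) required: model unidentified",
         call. = FALSE)
  }
  est1 <- function(d) {
    X <- cbind(1, P = d$proband, R = d$R)
    beta <- stats::lm.fit(X, d$cotwin)$coefficients
    g_mz <- mean(d$cotwin[d$R == 1])
    g_dz <- mean(d$cotwin[d$R == 0.5])
    c(intercept = beta[[1]], beta1 = beta[[2]], beta2 = beta[[3]],
      group_h2 = beta[[3]], group_c2 = g_mz - beta[[3]], group_e2 = 1 - g_mz,
      group_r_mz = g_mz, group_r_dz = g_dz)
  }
  est <- est1(rows)
  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    fams <- split(seq_len(nrow(rows)), rows$family_id)
    strata <- vapply(fams, function(i) rows$R[i[1]], 0)  # resample within class
    by_R <- split(seq_along(fams), strata)
    boot <- replicate(n_boot, {
      pick <- unlist(lapply(by_R, function(i) sample(i, length(i), replace = TRUE)))
      est1(rows[unlist(fams[pick]), ])
    })
    alpha <- (1 - level) / 2
    ci <- apply(boot, 1, stats::quantile, probs = c(alpha, 1 - alpha))
  }
  structure(
    list(estimates = est, ci = ci, n_rows = nrow(rows),
         n_boot = n_boot, seed = seed),
    class = "df_fit"
  )
}

#' @export
print.df_fit <- function(x, ...) {
  e <- x$estimates
  fmt <- function(nm) {
    if (is.null(x$ci)) sprintf("%.2f", e[[nm]])
    else sprintf("%.2f (%.2f-%.2f)", e[[nm]], x$ci[1, nm], x$ci[2, nm])
  }
  cat(sprintf("DF extremes regression (%d proband rows, %d bootstrap resamples)\n",
              x$n_rows, x$n_boot))
  cat(sprintf("  b1 (twin resemblance) = %s, b2 = %s, intercept = %.2f\n",
              fmt("beta1"), fmt("beta2"), e[["intercept"]]))
  cat(sprintf("  group correlations: MZ %s, DZ/SIB %s\n",
              fmt("group_r_mz"), fmt("group_r_dz")))
  cat(sprintf("  group ACE: A = %s, C = %s, E = %s\n",
              fmt("group_h2"), fmt("group_c2"), fmt("group_e2")))
  invisible(x)
}
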