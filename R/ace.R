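# Sufficient statistics for the zero-mean, unit-variance bivariate-normal
# pair likelihood: per relatedness group the log-likelihood depends on the
# data only through n and the sums of squares / cross-products.
pair_suffstats <- function(pairs, include_sib = FALSE) {
  keep <- pairs$relationship %in% c("MZ", "DZ", if (include_sib) "SIB")
  pairs <- pairs[keep, ]
  grp <- ifelse(pairs$relationship == "MZ", "MZ", "DZ05")
  lapply(split(pairs, grp), function(d) {
    list(n = nrow(d),
         s11 = sum(d$score_1^2), s22 = sum(d$score_2^2),
         s12 = sum(d$score_1 * d$score_2))
  })
}

group_loglik <- function(r, s) {
  r <- min(max(r, -1 + 1e-12), 1 - 1e-12)
  q <- 1 - r^2
  -s$n * log(2 * pi) - s$n / 2 * log(q) -
    (s$s11 + s$s22 - 2 * r * s$s12) / (2 * q)
}

ace_loglik_continuous <- function(a2, c2, ss) {
  ll <- 0
  if (!is.null(ss$MZ)) ll <- ll + group_loglik(a2 + c2, ss$MZ)
  if (!is.null(ss$DZ05)) ll <- ll + group_loglik(0.5 * a2 + c2, ss$DZ05)
  ll
}

# maximize over the free components of a given submodel; returns par + loglik
maximize_ace <- function(ll_fun, model) {
  switch(model,
    ACE = {
      nll <- function(p) {
        if (any(p < 0) || sum(p) > 1) return(1e10)
        -ll_fun(p[1], p[2])
      }
      o <- stats::optim(c(0.4, 0.2), nll, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
      list(a2 = o$par[1], c2 = o$par[2], loglik = -o$value)
    },
    AE = {
      o <- stats::optimize(function(a2) -ll_fun(a2, 0), c(0, 1), tol = 1e-10)
      list(a2 = o$minimum, c2 = 0, loglik = -o$objective)
    },
    CE = {
      o <- stats::optimize(function(c2) -ll_fun(0, c2), c(0, 1), tol = 1e-10)
      list(a2 = 0, c2 = o$minimum, loglik = -o$objective)
    },
    E = list(a2 = 0, c2 = 0, loglik = ll_fun(0, 0))
  )
}

# maximize f over [lo, hi], tolerating degenerate (zero-width) intervals
profile_max <- function(f, lo, hi, tol = 1e-10) {
  if (hi - lo < 1e-8) return(f(lo))
  -stats::optimize(function(x) -f(x), c(lo, hi), tol = tol)$objective
}

# Profile-likelihood 95% CI for one component: the endpoints are where the
# profiled log-likelihood drops 1.9207 (= qchisq(.95, 1) / 2) below the
# maximum; endpoints trapped at 0 or 1 are returned as the boundary.
profile_ci <- function(profile_ll, est, ll_max, lower = 0, upper = 1,
                       drop = stats::qchisq(0.95, 1) / 2) {
  target <- function(x) profile_ll(x) - (ll_max - drop)
  lo <- if (est <= lower + 1e-10 || target(lower) >= 0) lower else
    stats::uniroot(target, c(lower, est), tol = 1e-9)$root
  hi <- if (est >= upper - 1e-10 || target(upper) >= 0) upper else
    stats::uniroot(target, c(est, upper), tol = 1e-9)$root
  c(lo, hi)
}

new_ace_fit <- function(a2, c2, loglik, model, variant, ci = NULL,
                        threshold = NULL, n = NA_integer_) {
  structure(
    list(a2 = a2, c2 = c2, e2 = 1 - a2 - c2,
         ci_a2 = ci$a2, ci_c2 = ci$c2, ci_e2 = ci$e2,
         loglik = loglik, model = model, variant = variant,
         implied_r_mz = a2 + c2, implied_r_dz = 0.5 * a2 + c2,
         threshold = threshold, n = n),
    class = "ace_fit"
  )
}

#' @export
print.ace_fit <- function(x, ...) {
  fmt <- function(v, ci) {
    if (is.null(ci) || anyNA(ci)) sprintf("%.2f", v)
    else sprintf("%.2f (%.2f-%.2f)", v, ci[1], ci[2])
  }
  cat(sprintf("%s %s model (n = %s pairs)\n", x$variant, x$model, x$n))
  cat(sprintf("  A = %s  C = %s  E = %s\n",
              fmt(x$a2, x$ci_a2), fmt(x$c2, x$ci_c2), fmt(x$e2, x$ci_e2)))
  cat(sprintf("  implied r_MZ = %.2f, r_DZ = %.2f, loglik = %.2f\n",
              x$implied_r_mz, x$implied_r_dz, x$loglik))
  invisible(x)
}

#' ACE variance decomposition for continuous paired scores
#'
#' Maximizes the bivariate-normal pair likelihood with zero mean, unit
#' variance (the scores are standardized upstream) and pair correlation
#' \eqn{a^2 + c^2} for MZ pairs and \eqn{a^2/2 + c^2} for DZ (and,
#' optionally, non-twin sibling) pairs. 95% CIs are profile-likelihood
#' intervals (log-likelihood drop 1.92).
#'
#' @param pairs A standardized pair table (see [adjust_and_standardize()]).
#' @param model `"ACE"` (full) or the nested `"AE"`, `"CE"`, `"E"`.
#' @param include_sib Include SIB pairs (relatedness 0.5, pooled with DZ)?
#'   Off by default: the classical twin fit uses twins only.
#' @param ci Compute profile-likelihood CIs for A, C, E?
#' @return An `ace_fit` object.
#' @export
fit_ace_continuous <- function(pairs, model = c("ACE", "AE", "CE", "E"),
                               include_sib = FALSE, ci = TRUE) {
  model <- match.arg(model)
  ss <- pair_suffstats(pairs, include_sib)
  if (length(ss) < 2L) {
    stop("need both MZ and relatedness-0.5 pairs: model unidentified", call. = FALSE)
  }
  ll_fun <- function(a2, c2) ace_loglik_continuous(a2, c2, ss)
  fit <- maximize_ace(ll_fun, model)
  cis <- NULL
  if (ci && model == "ACE") {
    prof_a2 <- function(a2) profile_max(function(c2) ll_fun(a2, c2), 0, 1 - a2)
    prof_c2 <- function(c2) profile_max(function(a2) ll_fun(a2, c2), 0, 1 - c2)
    prof_e2 <- function(e2) profile_max(function(a2) ll_fun(a2, 1 - e2 - a2),
                                        0, 1 - e2)
    cis <- list(
      a2 = profile_ci(prof_a2, fit$a2, fit$loglik),
      c2 = profile_ci(prof_c2, fit$c2, fit$loglik),
      e2 = profile_ci(prof_e2, 1 - fit$a2 - fit$c2, fit$loglik)
    )
  }
  n <- sum(vapply(ss, `[[`, 0, "n"))
  new_ace_fit(fit$a2, fit$c2, fit$loglik, model, "continuous", cis, n = n)
}

#' Liability-threshold ACE decomposition from MZ and DZ pair tables
#'
#' Jointly fits both symmetric 2x2 tables by multinomial maximum likelihood:
#' latent liability correlations are \eqn{a^2 + c^2} (MZ) and
#' \eqn{a^2/2 + c^2} (DZ), cell probabilities come from
#' [cell_probabilities()], and the liability threshold is equated across
#' zygosity groups by default (a single population base rate). The
#' heritability estimated is that of the latent liability, not of the
#' observed score. 95% CIs are profile-likelihood intervals.
#'
#' @param mz,dz [contingency2x2()] tables for MZ and DZ pairs.
#' @param model `"ACE"`, `"AE"`, `"CE"` or `"E"`.
#' @param equate_threshold Single threshold for both groups (default), or
#'   one threshold per zygosity.
#' @param ci Compute profile-likelihood CIs?
#' @return An `ace_fit` object (variant `"liability"`, with `threshold`).
#' @export
#' @examples
#' fit_ace_liability(contingency2x2(54, 131, 2854, "MZ"),
#'                   contingency2x2(28, 168, 3000, "DZ"), ci = FALSE)
fit_ace_liability <- function(mz, dz, model = c("ACE", "AE", "CE", "E"),
                              equate_threshold = TRUE, ci = TRUE) {
  model <- match.arg(model)
  cmz <- tetra_counts(mz); cdz <- tetra_counts(dz)
  if (sum(cmz) == 0 || sum(cdz) == 0) stop("empty table", call. = FALSE)
  n_thr <- if (equate_threshold) 1L else 2L

  ll_cells <- function(a2, c2, thr) {
    r_mz <- min(a2 + c2, 1)
    r_dz <- 0.5 * a2 + c2
    t_mz <- thr[1]; t_dz <- thr[n_thr]
    table_loglik(cmz, cell_probabilities(r_mz, t_mz)) +
      table_loglik(cdz, cell_probabilities(r_dz, t_dz))
  }
  # concentrate the threshold(s) out to reuse the generic simplex maximizer
  t_start <- stats::qnorm(1 - (2 * (cmz[1] + cdz[1]) + cmz[2] + cdz[2]) /
                            (2 * (sum(cmz) + sum(cdz))))
  ll_fun <- function(a2, c2) {
    o <- stats::optim(rep(t_start, n_thr), function(thr) -ll_cells(a2, c2, thr),
                      method = "BFGS", control = list(reltol = 1e-12))
    -o$value
  }
  fit <- maximize_ace(ll_fun, model)
  thr_fit <- stats::optim(rep(t_start, n_thr),
                          function(thr) -ll_cells(fit$a2, fit$c2, thr),
                          method = "BFGS", control = list(reltol = 1e-12))$par
  cis <- NULL
  if (ci && model == "ACE") {
    prof_a2 <- function(a2) profile_max(function(c2) ll_fun(a2, c2), 0, 1 - a2, 1e-9)
    prof_c2 <- function(c2) profile_max(function(a2) ll_fun(a2, c2), 0, 1 - c2, 1e-9)
    prof_e2 <- function(e2) profile_max(function(a2) ll_fun(a2, 1 - e2 - a2),
                                        0, 1 - e2, 1e-9)
    cis <- list(
      a2 = profile_ci(prof_a2, fit$a2, fit$loglik),
      c2 = profile_ci(prof_c2, fit$c2, fit$loglik),
      e2 = profile_ci(prof_e2, 1 - fit$a2 - fit$c2, fit$loglik)
    )
  }
  out <- new_ace_fit(fit$a2, fit$c2, fit$loglik, model, "liability", cis,
                     threshold = thr_fit, n = sum(cmz) + sum(cdz))
  out$boundary <- any(c(cmz, cdz) == 0)
  out
}

#' Likelihood-ratio comparison of the full ACE model with its submodels
#'
#' Refits the nested AE, CE and E models and tests each drop in fit.
#' Because the dropped variance components sit on the boundary of the
#' parameter space, p-values use the 50:50 \eqn{\chi^2_0:\chi^2_1} mixture
#' for single-component drops, and the 1:2:1 \eqn{\chi^2_0:\chi^2_1:\chi^2_2}
#' mixture for the E model (two boundary constraints).
#'
#' @param data Either a standardized pair table (continuous variant) or a
#'   list `list(mz = , dz = )` of [contingency2x2()] tables (liability).
#' @param ... Passed on to the underlying fit function.
#' @return A `model_comparison`: the full fit, the submodel fits, and a
#'   data frame of LRT statistics, df and p-values.
#' @export
compare_submodels <- function(data, ...) {
  fit1 <- if (is.data.frame(data)) {
    function(model, ci) fit_ace_continuous(data, model = model, ci = ci, ...)
  } else {
    function(model, ci) fit_ace_liability(data$mz, data$dz, model = model, ci = ci, ...)
  }
  full <- fit1("ACE", ci = FALSE)
  subs <- lapply(c(AE = "AE", CE = "CE", E = "E"), fit1, ci = FALSE)
  stat <- vapply(subs, function(s) max(0, 2 * (full$loglik - s$loglik)), 0)
  df <- c(AE = 1L, CE = 1L, E = 2L)
  pval <- ifelse(df == 1L,
                 ifelse(stat == 0, 1, 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)),
                 ifelse(stat == 0, 1,
                        0.5 * stats::pchisq(stat, 1, lower.tail = FALSE) +
                          0.25 * stats::pchisq(stat, 2, lower.tail = FALSE)))
  structure(
    list(full = full, submodels = subs,
         lrt = data.frame(model = names(subs), lrt = stat, df = df, p = pval,
                          row.names = NULL)),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$full)
  cat("Submodel likelihood-ratio tests (boundary-mixture p-values):\n")
  print(x$lrt, digits = 4)
  invisible(x)
}
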