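# pair tables with exactly the requested sample correlations (via MASS)
exact_corr_pairs <- function(r_mz, r_dz, n = 20000, seed = 61) {
  skip_if_not_installed("MASS")
  set.seed(seed)
  draw <- function(r, rel) {
    x <- MASS::mvrnorm(n, c(0, 0), matrix(c(1, r, r, 1), 2), empirical = TRUE)
    data.frame(family_id = paste0(rel, seq_len(n)), relationship = rel,
               score_1 = x[, 1], score_2 = x[, 2],
               birth_year_1 = 1970L, birth_year_2 = 1970L,
               stringsAsFactors = FALSE)
  }
  rbind(draw(r_mz, "MZ"), draw(r_dz, "DZ"))
}

test_that("continuous ACE recovers the decomposition implied by twin correlations", {
  pairs <- exact_corr_pairs(0.80, 0.51)
  fit <- fit_ace_continuous(pairs)
  expect_equal(fit$a2, 0.58, tolerance = 0.01)
  expect_equal(fit$c2, 0.22, tolerance = 0.01)
  expect_equal(fit$e2, 0.20, tolerance = 0.01)
  # implied correlations reproduce the observed ones
  expect_equal(fit$implied_r_mz, 0.80, tolerance = 0.01)
  expect_equal(fit$implied_r_dz, 0.51, tolerance = 0.01)
  # model class is additive: implied r_MZ can never exceed 2 r_DZ
  expect_lte(fit$implied_r_mz, 2 * fit$implied_r_dz + 1e-9)
})

test_that("equal MZ and DZ correlations push heritability to zero", {
  fit <- fit_ace_continuous(exact_corr_pairs(0.5, 0.5, n = 5000), ci = FALSE)
  expect_lt(fit$a2, 0.01)
  expect_equal(fit$c2, 0.5, tolerance = 0.01)
})

test_that("profile CI endpoints sit exactly 1.92 log-likelihood units down", {
  pairs <- exact_corr_pairs(0.80, 0.51, n = 5000, seed = 62)
  fit <- fit_ace_continuous(pairs)
  ss <- twinextremes:::pair_suffstats(pairs)
  prof_a2 <- function(a2) {
    twinextremes:::profile_max(
      function(c2) twinextremes:::ace_loglik_continuous(a2, c2, ss), 0, 1 - a2)
  }
  for (endpt in fit$ci_a2) {
    expect_equal(prof_a2(endpt), fit$loglik - qchisq(0.95, 1) / 2,
                 tolerance = 1e-4)
  }
  expect_true(fit$ci_a2[1] < fit$a2 && fit$a2 < fit$ci_a2[2])
})

test_that("continuous fit requires two relatedness classes", {
  pairs <- exact_corr_pairs(0.8, 0.5, n = 200)
  expect_error(fit_ace_continuous(pairs[pairs$relationship == "MZ", ]),
               "unidentified")
})

test_that("liability ACE reproduces the published joint fit", {
  tabs <- paper_tables()
  fit <- fit_ace_liability(tabs$MZ, tabs$DZ)
  expect_equal(fit$a2, 0.42, tolerance = 0.03)
  expect_equal(fit$c2, 0.36, tolerance = 0.03)
  expect_equal(fit$e2, 0.22, tolerance = 0.03)
  # published CIs (0.17-0.68), (0.12-0.57), (0.16-0.30) as plausibility bands
  expect_equal(fit$ci_a2, c(0.17, 0.68), tolerance = 0.04)
  expect_equal(fit$ci_c2, c(0.12, 0.57), tolerance = 0.04)
  expect_equal(fit$ci_e2, c(0.16, 0.30), tolerance = 0.04)
  # threshold equated: close to the pooled marginal proband rate
  rate <- (2 * (54 + 28) + 131 + 168) / (2 * 6235)
  expect_equal(pnorm(-fit$threshold[1]), rate, tolerance = 0.01)
})

test_that("liability ACE is self-consistent on exactly model-generated tables", {
  a2 <- 0.6; c2 <- 0.2; thr <- qnorm(0.95); n <- 1e6
  tab <- function(r) {
    p <- cell_probabilities(r, thr)
    contingency2x2(p[1] * n, p[2] * n, p[3] * n)
  }
  fit <- fit_ace_liability(tab(a2 + c2), tab(a2 / 2 + c2), ci = FALSE)
  expect_equal(fit$a2, a2, tolerance = 1e-3)
  expect_equal(fit$c2, c2, tolerance = 1e-3)
  expect_equal(fit$threshold[1], thr, tolerance = 1e-3)
})

test_that("identical MZ and DZ tables give zero liability heritability", {
  t <- contingency2x2(54, 131, 2854)
  fit <- fit_ace_liability(t, t, ci = FALSE)
  expect_lt(fit$a2, 0.01)
  # the shared-environment correlation collapses onto the single-table
  # tetrachoric estimate
  expect_equal(fit$c2, fit_tetrachoric(t)$r, tolerance = 0.01)
})

test_that("submodel comparison rejects the wrong reductions", {
  # truth has no shared environment: AE retained, CE and E rejected
  n_rej_ce <- 0; n_rej_e <- 0; n_keep_ae <- 0
  reps <- 30
  for (i in seq_len(reps)) {
    std <- small_cohort(n = 5000, a2 = 0.6, c2 = 0, seed = 700 + i,
                        score = "latent", rule = list(quantile = 0.05))
    cmp <- compare_submodels(std)
    expect_lte(max(vapply(cmp$submodels, `[[`, 0, "loglik")),
               cmp$full$loglik + 1e-6)
    p <- setNames(cmp$lrt$p, cmp$lrt$model)
    n_rej_ce <- n_rej_ce + (p["CE"] < 0.05)
    n_rej_e <- n_rej_e + (p["E"] < 0.05)
    n_keep_ae <- n_keep_ae + (p["AE"] >= 0.05)
  }
  expect_gte(n_rej_ce / reps, 0.9)
  expect_gte(n_rej_e / reps, 0.9)
  expect_gte(n_keep_ae / reps, 0.75)   # nominal 5% false-rejection rate
})

test_that("an exactly-AE-structured sample yields a zero LRT for AE", {
  pairs <- exact_corr_pairs(0.6, 0.3, n = 4000, seed = 63)  # r_mz = 2 r_dz
  cmp <- compare_submodels(pairs)
  expect_lt(cmp$lrt$lrt[cmp$lrt$model == "AE"], 0.01)
  expect_gte(cmp$lrt$p[cmp$lrt$model == "AE"], 0.45)
})

test_that("the full model is preferred on the published tables", {
  tabs <- paper_tables()
  cmp <- compare_submodels(list(mz = tabs$MZ, dz = tabs$DZ))
  expect_true(all(cmp$lrt$p < 0.05))
  expect_equal(cmp$full$a2, 0.42, tolerance = 0.03)
})
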