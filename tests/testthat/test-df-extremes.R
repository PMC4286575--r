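test_that("group correlation is the ratio of mean deviations", {
  expect_equal(round(group_correlation(1.98, 1.39), 2), 0.70)
  expect_equal(round(group_correlation(1.98, 0.95), 2), 0.48)
  expect_equal(round(group_correlation(1.98, 0.81), 2), 0.41)
  expect_equal(group_correlation(2, 0), 0)   # complete regression to the mean
  expect_error(group_correlation(0, 0.5), "undefined")
})

test_that("doubling the group-correlation gap gives a closed group-ACE triple", {
  g <- group_h2_doubling(0.70, 0.48)
  expect_equal(unname(g["group_h2"]), 0.44)
  expect_equal(sum(g), 1)
  expect_equal(unname(group_h2_doubling(0.6, 0.6)["group_h2"]), 0)
  expect_equal(unname(group_h2_doubling(1.0, 0.5)), c(1, 0, 0))
})

# proband scores spread around proband_dev with exact mean; co-twin scores
# spread around g * proband_dev with exact mean, so the transformed class
# means (1 and g) are exact while the design matrix keeps full rank
df_fixture <- function(proband_dev = 1.98, g_mz = 0.70, g_dz = 0.48,
                       n = 400, spread = 0, noise = 0, seed = 71) {
  set.seed(seed)
  centred <- function() { e <- rnorm(n); e - mean(e) }
  build <- function(rel, g) {
    structure(data.frame(
      family_id = paste0(rel, seq_len(n)), relationship = rel,
      score_1 = proband_dev + spread * centred(),
      score_2 = g * proband_dev + noise * centred(),
      birth_year_1 = 1970L, birth_year_2 = 1970L,
      proband_1 = TRUE, proband_2 = FALSE, stringsAsFactors = FALSE),
      class = c("std_pair_table", "pair_table", "data.frame"))
  }
  rbind(build("MZ", g_mz), build("DZ", g_dz))
}

test_that("the DF transform self-normalizes probands and double-enters", {
  rows <- df_transform(df_fixture(spread = 0.2))
  expect_equal(mean(rows$proband[rows$R == 1]), 1, tolerance = 1e-12)
  expect_equal(mean(rows$proband[rows$R == 0.5]), 1, tolerance = 1e-12)
  expect_equal(mean(rows$cotwin[rows$R == 1]), 0.70, tolerance = 1e-12)
  expect_equal(mean(rows$cotwin[rows$R == 0.5]), 0.48, tolerance = 1e-12)

  # concordant pairs contribute both orientations
  p <- df_fixture(n = 1)
  p$proband_2 <- TRUE
  rows2 <- df_transform(p)
  expect_equal(sum(rows2$relationship == "MZ"), 2)
  mzrows <- rows2[rows2$relationship == "MZ", ]
  expect_equal(sort(mzrows$proband), sort(mzrows$cotwin))
  expect_error(df_transform(df_fixture()[, 1:6]), "flags missing")
})

test_that("DF regression recovers group heritability from exact group correlations", {
  rows <- df_transform(df_fixture(spread = 0.2, noise = 0.3))
  fit <- fit_df(rows, n_boot = 200, seed = 5)
  e <- fit$estimates
  expect_equal(e[["group_h2"]], 0.44, tolerance = 1e-6)
  expect_equal(e[["group_r_mz"]], 0.70, tolerance = 1e-6)
  expect_equal(e[["group_r_dz"]], 0.48, tolerance = 1e-6)
  expect_equal(sum(e[c("group_h2", "group_c2", "group_e2")]), 1, tolerance = 1e-6)
  expect_true(fit$ci["2.5%", "group_h2"] <= 0.44 &&
              0.44 <= fit$ci["97.5%", "group_h2"])
})

test_that("a co-twin identical to the proband gives b1 = 1, b2 = 0", {
  p <- df_fixture(spread = 0.2, seed = 72)
  p$score_2 <- p$score_1
  fit <- fit_df(df_transform(p, pooled_divisor = TRUE), n_boot = 0)
  expect_equal(fit$estimates[["beta1"]], 1, tolerance = 1e-8)
  expect_equal(fit$estimates[["beta2"]], 0, tolerance = 1e-8)
})

test_that("DF OLS equals the direct normal-equations solve", {
  rows <- df_transform(df_fixture(spread = 0.3, noise = 0.5, seed = 73))
  fit <- fit_df(rows, n_boot = 0)
  X <- cbind(1, rows$proband, rows$R)
  beta <- solve(t(X) %*% X, t(X) %*% rows$cotwin)
  expect_equal(fit$estimates[["intercept"]], beta[1], tolerance = 1e-10)
  expect_equal(fit$estimates[["beta1"]], beta[2], tolerance = 1e-10)
  expect_equal(fit$estimates[["beta2"]], beta[3], tolerance = 1e-10)
})

test_that("with equal proband means, b2 is twice the co-twin mean difference", {
  # closed-form OLS identity for a binary-coded relatedness regressor
  rows <- df_transform(df_fixture(spread = 0.25, noise = 0.4, seed = 74))
  fit <- fit_df(rows, n_boot = 0)
  d <- mean(rows$cotwin[rows$R == 1]) - mean(rows$cotwin[rows$R == 0.5])
  expect_equal(fit$estimates[["beta2"]], 2 * d, tolerance = 1e-10)
})

test_that("a single relatedness level is rejected as unidentified", {
  rows <- df_transform(df_fixture())
  expect_error(fit_df(rows[rows$R == 1, ]), "unidentified")
})

test_that("regression and doubling estimators agree on simulated cohorts", {
  std <- small_cohort(n = 2e4, a2 = 0.58, c2 = 0.22, seed = 75,
                      score = "latent", rule = list(quantile = 0.05))
  fit <- fit_df(df_transform(std), n_boot = 200, seed = 6)
  g <- group_h2_doubling(fit$estimates[["group_r_mz"]],
                         fit$estimates[["group_r_dz"]])
  expect_equal(fit$estimates[["group_h2"]], unname(g["group_h2"]),
               tolerance = 0.03)
  # sibling pairs can stand in for DZ pairs without changing expectations
  std_sib <- small_cohort(n = 2e4, a2 = 0.58, c2 = 0.22, seed = 76,
                          score = "latent", rule = list(quantile = 0.05),
                          n_sib = 2e4)
  rows_sib <- df_transform(std_sib[std_sib$relationship != "DZ", ])
  fit_sib <- fit_df(rows_sib, n_boot = 0)
  expect_equal(fit_sib$estimates[["group_h2"]], fit$estimates[["group_h2"]],
               tolerance = 0.1)
})
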