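test_that("sim_config validates the ACE simplex and structural fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(a2 = 0.6, c2 = 0.5, e2 = 0.2), "equal 1")
  expect_error(sim_config(a2 = -0.1, c2 = 0.9, e2 = 0.2), ">= 0")
  expect_error(sim_config(stanine_cutpoints = rep(0, 8)), "ascending")
  expect_error(sim_config(birth_year_range = c(1990, 1950)), "ascending")
  expect_error(sim_config(proband_rule = list(quantile = 1.2)), "0 < q < 1")
  expect_error(simulate_pairs(sim_config(n_mz = 0, n_dz = 0, n_sib = 0)),
               "nothing to simulate")
})

test_that("stanine transform places z-scores in half-open bins", {
  expect_identical(stanine_transform(0), 5L)
  expect_identical(stanine_transform(2.5), 9L)
  # right-closed: the boundary value belongs to the lower category
  expect_identical(stanine_transform(c(0.25, 0.25 + 1e-9)), c(5L, 6L))
  expect_identical(stanine_transform(-10), 1L)
  expect_error(stanine_transform(0, cutpoints = c(1, 1, 2, 3, 4, 5, 6, 7)),
               "ascending")
})

test_that("stanine scale matches its closed-form moments on normal input", {
  cp <- stanine_cutpoints("classical")
  # closed-form cell probabilities are the oracle for the scale's moments
  p <- diff(c(0, pnorm(cp), 1))
  mu <- sum(1:9 * p)
  sdev <- sqrt(sum((1:9 - mu)^2 * p))
  expect_equal(mu, 5)               # symmetric cutpoints
  expect_equal(sdev, 1.944, tolerance = 1e-3)  # nominal "SD 2" scale
  expect_equal(pnorm(-1.75), p[9], tolerance = 1e-12)

  set.seed(401)
  s <- stanine_transform(rnorm(1e6), cp)
  expect_lt(abs(mean(s == 9) - pnorm(-1.75)), 0.002)
  expect_lt(abs(mean(s) - 5), 0.01)
  expect_lt(abs(sd(s) - sdev), 0.01)
  # the top-5% dialect widens the top category to 5%
  s5 <- stanine_transform(rnorm(1e5), stanine_cutpoints("top5"))
  expect_lt(abs(mean(s5 == 9) - 0.05), 0.005)
})

test_that("simulated pair correlations match the configured ACE structure", {
  n <- 1e5
  cfg <- sim_config(a2 = 0.58, c2 = 0.22, n_mz = n, n_dz = n, n_sib = 0,
                    drift_per_year = 0, seed = 301)
  p <- simulate_pairs(cfg)
  r <- function(rel) with(p[p$relationship == rel, ], cor(score_1, score_2))
  expect_equal(r("MZ"), 0.80, tolerance = 0.01)
  expect_equal(r("DZ"), 0.51, tolerance = 0.01)
  x <- c(p$score_1, p$score_2)
  expect_lt(abs(mean(x)), 3 / sqrt(length(x)))
  expect_lt(abs(var(x) - 1), 3 / sqrt(length(x)))
})

test_that("degenerate ACE configurations behave as expected", {
  # identical genomes, no E: MZ members are exact copies
  p1 <- simulate_pairs(sim_config(a2 = 1, c2 = 0, e2 = 0, n_mz = 500, n_dz = 0,
                                  n_sib = 0, drift_per_year = 0, seed = 3))
  expect_equal(p1$score_1, p1$score_2, tolerance = 1e-12)
  # full independence
  p0 <- simulate_pairs(sim_config(a2 = 0, c2 = 0, e2 = 1, n_mz = 2e4, n_dz = 2e4,
                                  n_sib = 2e4, drift_per_year = 0, seed = 4))
  for (rel in c("MZ", "DZ", "SIB")) {
    rr <- with(p0[p0$relationship == rel, ], cor(score_1, score_2))
    expect_lt(abs(rr), 3 / sqrt(2e4))
  }
})

test_that("DZ and SIB pairs are exchangeable in distribution without drift", {
  n <- 5e4
  p <- simulate_pairs(sim_config(n_mz = 0, n_dz = n, n_sib = n,
                                 drift_per_year = 0, seed = 77))
  dz <- p[p$relationship == "DZ", ]; sib <- p[p$relationship == "SIB", ]
  expect_lt(abs(cor(dz$score_1, dz$score_2) - cor(sib$score_1, sib$score_2)),
            3 * sqrt(2 / n))
  expect_lt(abs(mean(dz$score_1) - mean(sib$score_1)), 3 * sqrt(2 / n))
  expect_lt(abs(sd(dz$score_1) - sd(sib$score_1)), 3 * sqrt(2 / n))
})

test_that("birth-year drift shifts means and twins share a birth year", {
  p <- simulate_pairs(sim_config(n_mz = 2e4, n_dz = 2e4, n_sib = 2e4,
                                 drift_per_year = 0.02, seed = 9))
  tw <- p$relationship != "SIB"
  expect_true(all(p$birth_year_1[tw] == p$birth_year_2[tw]))
  expect_true(all(p$birth_year_2[!tw] >= p$birth_year_1[!tw]))
  expect_gt(cor(p$score_1, p$birth_year_1), 0.1)
  expect_true(all(p$stanine_1 %in% 1:9 & p$stanine_2 %in% 1:9))
})

test_that("study-pair selection follows the one-pair-per-family rule", {
  # twins beat siblings
  r1 <- family_roster("f", c("s1", "s2", "t1", "t2"), c(1985, 1988, 1990, 1990),
                      c(NA, NA, "tw", "tw"))
  expect_setequal(select_study_pair(r1), c("t1", "t2"))
  # youngest twin pair when several
  r2 <- family_roster("f", c("a1", "a2", "b1", "b2"), c(1980, 1980, 1990, 1990),
                      c("A", "A", "B", "B"))
  expect_setequal(select_study_pair(r2), c("b1", "b2"))
  # unique minimal age gap
  r3 <- family_roster("f", c("x", "y", "z"), c(1984, 1986, 1991))
  expect_identical(select_study_pair(r3), c("x", "y"))
  # equal gaps: youngest pair wins
  r4 <- family_roster("f", c("a", "b", "c", "d"), c(1980, 1982, 1990, 1992))
  expect_identical(select_study_pair(r4), c("c", "d"))
  expect_error(select_study_pair(family_roster("f", "solo", 1980)), "fewer than two")
  expect_error(family_roster("f", c("a", "b", "c"), c(1980, 1980, 1980),
                             c("T", "T", "T")), "exactly two")
})

test_that("pair tables survive a TSV round trip", {
  p <- simulate_pairs(sim_config(n_mz = 50, n_dz = 50, n_sib = 50, seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_table(p, path)
  q <- read_pair_table(path)
  expect_equal(as.data.frame(q), as.data.frame(p), tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\n1\t2", bad)
  expect_error(read_pair_table(bad), "missing columns")
})
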