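# strip classes/attributes so jsonlite serialises fits as plain lists
as_plain <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), as_plain))
  attributes(x) <- attributes(x)["names"]
  x
}

#' Run the full extreme-group analysis pipeline
#'
#' Orchestrates simulate (or load) -> standardize & flag -> concordances ->
#' tetrachoric correlations -> continuous ACE -> liability ACE -> DF
#' extremes, and returns one report object holding every stage's results
#' plus provenance. Deterministic given the seed.
#'
#' @param config A list (or path to a YAML file) with optional sections:
#'   `sim` (arguments to [sim_config()]), `input` (path to a pair-table TSV,
#'   used instead of simulating), `prep` (`score`, `rule`), `df` (`n_boot`),
#'   `seed` (overrides the simulation seed and seeds the bootstrap).
#' @param out_json Optional path; when given the report is written there as
#'   JSON (full precision; stable key order).
#' @return An `analysis_report` list with sections `provenance`,
#'   `descriptives`, `concordance`, `tetrachoric`, `ace_continuous`,
#'   `ace_liability`, `df_extremes`.
#' @export
run_pipeline <- function(config = list(), out_json = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L

  if (!is.null(config$input)) {
    pairs <- read_pair_table(config$input)
  } else {
    sim_args <- config$sim %||% list()
    sim_args$seed <- seed
    pairs <- simulate_pairs(do.call(sim_config, sim_args))
  }

  prep <- config$prep %||% list()
  score <- prep$score %||% if ("stanine_1" %in% names(pairs)) "stanine" else "latent"
  rule <- prep$rule %||% if (score == "stanine") "top-stanine" else list(quantile = 0.05)
  std <- flag_probands(adjust_and_standardize(pairs, score = score), rule = rule)

  rels <- intersect(c("MZ", "DZ", "SIB"), unique(std$relationship))
  tabs <- lapply(stats::setNames(rels, rels), function(r) to_contingency(std, r))
  groups <- lapply(stats::setNames(rels, rels),
                   function(r) summarize_extreme_group(std, r))

  raw <- if (score == "stanine") c(pairs$stanine_1, pairs$stanine_2)
         else c(pairs$score_1, pairs$score_2)
  descriptives <- list(
    n_pairs = as.list(table(std$relationship)[rels]),
    raw_score_mean = mean(raw), raw_score_sd = stats::sd(raw),
    proband_fraction = mean(c(std$proband_1, std$proband_2)),
    proband_mean_deviation = mean(vapply(groups, `[[`, 0, "proband_mean")),
    group_means = lapply(groups, as_plain)
  )

  conc <- concordance_table(tabs)
  conc_h2 <- if (all(c("MZ", "DZ") %in% rels)) {
    as.numeric(concordance_h2(conc$probandwise[conc$relationship == "MZ"],
                              conc$probandwise[conc$relationship == "DZ"]))
  }

  tet <- ace_c <- ace_l <- NULL
  if (all(c("MZ", "DZ") %in% rels)) {
    tet_mz <- fit_tetrachoric(tabs$MZ)
    tet_dz <- fit_tetrachoric(tabs$DZ)
    tet <- list(MZ = as_plain(tet_mz), DZ = as_plain(tet_dz),
                falconer = as.list(falconer_ace(tet_mz$r, tet_dz$r)))
    ace_c <- compare_submodels(std[std$relationship != "SIB", ])
    ace_l <- compare_submodels(list(mz = tabs$MZ, dz = tabs$DZ))
  }

  dfres <- NULL
  if ("MZ" %in% rels && any(c("DZ", "SIB") %in% rels)) {
    rows <- df_transform(std[std$relationship != "SIB", ])
    dfres <- fit_df(rows, n_boot = (config$df %||% list())$n_boot %||% 2000,
                    seed = seed)
  }

  report <- list(
    provenance = list(package = "twinextremes",
                      version = as.character(utils::packageVersion("twinextremes")),
                      r_version = paste(R.version$major, R.version$minor, sep = "."),
                      seed = seed, config = config),
    descriptives = descriptives,
    concordance = list(table = conc, doubling_h2 = conc_h2),
    tetrachoric = tet,
    ace_continuous = if (!is.null(ace_c)) list(full = as_plain(ace_c$full),
                                               lrt = ace_c$lrt),
    ace_liability = if (!is.null(ace_l)) list(full = as_plain(ace_l$full),
                                              lrt = ace_l$lrt),
    df_extremes = if (!is.null(dfres)) as_plain(dfres)
  )
  class(report) <- "analysis_report"
  if (!is.null(out_json)) {
    jsonlite::write_json(unclass(report), out_json, auto_unbox = TRUE,
                         digits = NA, null = "null", dataframe = "rows")
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic fixture cohorts with known expected statistics
#'
#' Each registered fixture returns the data needed by a test plus the
#' statistics it is analytically expected to reproduce:
#' \describe{
#'   \item{`paper_tables`}{No simulation: the published pair tables
#'     (54/131/2854 MZ, 28/168/3000 DZ, 3302/25037 proband-containing
#'     sibling pairs) and group means (proband 1.98; co-twin/sibling means
#'     1.39, 0.95, 0.81), with the worked-example statistics they imply.}
#'   \item{`continuity`}{A cohort simulated under one ACE model
#'     (a2 = 0.58, c2 = 0.22) across the whole range; group heritability
#'     from the extremes is expected to equal a2.}
#'   \item{`null`}{a2 = c2 = 0: concordances are expected to equal the
#'     proband base rate.}
#'   \item{`perfect_h2`}{a2 = 1: the MZ group correlation is expected to
#'     be 1.}
#' }
#'
#' @param name Fixture name.
#' @param n_pairs Pairs per twin group for the simulated fixtures.
#' @param seed Simulation seed.
#' @param dir Optional directory; when given, the pair table (TSV) and
#'   expected values (JSON) are written there.
#' @return List with `pairs` (or `tables`/`means` for `paper_tables`) and
#'   `expected`.
#' @export
make_fixture <- function(name = c("paper_tables", "continuity", "null", "perfect_h2"),
                         n_pairs = 20000, seed = 1L, dir = NULL) {
  name <- match.arg(name)
  fx <- switch(name,
    paper_tables = list(
      tables = list(MZ = contingency2x2(54, 131, 2854, "MZ"),
                    DZ = contingency2x2(28, 168, 3000, "DZ"),
                    SIB = contingency2x2(3302, 25037, 326551, "SIB")),
      means = list(proband = 1.98, cotwin_mz = 1.39, cotwin_dz = 0.95,
                   sibling = 0.81, population = 0),
      expected = list(
        pairwise = c(MZ = 0.29, DZ = 0.14, SIB = 0.12),
        probandwise = c(MZ = 0.45, DZ = 0.25, SIB = 0.21),
        concordance_h2 = 0.40,
        tetrachoric = c(MZ = 0.78, DZ = 0.56),
        falconer_liability_a2 = 0.44,
        group_correlations = c(MZ = 0.70, DZ = 0.48, SIB = 0.41),
        group_h2 = 0.44,
        liability_ace = c(a2 = 0.42, c2 = 0.36, e2 = 0.22)
      )
    ),
    continuity = list(
      config = sim_config(a2 = 0.58, c2 = 0.22, n_mz = n_pairs, n_dz = n_pairs,
                          n_sib = 0, drift_per_year = 0, seed = seed),
      expected = list(r_mz = 0.80, r_dz = 0.51, group_h2 = 0.58)
    ),
    null = list(
      config = sim_config(a2 = 0, c2 = 0, e2 = 1, n_mz = n_pairs, n_dz = n_pairs,
                          n_sib = 0, drift_per_year = 0, seed = seed),
      expected = list(r_mz = 0, r_dz = 0,
                      probandwise = "proband base rate in every class")
    ),
    perfect_h2 = list(
      config = sim_config(a2 = 1, c2 = 0, e2 = 0, n_mz = n_pairs, n_dz = n_pairs,
                          n_sib = 0, drift_per_year = 0, seed = seed),
      expected = list(r_mz = 1, group_r_mz = 1)
    )
  )
  if (!is.null(fx$config)) fx$pairs <- simulate_pairs(fx$config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    if (!is.null(fx$pairs)) {
      write_pair_table(fx$pairs, file.path(dir, paste0(name, "_pairs.tsv")))
    }
    jsonlite::write_json(as_plain(fx[setdiff(names(fx), c("pairs", "config"))]),
                         file.path(dir, paste0(name, "_expected.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  fx
}
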