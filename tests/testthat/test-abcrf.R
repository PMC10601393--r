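# the separable two-scenario toy (non-overlapping Ne priors) is shared
# across several blocks; built once at file load
sep_cfg <- separable_cfg()
sep_rt <- suppressWarnings(append_lda_axes(
  build_reference_table(sep_cfg, n_per_scenario = 250, seed = 21)
))

test_that("reference tables have the right shape, balance and determinism", {
  rt <- suppressWarnings(build_reference_table(sep_cfg, n_per_scenario = 20, seed = 5))
  expect_equal(nrow(rt), 40)
  expect_equal(as.integer(table(rt$scenario)), c(20L, 20L))
  expect_length(attr(rt, "stat_cols"), 16)   # 2 populations
  rt2 <- suppressWarnings(build_reference_table(sep_cfg, n_per_scenario = 20, seed = 5))
  expect_identical(as.data.frame(rt), as.data.frame(rt2))
  rt3 <- suppressWarnings(build_reference_table(sep_cfg, n_per_scenario = 20, seed = 6))
  expect_false(identical(as.data.frame(rt), as.data.frame(rt3)))
  expect_error(build_reference_table(sep_cfg, n_per_scenario = 0), "at least 1")
  # scenario parameters unused by a scenario stay NA
  expect_true(all(is.na(rt$NeBig[rt$scenario == "1"])))
  expect_true(all(!is.na(rt$NeBig[rt$scenario == "2"])))
})

test_that("LDA appends k-1 axes and projects training rows consistently", {
  expect_equal(attr(sep_rt, "lda_cols"), "LD1")   # 2 scenarios -> 1 axis
  obs_row <- sep_rt[3, attr(sep_rt, "stat_cols")]
  pr <- project_lda(sep_rt, obs_row)
  expect_equal(pr$LD1, sep_rt$LD1[3], tolerance = 1e-10)

  cfg <- scenarios_caucasus()
  rt8 <- suppressWarnings(
    build_reference_table(cfg, n_per_scenario = 12, seed = 31))
  rt8 <- suppressWarnings(append_lda_axes(rt8))
  expect_equal(attr(rt8, "lda_cols"), paste0("LD", 1:7))
})

test_that("separable scenarios are recovered nearly perfectly", {
  ch <- scenario_choice(sep_rt, observed = NULL, n_trees = 300, seed = 2,
                        compute_posterior = FALSE)
  expect_lt(ch$prior_error, 0.05)
  # held-out simulation votes overwhelmingly for its generating scenario
  set.seed(99)
  dr <- sample_draw(sep_cfg$priors, sep_cfg$scenarios[[2]], n_loci = 3)
  obs <- summarize_dataset(
    simulate_dataset(sep_cfg$scenarios[[2]], dr, default_loci(3), seed = 1234))
  ch2 <- scenario_choice(sep_rt, obs, n_trees = 300, seed = 2)
  expect_equal(ch2$selected, "2")
  expect_gt(ch2$votes$vote_share[ch2$votes$scenario == "2"], 0.9)
  expect_equal(sum(ch2$votes$votes), 300)
  expect_gt(ch2$posterior_prob, 0.5)
  expect_equal(ch2$local_error, 1 - ch2$posterior_prob)
  g <- glance(ch2)
  expect_equal(g$selected, "2")
})

test_that("label permutation drives the prior error to chance level", {
  rt <- sep_rt
  set.seed(4)
  rt$scenario <- sample(rt$scenario)
  ch <- scenario_choice(rt, observed = NULL, n_trees = 300, seed = 3,
                        compute_posterior = FALSE)
  expect_lt(abs(ch$prior_error - 0.5), 0.07)
})

test_that("forests are reproducible under a fixed seed", {
  set.seed(99)
  dr <- sample_draw(sep_cfg$priors, sep_cfg$scenarios[[1]], n_loci = 3)
  obs <- summarize_dataset(
    simulate_dataset(sep_cfg$scenarios[[1]], dr, default_loci(3), seed = 55))
  a <- scenario_choice(sep_rt, obs, n_trees = 100, seed = 7)
  b <- scenario_choice(sep_rt, obs, n_trees = 100, seed = 7)
  expect_identical(a$votes, b$votes)
  expect_identical(a$prior_error, b$prior_error)
  expect_identical(a$posterior_prob, b$posterior_prob)
})

test_that("replicate analyses on a separable table have low forest noise", {
  set.seed(99)
  dr <- sample_draw(sep_cfg$priors, sep_cfg$scenarios[[2]], n_loci = 3)
  obs <- summarize_dataset(
    simulate_dataset(sep_cfg$scenarios[[2]], dr, default_loci(3), seed = 56))
  rep5 <- replicate_analysis(sep_rt, obs, n_replicates = 5, n_trees = 200,
                             seed = 11, compute_posterior = FALSE)
  v2 <- dplyr::filter(rep5$votes, scenario == "2")
  expect_gt(v2$mean_votes, 180)
  expect_lt(v2$sd_votes, v2$mean_votes / 5)
  expect_equal(rep5$summary$selected_modal, "2")
})

test_that("quantile regression forests nail a perfectly informative feature", {
  set.seed(13)
  n <- 1500
  y <- runif(n, 100, 1000)
  stats <- tibble::tibble(
    S1 = y, S2 = rnorm(n), S3 = rnorm(n), S4 = rnorm(n), S5 = rnorm(n)
  )
  tb <- dplyr::bind_cols(tibble::tibble(scenario = factor(rep(1, n)), t1 = y),
                         stats)
  attr(tb, "stat_cols") <- paste0("S", 1:5)
  class(tb) <- c("msat_reftable", class(tb))
  obs <- stats[7, ]
  est <- estimate_parameters(tb, obs, parameters = "t1", n_trees = 300,
                             n_oob = 300, pls_axes = 2, seed = 3)
  expect_lt(est$nmae_global, 0.02)
  expect_gte(est$coverage_90, 0.9)
  expect_true(est$q05 <= est$median && est$median <= est$q95)
  expect_lt(abs(est$median - y[7]) / y[7], 0.05)
  expect_error(estimate_parameters(tb, obs, parameters = "nope"),
               "not in the reference table")
})

test_that("reference tables round-trip through the provenance text format", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reftable(sep_rt, path)
  back <- read_reftable(path)
  expect_equal(attr(back, "stat_cols"), attr(sep_rt, "stat_cols"))
  expect_equal(nrow(back), nrow(sep_rt))
  expect_equal(back$HET_A, sep_rt$HET_A, tolerance = 1e-12)
  expect_equal(as.character(back$scenario), as.character(sep_rt$scenario))
  first <- readLines(path, n = 1)
  expect_match(first, "^# msatabc reference table")
})
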