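test_that("scenario presets carry the published shock magnitudes", {
  cl <- build_scenario("climate")
  expect_equal(unname(cl$dimension_multipliers), c(0.8, 1, 1))
  expect_equal(cl$income_multiplier, 1)
  ec <- build_scenario("economic")
  expect_equal(unname(ec$dimension_multipliers), c(1, 1, 1))
  expect_equal(ec$income_multiplier, 0.5)
  co <- build_scenario("combined")
  expect_equal(unname(co$dimension_multipliers), c(0.8, 1, 1))
  expect_equal(co$income_multiplier, 0.5)
  bl <- build_scenario("baseline")
  expect_true(all(bl$dimension_multipliers == 1) &&
                bl$income_multiplier == 1 && bl$lambda_multiplier == 1)
  # adaptive-capacity transforms scale lambda by +/- 50%
  expect_equal(build_scenario("climate", "constrained")$lambda_multiplier,
               0.5)
  expect_equal(build_scenario("climate", "enabled")$lambda_multiplier, 1.5)
  expect_error(build_scenario("volcano"), "arg")
})

test_that("the identity scenario reproduces the plain simulation bitwise", {
  cfg <- generator_config(n_wards = 2, months = 12, seed = 51)
  gt <- generate_ground_truth(cfg)
  params <- gt$true_params
  tr <- run_counterfactuals(params, default_inputs(gt),
                            build_scenario("baseline"), replicates = 2,
                            seed = 9)
  set.seed(9)
  rep_seeds <- sample.int(2147483646L, 2)
  for (r in 1:2) {
    p <- params
    p$seed <- rep_seeds[r]
    plain <- simulate_run(gt$households, gt$stressors, p)
    got <- tr[tr$replicate == r, c("ward_id", "month", "prevalence_pct",
                                   "ipc_phase")]
    rownames(got) <- NULL
    expect_identical(got, plain)
  }
})

test_that("scenario runs are paired across specs and tidily summarised", {
  cfg <- generator_config(n_wards = 2, months = 12, seed = 53)
  gt <- generate_ground_truth(cfg)
  specs <- list(build_scenario("baseline"), build_scenario("combined"))
  tr <- run_counterfactuals(gt$true_params, default_inputs(gt), specs,
                            replicates = 3, seed = 4)
  expect_equal(sort(unique(tr$scenario)),
               c("baseline_baseline", "combined_baseline"))
  expect_equal(nrow(tr), 2L * 3L * 2L * 12L)  # specs x reps x wards x months
  sm <- summarize_counterfactuals(tr)
  expect_equal(nrow(sm), 2L * 2L * 12L)
  expect_true(all(sm$lo_pct <= sm$mean_pct & sm$mean_pct <= sm$hi_pct))
  expect_error(run_counterfactuals(gt$true_params, default_inputs(gt),
                                   list(build_scenario("climate"),
                                        build_scenario("climate")),
                                   replicates = 1, seed = 1),
               "unique")
})

test_that("shock scenarios depress outcomes relative to baseline in the window", {
  cfg <- generator_config(n_wards = 2, months = 12, seed = 57)
  gt <- generate_ground_truth(cfg)
  specs <- list(build_scenario("baseline"), build_scenario("combined"))
  tr <- run_counterfactuals(gt$true_params, default_inputs(gt), specs,
                            replicates = 8, seed = 6)
  months <- sort(unique(tr$month))
  window <- months[9:12]
  m <- tapply(tr$prevalence_pct[tr$month %in% window],
              tr$scenario[tr$month %in% window], mean)
  expect_gte(m[["combined_baseline"]], m[["baseline_baseline"]])
  # outside the window the trajectories are identical by pairing
  pre <- tr[tr$month < window[1], ]
  base <- pre[pre$scenario == "baseline_baseline",
              c("replicate", "ward_id", "month", "prevalence_pct")]
  comb <- pre[pre$scenario == "combined_baseline",
              c("replicate", "ward_id", "month", "prevalence_pct")]
  rownames(base) <- rownames(comb) <- NULL
  expect_identical(base, comb)
})

test_that("lambda transforms outside the calibration box are flagged", {
  cfg <- generator_config(n_wards = 2, months = 12, seed = 59)
  gt <- generate_ground_truth(cfg)
  p <- gt$true_params
  p$lambda <- 0.08   # x1.5 leaves the [0.01, 0.1] box
  expect_message(
    run_counterfactuals(p, default_inputs(gt),
                        build_scenario("climate", "enabled"),
                        replicates = 1, seed = 2),
    "outside the calibration box")
})
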