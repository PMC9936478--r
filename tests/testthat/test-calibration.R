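# small world keeps these fast: 2 wards x 60 households x 18 months
cal_world <- function(seed = 29, months = 18) {
  cfg <- generator_config(n_wards = 2, months = months, seed = seed)
  generate_ground_truth(cfg)
}

test_that("a single-cell grid is returned as-is and runs are reproducible", {
  gt <- cal_world()
  grid1 <- calibration_grid(lambda = 0.04, spawn = 0.06, replicates = 2)
  cal <- calibrate(gt$observed, default_inputs(gt), grid1, seed = 5,
                   base_params = sim_params(n_0 = 0.04))
  expect_equal(cal$best_params$lambda, 0.04)
  expect_equal(cal$best_params$spawn_rate, 0.06)
  expect_equal(nrow(cal$grid_table), 1L)

  grid2 <- calibration_grid(lambda = c(0.03, 0.08), replicates = 2)
  a <- calibrate(gt$observed, default_inputs(gt), grid2, seed = 5,
                 base_params = sim_params(n_0 = 0.04))
  b <- calibrate(gt$observed, default_inputs(gt), grid2, seed = 5,
                 base_params = sim_params(n_0 = 0.04))
  expect_identical(a$best_params, b$best_params)
  expect_identical(a$grid_table, b$grid_table)
  expect_error(calibrate(gt$observed, default_inputs(gt),
                         calibration_grid(lambda = 0.2)),
               "calibration box")
})

test_that("calibration never touches observations after the training span", {
  gt <- cal_world()
  grid <- calibration_grid(lambda = c(0.03, 0.08), replicates = 2)
  months <- sort(unique(gt$observed$month))
  split <- months[13]
  train <- gt$observed[gt$observed$month < split, ]

  run_split <- function(obs) {
    temporal_split_eval(obs, default_inputs(gt), split, grid, seed = 5,
                        base_params = sim_params(n_0 = 0.04))
  }
  clean <- run_split(gt$observed)
  # poison every test-span observation; the calibrated optimum must not move
  poisoned <- gt$observed
  poisoned$prevalence_pct[poisoned$month >= split] <- 99
  dirty <- run_split(poisoned)
  expect_identical(clean$calibration$best_params,
                   dirty$calibration$best_params)
  expect_identical(clean$calibration$grid_table,
                   dirty$calibration$grid_table)
  # and the train-side report is untouched by the poisoning
  expect_identical(clean$train_report, dirty$train_report)

  # calibrating on the training rows alone gives the same optimum
  direct <- calibrate(train, default_inputs(gt), grid, seed = 5,
                      base_params = sim_params(n_0 = 0.04))
  expect_identical(clean$calibration$best_params, direct$best_params)
})

test_that("a degenerate test span equal to the train span mirrors its report", {
  gt <- cal_world()
  grid <- calibration_grid(lambda = 0.05, replicates = 2)
  months <- sort(unique(gt$observed$month))
  split <- months[13]
  train_months <- months[months < split]
  sp <- temporal_split_eval(gt$observed, default_inputs(gt), split, grid,
                            seed = 5, base_params = sim_params(n_0 = 0.04),
                            test_months = train_months)
  # scored on the same ward-months with the same frozen parameters and
  # replicate seeds, train and test must agree except for burn-in trimming
  full_train <- temporal_split_eval(gt$observed, default_inputs(gt), split,
                                    grid, seed = 5,
                                    base_params = sim_params(n_0 = 0.04),
                                    test_months = sp$calibration$score_months)
  expect_equal(full_train$train_report$rmsd, full_train$test_report$rmsd)
  expect_equal(full_train$train_report$f1_macro,
               full_train$test_report$f1_macro)
  expect_s3_class(sp$test_report, "amews_report")
})

test_that("single-ward data still runs but warns", {
  cfg <- generator_config(n_wards = 1, months = 12, seed = 41)
  gt <- generate_ground_truth(cfg)
  grid <- calibration_grid(lambda = 0.05, replicates = 1)
  expect_warning(
    calibrate(gt$observed, default_inputs(gt), grid, seed = 2,
              base_params = sim_params(n_0 = 0.04)),
    "single ward")
})

test_that("leading-edge windows tile the test span without overlap", {
  gt <- cal_world(seed = 37, months = 24)
  grid <- calibration_grid(lambda = 0.05, replicates = 1)
  le <- leading_edge(gt$observed, default_inputs(gt), horizon = 4, seed = 3,
                     grid = grid, base_params = sim_params(n_0 = 0.04),
                     train_min = 12)
  expect_equal(nrow(le$windows), 3L)
  months <- sort(unique(gt$observed$month))
  expect_equal(le$windows$start, months[c(13, 17, 21)])
  expect_equal(le$windows$end, months[c(16, 20, 24)])
  # bookkeeping: one recorded error per window x ward x month-in-window
  expect_equal(nrow(le$errors), 3L * 2L * 4L)

  le2 <- leading_edge(gt$observed, default_inputs(gt), horizon = 2,
                      seed = 3, grid = grid,
                      base_params = sim_params(n_0 = 0.04), train_min = 12)
  expect_equal(nrow(le2$windows), 6L)
  expect_error(leading_edge(gt$observed, default_inputs(gt), horizon = 5,
                            seed = 3, grid = grid),
               "horizon must be 2 or 4")
})
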