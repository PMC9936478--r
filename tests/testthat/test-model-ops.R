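test_that("food availability is the capability-weighted dot product per child", {
  # normalisation anchor: fully capable, unshocked, single child, pure strategy
  expect_equal(compute_food_availability(c(1, 0, 0), c(1, 1, 1),
                                         c(1, 1, 1), 1), 1.0)
  # an 80% effectiveness reduction propagates linearly
  expect_equal(compute_food_availability(c(1, 0, 0), c(1, 1, 1),
                                         c(0.2, 1, 1), 1), 0.2)
  # mixed strategy, partial capability, two children
  expect_equal(compute_food_availability(c(0.5, 0.5, 0), c(1, 0, 1),
                                         c(1, 1, 1), 2), 0.25)
  expect_error(compute_food_availability(c(1, 0), c(1, 1, 1), c(1, 1, 1), 1),
               "length 3")
  expect_error(compute_food_availability(c(1, 0, 0), c(-1, 1, 1),
                                         c(1, 1, 1), 1), "negative")
})

test_that("sufficiency multiplies health and asset factors against n_0", {
  r <- evaluate_sufficiency(1.0, 1, 1, 0.5)
  expect_equal(r$n_s, 1.0)
  expect_true(r$sufficient)
  # multiplicative annihilation: a fully sick child cannot be sufficient
  r0 <- evaluate_sufficiency(1.0, 0, 1, 0.5)
  expect_equal(r0$n_s, 0)
  expect_false(r0$sufficient)
  r2 <- evaluate_sufficiency(0.8, 0.9, 0.8, 0.5)
  expect_equal(r2$n_s, 0.576)
  expect_true(r2$sufficient)
  expect_error(evaluate_sufficiency(1, 1.2, 1, 0.5), "\\[0, 1\\]")
  expect_error(evaluate_sufficiency(1, 1, 1, 0), "positive")
})

test_that("malnutrition requires K consecutive insufficient rounds", {
  expect_true(update_malnutrition(c(FALSE, FALSE), 2))
  expect_false(update_malnutrition(c(TRUE, FALSE), 2))
  # a break in the run resets the spell
  expect_false(update_malnutrition(c(FALSE, TRUE, FALSE), 2))
  # histories shorter than K cannot qualify (missing entries sufficient)
  expect_false(update_malnutrition(FALSE, 2))
  expect_error(update_malnutrition(logical(0), 2), "non-empty")
})

test_that("strategy selection is proportional to memory with a floor", {
  expect_identical(select_strategy(5), 1L)
  # equal memories: ~50/50 within 3 sigma of the binomial
  set.seed(11)
  n <- 10000
  draws <- vapply(seq_len(n), function(i) select_strategy(c(1, 1), 0.05),
                  integer(1))
  p_hat <- mean(draws == 1L)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n))
  # memories (2, 1) with no floor: 2:1 selection odds
  draws2 <- vapply(seq_len(30000), function(i) select_strategy(c(2, 1), 0),
                   integer(1))
  p2 <- mean(draws2 == 1L)
  expect_lt(abs(p2 - 2 / 3), 3 * sqrt(2 / 9 / 30000))
  # all-zero memory falls back to uniform rather than failing
  draws0 <- vapply(seq_len(5000), function(i) select_strategy(c(0, 0, 0), 0),
                   integer(1))
  expect_true(all(sort(unique(draws0)) == 1:3))
  expect_error(select_strategy(numeric(0)), "non-empty")
})

test_that("ward prevalence equals the brute-force child roster count", {
  hh <- make_households(n = 30, wards = "A")
  p <- sim_params(seed = 1)
  st <- initialize_model(hh, p)
  # no one malnourished
  expect_equal(aggregate_prevalence(st, "A"), 0)
  # 3 of 30 single-child households malnourished
  st$w[1:3] <- TRUE
  expect_equal(aggregate_prevalence(st, "A"), 10)
  expect_error(aggregate_prevalence(st, "Z"), "unknown ward")
  # mixed child counts against the exhaustive roster oracle
  for (rep in 1:5) {
    set.seed(100 + rep)
    kids <- sample(1:6, 20, replace = TRUE)
    flags <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    hh2 <- make_households(n = 20, wards = "A", n_children = kids)
    st2 <- initialize_model(hh2, sim_params(seed = rep))
    st2$w <- flags
    expect_equal(aggregate_prevalence(st2, "A"),
                 oracle_prevalence(kids, flags))
  }
})
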