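test_that("initialization is deterministic and respects the catalog", {
  hh <- make_households(n = 10)
  p <- sim_params(seed = 42)
  # singleton catalog forces every household onto that strategy
  cat1 <- matrix(c(0, 1, 0), 1, 3,
                 dimnames = list(NULL, colnames(strategy_catalog())))
  st <- initialize_model(hh, p, catalog = cat1)
  for (i in 1:10) {
    expect_equal(nrow(st$strat[[i]]), 1L)
    expect_equal(as.numeric(st$strat[[i]][1, ]), c(0, 1, 0))
  }
  # same seed twice: identical assignments
  s1 <- initialize_model(hh, p)
  s2 <- initialize_model(hh, p)
  expect_identical(s1$active, s2$active)
  expect_identical(s1$strat, s2$strat)
  expect_identical(s1$neighbors, s2$neighbors)
  expect_error(initialize_model(hh[0, ], p), "empty")
})

test_that("initial active strategies are uniform over a catalog of 6", {
  hh <- make_households(n = 10000, wards = "A")
  cat6 <- strategy_catalog(0.5)
  st <- initialize_model(hh, sim_params(seed = 9), catalog = cat6)
  counts <- tabulate(st$active, 6L)
  # 3 sigma band of the uniform multinomial cell count
  expected <- 10000 / 6
  band <- 3 * sqrt(10000 * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - expected) < band))
})

test_that("a step updates every household once, deterministically", {
  hh <- make_households(n = 20, caps = c(0.8, 0.6, 0.4), h_a = 0.9)
  p <- sim_params(seed = 7, n_0 = 0.3)
  x1 <- matrix(1, 2, 3, dimnames = list(c("A", "B"), NULL))
  run_two <- function() {
    st <- initialize_model(hh, p)
    step_model(st, x1)
    step_model(st, x1)
    st
  }
  a <- run_two()
  b <- run_two()
  expect_identical(a$last_ns, b$last_ns)
  expect_identical(a$w, b$w)
  expect_identical(a$mem, b$mem)
  expect_equal(a$t, 2L)
  # every household carries a realised n_s after the first step
  expect_false(anyNA(a$last_ns))
  expect_error(step_model(initialize_model(hh, p),
                          matrix(1, 1, 3, dimnames = list("A", NULL))),
               "missing stressor")
})

test_that("strategy weights still sum to 1 after many adaptive steps", {
  hh <- make_households(n = 24, caps = c(0.9, 0.5, 0.4), h_a = 0.6,
                        n_children = rep(1:4, 6))
  # harsh world so adapt/spawn fire often
  p <- sim_params(lambda = 0.5, spawn_rate = 0.5, n_0 = 0.4, seed = 3)
  st <- initialize_model(hh, p)
  x <- matrix(c(0.3, 1, 1, 0.3, 1, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), NULL))
  for (t in 1:12) {
    step_model(st, x)
    for (i in seq_along(st$strat)) {
      expect_true(all(abs(rowSums(st$strat[[i]]) - 1) < 1e-9))
      expect_lte(nrow(st$strat[[i]]), p$max_size)
      expect_equal(length(st$mem[[i]]), nrow(st$strat[[i]]))
      expect_true(st$active[i] >= 1 && st$active[i] <= nrow(st$strat[[i]]))
    }
  }
})

test_that("benign world yields identically zero prevalence", {
  hh <- make_households(n = 30, n_children = rep(1:2, 15))
  p <- sim_params(n_0 = 0.4, seed = 5)
  st <- initialize_model(hh, p)
  x1 <- matrix(1, 2, 3, dimnames = list(c("A", "B"), NULL))
  for (t in 1:8) {
    step_model(st, x1)
    expect_equal(aggregate_prevalence(st, "A"), 0)
    expect_equal(aggregate_prevalence(st, "B"), 0)
  }
})

test_that("adaptation is gated on failure and copies strictly better neighbours", {
  # lambda = spawn = 0: nothing changes even under failure
  hh <- make_households(n = 6, wards = "A", caps = c(0.1, 0.1, 0.1))
  p0 <- sim_params(lambda = 0, spawn_rate = 0, n_0 = 0.9, seed = 2)
  st <- initialize_model(hh, p0)
  sets_before <- st$strat
  step_model(st, matrix(1, 1, 3, dimnames = list("A", NULL)))
  expect_identical(st$strat, sets_before)

  # lambda = 1: a failing household adopts its better neighbour's strategy
  hh2 <- make_households(n = 2, wards = "A")
  hh2$cap_own <- c(0.1, 1)       # h1 fails on own production, h2 thrives
  hh2$cap_network <- c(0.1, 1)
  hh2$cap_market <- c(0.1, 1)
  p1 <- sim_params(lambda = 1, spawn_rate = 0, n_0 = 0.5, seed = 4,
                   neighborhood_k = 1, epsilon = 0)
  cat_own <- strategy_catalog(1)  # three pure strategies
  st2 <- initialize_model(hh2, p1, catalog = cat_own)
  x1 <- matrix(1, 1, 3, dimnames = list("A", NULL))
  step_model(st2, x1)  # h2's n_s = 1 recorded
  step_model(st2, x1)  # h1 fails and must copy h2's latest strategy
  expect_equal(as.numeric(st2$strat[[1]][st2$active[1], ]),
               as.numeric(st2$last_strat[2, ]))
})

test_that("ties among best neighbours are broken uniformly", {
  # household 1 always fails; neighbours 2 and 3 are identical twins that
  # always succeed with distinct pure strategies
  hh <- make_households(n = 3, wards = "A")
  hh$cap_own <- c(0.01, 1, 1)
  hh$cap_network <- c(0.01, 1, 1)
  hh$cap_market <- c(0.01, 1, 1)
  x1 <- matrix(1, 1, 3, dimnames = list("A", NULL))
  picks <- integer(400)
  for (r in seq_len(400)) {
    p <- sim_params(lambda = 1, spawn_rate = 0, n_0 = 0.5, seed = r,
                    neighborhood_k = 2, epsilon = 0)
    st <- initialize_model(hh, p, catalog = strategy_catalog(1))
    # pin the twins to distinct strategies, the victim to a third
    st$strat[[1]] <- strategy_catalog(1)[1, , drop = FALSE]
    st$mem[[1]] <- 0
    st$active[1] <- 1L
    st$strat[[2]] <- strategy_catalog(1)[2, , drop = FALSE]
    st$mem[[2]] <- 0
    st$active[2] <- 1L
    st$strat[[3]] <- strategy_catalog(1)[3, , drop = FALSE]
    st$mem[[3]] <- 0
    st$active[3] <- 1L
    step_model(st, x1)  # twins record n_s = 1, victim fails
    step_model(st, x1)  # victim copies one of the tied twins
    adopted <- st$strat[[1]][st$active[1], ]
    picks[r] <- if (adopted["local_networks"] == 1) 2L else 3L
  }
  p_hat <- mean(picks == 2L)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("mean prevalence is monotone in shock severity", {
  hh <- make_households(n = 40, wards = "A", caps = c(0.9, 0.3, 0.3),
                        h_a = 0.8, n_children = rep(1:2, 20))
  mean_prev <- function(factor_own) {
    vapply(1:20, function(s) {
      p <- sim_params(n_0 = 0.3, seed = s)
      st <- initialize_model(hh, p)
      x <- matrix(c(factor_own, 1, 1), 1, 3, dimnames = list("A", NULL))
      for (t in 1:6) step_model(st, x)
      aggregate_prevalence(st, "A")
    }, numeric(1)) |> mean()
  }
  m_none <- mean_prev(1)
  m_mid <- mean_prev(0.6)
  m_hard <- mean_prev(0.3)
  expect_lte(m_none, m_mid)
  expect_lte(m_mid, m_hard)
})

test_that("under sustained shock, more learning means no more malnutrition", {
  # adaptation benefit: mean prevalence non-increasing in lambda
  cfg <- generator_config(n_wards = 2, months = 15, seed = 31,
                          shock_schedule = data.frame(
                            type = "drought", start = 4L, duration = 12L,
                            magnitude = -3))
  hh <- generate_households(cfg)
  str <- generate_stressors(cfg)
  mean_prev <- function(lam) {
    vapply(1:20, function(s) {
      p <- sim_params(lambda = lam, spawn_rate = 0.05, n_0 = 0.04,
                      seed = 500 + s)
      mean(simulate_run(hh, str, p)$prevalence_pct)
    }, numeric(1)) |> mean()
  }
  lo <- mean_prev(0.025)
  hi <- mean_prev(0.075)
  expect_lte(hi, lo)
})
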