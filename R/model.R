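#' Per-child food availability of a strategy
#'
#' The selected strategy `s` together with the household capability profile
#' `h_s` and the external effectiveness factors `x` determines food
#' availability: the sum over the three dimensions of
#' `s_d * h_s_d * x_d`, divided by the number of children. Units are
#' normalised so that a fully capable, unshocked, single-child household on
#' any pure strategy attains 1.0.
#'
#' @param strategy Numeric 3-vector of reliance weights (sums to 1).
#' @param h_s Numeric 3-vector of capabilities, each in `[0, 1]`.
#' @param x Numeric 3-vector of effectiveness factors, each in `(0, 1]`.
#' @param n_children Number of children in the household (>= 1).
#' @return Food available per child (scalar >= 0).
#' @examples
#' compute_food_availability(c(1, 0, 0), c(1, 1, 1), c(1, 1, 1), 1)   # 1.0
#' compute_food_availability(c(1, 0, 0), c(1, 1, 1), c(0.2, 1, 1), 1) # 0.2
#' @export
compute_food_availability <- function(strategy, h_s, x, n_children) {
  if (length(strategy) != 3L || length(h_s) != 3L || length(x) != 3L) {
    stop("strategy, h_s and x must all have length 3", call. = FALSE)
  }
  if (any(strategy < 0) || any(h_s < 0) || any(x < 0) || n_children < 1) {
    stop("negative inputs are not allowed; n_children must be >= 1",
         call. = FALSE)
  }
  sum(strategy * h_s * x) / n_children
}

#' Nutritional sufficiency of a household round
#'
#' Food availability is necessary but not sufficient for child nutrition:
#' realised nutrition `n_s` is further constrained multiplicatively by the
#' health factor `h_p` and monetary assets `h_a` (both in `[1 ... 0]`; the
#' sicker the child or the smaller the assets, the greater the reduction).
#' The household is sufficient this round when `n_s >= n_0`.
#'
#' @param food_per_child Food available per child (>= 0).
#' @param h_p Health factor in `[0, 1]`.
#' @param h_a Asset factor in `[0, 1]`.
#' @param n_0 Global sufficiency threshold (> 0).
#' @return A list with elements `n_s` and `sufficient`.
#' @examples
#' evaluate_sufficiency(0.8, 0.9, 0.8, 0.5)  # n_s = 0.576, sufficient
#' @export
evaluate_sufficiency <- function(food_per_child, h_p, h_a, n_0) {
  if (h_p < 0 || h_p > 1 || h_a < 0 || h_a > 1) {
    stop("h_p and h_a must lie in [0, 1]", call. = FALSE)
  }
  if (n_0 <= 0) stop("n_0 must be positive", call. = FALSE)
  if (food_per_child < 0) stop("food_per_child must be >= 0", call. = FALSE)
  n_s <- food_per_child * h_p * h_a
  list(n_s = n_s, sufficient = n_s >= n_0)
}

#' Acute malnutrition as sustained insufficiency
#'
#' A household is acutely malnourished (`w = TRUE`) when it has failed the
#' sufficiency threshold for `K` consecutive rounds, i.e. the most recent
#' `K` entries of its sufficiency history are all insufficient. When the
#' history is shorter than `K`, the missing leading entries are treated as
#' sufficient, so a household cannot be malnourished before it has `K`
#' recorded failures.
#'
#' @param sufficiency_history Logical vector, ordered oldest to newest;
#'   `TRUE` means the household was sufficient that round.
#' @param K Persistence window (>= 1).
#' @return Logical `w`.
#' @examples
#' update_malnutrition(c(FALSE, FALSE), 2)        # TRUE
#' update_malnutrition(c(FALSE, TRUE, FALSE), 2)  # FALSE
#' @export
update_malnutrition <- function(sufficiency_history, K) {
  if (length(sufficiency_history) == 0L) {
    stop("sufficiency_history must be non-empty", call. = FALSE)
  }
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (length(sufficiency_history) < K) return(FALSE)
  recent <- sufficiency_history[(length(sufficiency_history) - K + 1L):
                                  length(sufficiency_history)]
  all(!recent)
}

#' Performance-weighted strategy selection
#'
#' Samples a strategy index with probability proportional to
#' `memory + epsilon * mean(memory)`: successful strategies are more likely
#' to be selected, while the selection floor `epsilon` preserves some
#' exploration. With an all-zero memory (and regardless of `epsilon`) the
#' draw falls back to uniform. Consumes the global RNG stream.
#'
#' @param memory Numeric vector of smoothed per-strategy performance scores.
#' @param epsilon Selection floor in `[0, 1)`.
#' @return An integer index into `memory`.
#' @export
select_strategy <- function(memory, epsilon = 0.05) {
  k <- length(memory)
  if (k == 0L) stop("strategy set must be non-empty", call. = FALSE)
  if (k == 1L) return(1L)
  w <- memory + epsilon * mean(memory)
  tot <- sum(w)
  if (tot <= 0) return(sample.int(k, 1L))
  sample.int(k, 1L, prob = w)
}

## ---- model state ---------------------------------------------------------

#' Initialize the household model state
#'
#' Each household receives a strategy set drawn from the catalog (the whole
#' catalog when it fits under `max_size`, otherwise a uniform random subset),
#' a uniformly random initial active strategy, and a common performance
#' memory prior. Households use the coordinates given in the table; rows
#' with missing coordinates are placed uniformly at random inside their
#' ward's unit cell. Neighbourhoods are the `neighborhood_k` nearest
#' same-ward households by planar distance, fixed for the run. Seeds the
#' single global RNG stream with `params$seed`.
#'
#' @param households Household table as read by [read_households_csv()]:
#'   columns `id`, `ward_id`, `x`, `y`, `cap_own`, `cap_network`,
#'   `cap_market`, `h_p`, `h_a`, `n_children`, optionally
#'   `livelihood_zone`.
#' @param params An [sim_params()] object.
#' @param catalog Strategy catalog matrix, see [strategy_catalog()].
#' @param zone_masks Optional named list of zone name -> logical mask over
#'   catalog rows, restricting the strategies available in that livelihood
#'   zone.
#' @return An environment of class `amews_state`.
#' @export
initialize_model <- function(households, params,
                             catalog = strategy_catalog(),
                             zone_masks = NULL) {
  validate_households(households)
  validate_params(params)
  validate_catalog(catalog)
  set.seed(params$seed)

  n <- nrow(households)
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$params <- params
  st$ward <- as.character(households$ward_id)
  st$ward_levels <- sort(unique(st$ward))
  st$ward_idx <- match(st$ward, st$ward_levels)
  st$hs <- cbind(households$cap_own, households$cap_network,
                 households$cap_market)
  st$hp <- households$h_p
  st$ha <- households$h_a
  st$children <- as.integer(households$n_children)
  st$id <- households$id

  xx <- if ("x" %in% names(households)) households$x else rep(NA_real_, n)
  yy <- if ("y" %in% names(households)) households$y else rep(NA_real_, n)
  miss <- is.na(xx) | is.na(yy)
  if (any(miss)) {
    xx[miss] <- st$ward_idx[miss] + stats::runif(sum(miss))
    yy[miss] <- stats::runif(sum(miss))
  }
  st$x <- xx
  st$y <- yy

  zones <- if ("livelihood_zone" %in% names(households)) {
    as.character(households$livelihood_zone)
  } else {
    rep(NA_character_, n)
  }

  st$strat <- vector("list", n)
  st$mem <- vector("list", n)
  st$active <- integer(n)
  for (i in seq_len(n)) {
    cat_i <- catalog
    if (!is.na(zones[i]) && !is.null(zone_masks) &&
        zones[i] %in% names(zone_masks)) {
      cat_i <- catalog[zone_masks[[zones[i]]], , drop = FALSE]
      if (nrow(cat_i) == 0L) {
        stop("zone mask for '", zones[i], "' removed every strategy",
             call. = FALSE)
      }
    }
    m <- nrow(cat_i)
    rows <- if (m <= params$max_size) seq_len(m) else
      sample.int(m, params$max_size)
    st$strat[[i]] <- cat_i[rows, , drop = FALSE]
    st$mem[[i]] <- rep(params$memory_prior, length(rows))
    st$active[i] <- sample.int(length(rows), 1L)
  }

  st$last_ns <- rep(NA_real_, n)
  st$last_strat <- matrix(NA_real_, n, 3L)
  st$consec <- integer(n)
  st$w <- logical(n)
  st$neighbors <- build_neighbors(st$x, st$y, st$ward_idx,
                                  params$neighborhood_k)
  class(st) <- "amews_state"
  st
}

build_neighbors <- function(x, y, ward_idx, k) {
  n <- length(x)
  nb <- vector("list", n)
  for (wi in unique(ward_idx)) {
    ids <- which(ward_idx == wi)
    if (length(ids) == 1L) { nb[[ids]] <- integer(0); next }
    d <- as.matrix(stats::dist(cbind(x[ids], y[ids])))
    for (a in seq_along(ids)) {
      ord <- order(d[a, ])
      ord <- ord[ord != a]
      nb[[ids[a]]] <- ids[ord[seq_len(min(k, length(ord)))]]
    }
  }
  nb
}

#' @export
print.amews_state <- function(x, ...) {
  cat(sprintf("<amews_state> %d households, %d wards, month index %d\n",
              length(x$id), length(x$ward_levels), x$t))
  invisible(x)
}

#' Advance the model by one month
#'
#' Runs one round of the cycle: each household, in a freshly shuffled
#' random sequential order, (1) selects a strategy from its set by
#' performance-weighted sampling, (2) realises per-child food availability
#' under the current effectiveness factors and its capability profile,
#' (3) evaluates sufficiency and updates its malnutrition state, and
#' (4) if insufficient, adapts: with probability `lambda` it copies the
#' strategy of the neighbour with the highest most-recent realised `n_s`
#' (only if that strictly exceeds its own; ties broken uniformly), and
#' independently with probability `spawn_rate` it appends a mutated version
#' of its active strategy, evicting the lowest-memory strategy if the set
#' cap is exceeded. Performance memory is updated by an exponential moving
#' average of realised `n_s`.
#'
#' @param state An `amews_state` created by [initialize_model()]; modified
#'   in place and returned invisibly.
#' @param x_ward Numeric matrix of effectiveness factors for the current
#'   month: one row per ward (rownames = ward ids), columns
#'   `(own_production, local_networks, buy_barter)`.
#' @return The updated state, invisibly.
#' @export
step_model <- function(state, x_ward) {
  p <- state$params
  missing_wards <- setdiff(state$ward_levels, rownames(x_ward))
  if (length(missing_wards)) {
    stop("missing stressor rows for ward(s): ",
         paste(missing_wards, collapse = ", "), call. = FALSE)
  }
  xw <- x_ward[state$ward_levels, , drop = FALSE]
  n <- length(state$id)
  ord <- sample.int(n)
  lambda <- p$lambda; spawn <- p$spawn_rate; n0 <- p$n_0
  alpha <- p$ema_alpha; eps <- p$epsilon; K <- p$K

  for (i in ord) {
    mem_i <- state$mem[[i]]
    j <- select_strategy(mem_i, eps)
    s <- state$strat[[i]][j, ]
    xv <- xw[state$ward_idx[i], ]
    food <- sum(s * state$hs[i, ] * xv) / state$children[i]
    ns <- food * state$hp[i] * state$ha[i]
    suff <- ns >= n0
    state$consec[i] <- if (suff) 0L else state$consec[i] + 1L
    state$w[i] <- state$consec[i] >= K
    mem_i[j] <- (1 - alpha) * mem_i[j] + alpha * ns
    state$mem[[i]] <- mem_i
    state$active[i] <- j
    state$last_strat[i, ] <- s
    state$last_ns[i] <- ns

    if (!suff) {
      nb <- state$neighbors[[i]]
      if (stats::runif(1) < lambda && length(nb)) {
        nb_ns <- state$last_ns[nb]
        ok <- !is.na(nb_ns)
        if (any(ok)) {
          best <- max(nb_ns[ok])
          if (best > ns) {
            cand <- nb[ok][nb_ns[ok] == best]
            src <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)]
                   else cand
            adopt_strategy(state, i, state$last_strat[src, ], best)
          }
        }
      }
      if (stats::runif(1) < spawn) {
        spawn_strategy(state, i)
      }
    }
  }
  state$t <- state$t + 1L
  invisible(state)
}

# copy a neighbour's strategy into household i's set (regardless of own h_s),
# seed its memory with the observed performance, and make it active
adopt_strategy <- function(state, i, s, observed_ns) {
  set_m <- state$strat[[i]]
  hit <- strategy_in_set(s, set_m)
  if (hit > 0L) {
    state$mem[[i]][hit] <- observed_ns
    state$active[i] <- hit
  } else {
    append_strategy(state, i, s, observed_ns, make_active = TRUE)
  }
  invisible(state)
}

# mutate the active strategy: symmetric gaussian perturbation, truncated at 0
# and renormalised; degenerate all-zero perturbations fall back to uniform
spawn_strategy <- function(state, i) {
  p <- state$params
  s <- state$strat[[i]][state$active[i], ]
  v <- pmax(s + stats::rnorm(3L, 0, p$spawn_scale), 0)
  if (sum(v) <= 0) v <- rep(1, 3L)
  v <- v / sum(v)
  if (strategy_in_set(v, state$strat[[i]]) > 0L) return(invisible(state))
  append_strategy(state, i, v, mean(state$mem[[i]]), make_active = FALSE)
  invisible(state)
}

append_strategy <- function(state, i, s, memory0, make_active) {
  set_m <- rbind(state$strat[[i]], as.numeric(s))
  mem <- c(state$mem[[i]], memory0)
  new_idx <- nrow(set_m)
  active <- if (make_active) new_idx else state$active[i]
  if (nrow(set_m) > state$params$max_size) {
    drop <- which.min(mem)
    set_m <- set_m[-drop, , drop = FALSE]
    mem <- mem[-drop]
    if (active == drop) {
      # the strategy we meant to keep active was itself evicted (it had the
      # lowest memory); fall back to the best remaining one
      active <- which.max(mem)
    } else if (active > drop) {
      active <- active - 1L
    }
  }
  state$strat[[i]] <- set_m
  state$mem[[i]] <- mem
  state$active[i] <- active
  invisible(state)
}

#' Ward-level acute malnutrition prevalence
#'
#' Aggregates household malnutrition states to the ward level. Households
#' are weighted by their number of children so the statistic matches
#' child-level MUAC-based prevalence: `100 * (children in malnourished
#' households) / (children in the ward)`.
#'
#' @param state An `amews_state`.
#' @param ward_id Ward identifier.
#' @return Prevalence in percent, in `[0, 100]`.
#' @export
aggregate_prevalence <- function(state, ward_id) {
  sel <- state$ward == as.character(ward_id)
  if (!any(sel)) stop("unknown ward '", ward_id, "'", call. = FALSE)
  100 * sum(state$children[sel][state$w[sel]]) / sum(state$children[sel])
}

#' Run the simulation over a monthly stressor series
#'
#' Initialises the model and steps it through every month of the stressor
#' table in chronological order, recording ward-month prevalence. An
#' optional scenario modifies effectiveness factors, assets and the
#' learning rate (see [build_scenario()]); multiplier 1 scenarios are exact
#' no-ops.
#'
#' @inheritParams initialize_model
#' @param stressors Stressor table as read by [read_stressors_csv()].
#' @param spar A [stressor_params()] object.
#' @param scenario Optional `amews_scenario` from [build_scenario()].
#' @param ipc_thresholds IPC phase breakpoints, see [prevalence_to_ipc()].
#' @return A data.frame with columns `ward_id`, `month`, `prevalence_pct`,
#'   `ipc_phase`, one row per ward-month.
#' @examples
#' synth <- generate_ground_truth(generator_config(n_wards = 2, months = 6,
#'                                                 seed = 7))
#' head(synth$observed)
#' @export
simulate_run <- function(households, stressors, params,
                         catalog = strategy_catalog(),
                         spar = stressor_params(),
                         scenario = NULL,
                         zone_masks = NULL,
                         ipc_thresholds = ipc_default_thresholds()) {
  fct <- stressor_factors(stressors, spar)
  months <- sort(unique(fct$month))

  state <- initialize_model(households, params, catalog, zone_masks)
  wards <- state$ward_levels
  scen_months <- scenario_months(scenario, months)

  out <- vector("list", length(months))
  for (ti in seq_along(months)) {
    mo <- months[ti]
    f <- fct[fct$month == mo, , drop = FALSE]
    xm <- as.matrix(f[, c("x_own", "x_net", "x_buy")])
    rownames(xm) <- as.character(f$ward_id)
    if (!is.null(scenario) && mo %in% scen_months) {
      if (mo == scen_months[1L]) {
        # scenario modifiers switch on at the start of the forecast window
        state$ha <- state$ha * scenario$income_multiplier
        state$params$lambda <- state$params$lambda *
          scenario$lambda_multiplier
      }
      xm <- sweep(xm, 2L, scenario$dimension_multipliers, `*`)
    }
    step_model(state, xm)
    prev <- vapply(wards, function(wd) aggregate_prevalence(state, wd),
                   numeric(1))
    out[[ti]] <- data.frame(ward_id = wards, month = mo,
                            prevalence_pct = as.numeric(prev),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$ward_id, res$month), ]
  rownames(res) <- NULL
  res$ipc_phase <- vapply(res$prevalence_pct, prevalence_to_ipc,
                          integer(1), thresholds = ipc_thresholds)
  res
}
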