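#' Build a counterfactual scenario specification
#'
#' Presets reproduce the counterfactual shock experiments crossed with
#' adaptive-capacity settings:
#'
#' * `climate` -- an early onset of the lean season reduces food from own
#'   production by 20% (own-production multiplier 0.8);
#' * `economic` -- pandemic-style restrictions reduce the ability of
#'   households to generate income by 50% (income multiplier 0.5 on the
#'   asset factor `h_a`);
#' * `combined` -- both at once;
#' * `baseline` -- no shock.
#'
#' Adaptive capacity is `baseline` (the calibrated learning rate),
#' `constrained` (lambda decreased by 50%) or `enabled` (lambda increased
#' by 50%). All modifiers take effect over the final `horizon_months` of
#' the simulated span (the forecast window); multiplier-1 presets are
#' exact no-ops.
#'
#' @param shock One of `"baseline"`, `"climate"`, `"economic"`,
#'   `"combined"`.
#' @param adaptation One of `"baseline"`, `"constrained"`, `"enabled"`.
#' @param horizon_months Length of the forecast window the modifiers
#'   apply to (default 4).
#' @return A list of class `amews_scenario` with `name`,
#'   `dimension_multipliers`, `income_multiplier`, `lambda_multiplier`,
#'   `horizon_months`.
#' @examples
#' build_scenario("climate")$dimension_multipliers   # 0.8 1 1
#' build_scenario("economic")$income_multiplier      # 0.5
#' build_scenario("climate", "enabled")$lambda_multiplier  # 1.5
#' @export
build_scenario <- function(shock = c("baseline", "climate", "economic",
                                     "combined"),
                           adaptation = c("baseline", "constrained",
                                          "enabled"),
                           horizon_months = 4L) {
  shock <- match.arg(shock)
  adaptation <- match.arg(adaptation)
  dims <- c(own_production = 1, local_networks = 1, buy_barter = 1)
  income <- 1
  if (shock %in% c("climate", "combined")) dims["own_production"] <- 0.8
  if (shock %in% c("economic", "combined")) income <- 0.5
  lam_mult <- switch(adaptation, baseline = 1, constrained = 0.5,
                     enabled = 1.5)
  structure(list(name = paste(shock, adaptation, sep = "_"),
                 shock = shock, adaptation = adaptation,
                 dimension_multipliers = dims,
                 income_multiplier = income,
                 lambda_multiplier = lam_mult,
                 horizon_months = as.integer(horizon_months)),
            class = "amews_scenario")
}

#' @export
print.amews_scenario <- function(x, ...) {
  cat(sprintf(
    "<amews_scenario> %s: dims=(%.2g, %.2g, %.2g) income=%.2g lambda x %.2g over %d months\n",
    x$name, x$dimension_multipliers[1], x$dimension_multipliers[2],
    x$dimension_multipliers[3], x$income_multiplier, x$lambda_multiplier,
    x$horizon_months))
  invisible(x)
}

# months of the simulated span a scenario's modifiers cover (the final
# horizon_months, i.e. the forecast window)
scenario_months <- function(scenario, months) {
  if (is.null(scenario)) return(character(0))
  h <- min(scenario$horizon_months, length(months))
  months[(length(months) - h + 1L):length(months)]
}

#' Run counterfactual scenarios
#'
#' Simulates each scenario from the same initial state structure: replicate
#' `r` of every scenario uses the same seed, so the baseline scenario
#' reproduces the plain simulation exactly and scenario contrasts are
#' paired. Income multipliers act on `h_a`, dimension multipliers compose
#' multiplicatively onto the observed effectiveness factors, and the
#' lambda multiplier scales the calibrated learning rate; all from the
#' start of the forecast window.
#'
#' @param params Calibrated [sim_params()].
#' @param inputs List with `households` and `stressors` (and optionally
#'   `catalog`, `spar`, `zone_masks`).
#' @param specs A single [build_scenario()] spec or a list of them.
#' @param replicates Number of replicate runs per scenario.
#' @param seed Seed for the replicate seed stream.
#' @return A tidy data.frame: `scenario`, `replicate`, `ward_id`, `month`,
#'   `prevalence_pct`, `ipc_phase`.
#' @export
run_counterfactuals <- function(params, inputs, specs, replicates = 20L,
                                seed = 1L) {
  if (inherits(specs, "amews_scenario")) specs <- list(specs)
  stopifnot(length(specs) >= 1L, replicates >= 1L)
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("scenario names must be unique", call. = FALSE)
  lam <- params$lambda *
    vapply(specs, `[[`, numeric(1), "lambda_multiplier")
  out_of_box <- !vapply(lam, in_calibration_box, logical(1))
  if (any(out_of_box)) {
    message("scenario lambda outside the calibration box [0.01, 0.1]: ",
            paste(sprintf("%s (%.3g)", nm[out_of_box], lam[out_of_box]),
                  collapse = ", "))
  }

  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, replicates)
  res <- vector("list", length(specs) * replicates)
  k <- 0L
  for (sp in specs) {
    for (r in seq_len(replicates)) {
      p <- params
      p$seed <- rep_seeds[r]
      sim <- simulate_run(inputs$households, inputs$stressors, p,
                          catalog = inputs$catalog %||% strategy_catalog(),
                          spar = inputs$spar %||% stressor_params(),
                          scenario = sp,
                          zone_masks = inputs$zone_masks)
      k <- k + 1L
      res[[k]] <- cbind(scenario = sp$name, replicate = r, sim,
                        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarise counterfactual trajectories
#'
#' Per scenario-ward-month mean prevalence with a 95% interval given by
#' the 2.5 and 97.5 percentiles over replicates.
#'
#' @param trajectories Output of [run_counterfactuals()].
#' @return A data.frame `scenario`, `ward_id`, `month`, `mean_pct`,
#'   `lo_pct`, `hi_pct`.
#' @export
summarize_counterfactuals <- function(trajectories) {
  sp <- split(trajectories$prevalence_pct,
              list(scenario = trajectories$scenario,
                   ward_id = trajectories$ward_id,
                   month = trajectories$month),
              drop = TRUE, sep = "\r")
  keys <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
  out <- data.frame(scenario = keys[, 1], ward_id = keys[, 2],
                    month = keys[, 3],
                    mean_pct = vapply(sp, mean, numeric(1)),
                    lo_pct = vapply(sp, stats::quantile, numeric(1),
                                    probs = 0.025, names = FALSE),
                    hi_pct = vapply(sp, stats::quantile, numeric(1),
                                    probs = 0.975, names = FALSE),
                    stringsAsFactors = FALSE)
  out <- out[order(out$scenario, out$ward_id, out$month), ]
  rownames(out) <- NULL
  out
}
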