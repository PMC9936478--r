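#' Calibration grid specification
#'
#' Axes of the grid search over the behavioural parameters that are
#' central to the mechanism yet empirically unobservable: the learning
#' rate and spawn rate (both boxed in `[0.01, 0.1]`), and optionally the
#' sufficiency threshold `n_0`.
#'
#' @param lambda Learning-rate axis.
#' @param spawn Spawn-rate axis.
#' @param n_0 Optional `n_0` axis; `NULL` keeps the base value.
#' @param replicates Replicate simulations per grid cell.
#' @return A list of class `amews_grid`.
#' @export
calibration_grid <- function(lambda = seq(0.01, 0.1, by = 0.01),
                             spawn = 0.05,
                             n_0 = NULL,
                             replicates = 20L) {
  stopifnot(length(lambda) >= 1L, length(spawn) >= 1L, replicates >= 1L)
  if (any(lambda < 0.01 - 1e-12) || any(lambda > 0.1 + 1e-12)) {
    stop("lambda axis must stay inside the calibration box [0.01, 0.1]",
         call. = FALSE)
  }
  if (any(spawn < 0.01 - 1e-12) || any(spawn > 0.1 + 1e-12)) {
    stop("spawn axis must stay inside the calibration box [0.01, 0.1]",
         call. = FALSE)
  }
  structure(list(lambda = lambda, spawn = spawn, n_0 = n_0,
                 replicates = as.integer(replicates)),
            class = "amews_grid")
}

# mean validation metrics of R replicate runs of `params` against the
# observed rows whose months fall in `score_months`; also returns the
# replicate-mean predicted trajectory over those months
replicate_scores <- function(observed, inputs, params, rep_seeds,
                             score_months, thresholds) {
  obs <- observed[observed$month %in% score_months, , drop = FALSE]
  f1 <- rms <- ham <- numeric(length(rep_seeds))
  acc <- NULL
  for (r in seq_along(rep_seeds)) {
    p <- params
    p$seed <- rep_seeds[r]
    sim <- simulate_run(inputs$households, inputs$stressors, p,
                        catalog = inputs$catalog %||% strategy_catalog(),
                        spar = inputs$spar %||% stressor_params(),
                        zone_masks = inputs$zone_masks,
                        ipc_thresholds = thresholds)
    rep_report <- validation_report(obs, sim, thresholds)
    f1[r] <- rep_report$f1_macro
    rms[r] <- rep_report$rmsd
    ham[r] <- rep_report$hamming
    sim <- sim[sim$month %in% score_months, , drop = FALSE]
    sim <- sim[order(sim$ward_id, sim$month), , drop = FALSE]
    if (is.null(acc)) {
      acc <- sim
      acc$prevalence_pct <- acc$prevalence_pct / length(rep_seeds)
    } else {
      acc$prevalence_pct <- acc$prevalence_pct +
        sim$prevalence_pct / length(rep_seeds)
    }
  }
  obs_o <- obs[order(obs$ward_id, obs$month), , drop = FALSE]
  key <- paste(obs_o$ward_id, obs_o$month)
  pidx <- match(key, paste(acc$ward_id, acc$month))
  list(f1 = mean(f1), rmsd_rep = mean(rms), hamming = mean(ham),
       rmsd = rmsd(obs_o$prevalence_pct / 100,
                   acc$prevalence_pct[pidx] / 100),
       n = nrow(obs), mean_pred = acc)
}

mean_report <- function(sc) {
  structure(list(f1_macro = sc$f1, hamming = sc$hamming, rmsd = sc$rmsd,
                 valid = joint_validity(sc$f1, sc$rmsd), n = sc$n),
            class = "amews_report")
}

#' Calibrate behavioural parameters against observed prevalence
#'
#' Grid search: every cell is simulated with `replicates` common-random-
#' number replicate runs over the observed span, and scored by the RMSD of
#' the replicate-mean trajectory against the observations (proportion
#' scale, minimised), with mean macro F1 as tie-break (maximised). Scoring
#' the replicate mean rather than averaging single-run RMSDs shrinks the
#' simulation-noise contribution roughly as `1/replicates`, leaving the
#' systematic bias the objective is meant to measure. The first `burn_in`
#' months are discarded before scoring, since the malnutrition state
#' needs history to be meaningful. Deterministic given `seed`.
#'
#' @param observed Observed ward-month prevalence (`ward_id`, `month`,
#'   `prevalence_pct`); needs at least 2 wards and 6 months.
#' @param inputs List with `households` and `stressors` (and optionally
#'   `catalog`, `spar`, `zone_masks`).
#' @param grid An [calibration_grid()].
#' @param seed Integer seed for the replicate seed stream.
#' @param base_params Base [sim_params()] supplying every parameter not on
#'   a grid axis.
#' @param burn_in Months discarded before scoring (default 6).
#' @param thresholds IPC breakpoints used for the F1 tie-break.
#' @return A list of class `amews_calibration`: `best_params`, `report`
#'   (mean metrics of the best cell), `grid_table` (one scored row per
#'   cell).
#' @export
calibrate <- function(observed, inputs, grid, seed = 1L,
                      base_params = sim_params(),
                      burn_in = 6L,
                      thresholds = ipc_default_thresholds()) {
  stopifnot(inherits(grid, "amews_grid"))
  validate_prevalence(observed)
  if (length(unique(observed$ward_id)) < 2L) {
    warning("calibrating on a single ward; estimates may be fragile")
  }
  obs_months <- sort(unique(observed$month))
  if (length(obs_months) < 6L) {
    stop("observed data must cover at least 6 months", call. = FALSE)
  }
  # simulate only the observed span: no information beyond it is touched
  stress <- inputs$stressors
  stress <- stress[stress$month <= max(obs_months), , drop = FALSE]
  sim_months <- sort(unique(stress$month))
  score_months <- setdiff(sim_months, utils::head(sim_months, burn_in))
  score_months <- intersect(score_months, obs_months)
  if (length(score_months) == 0L) {
    stop("no months left to score after burn-in", call. = FALSE)
  }
  inputs$stressors <- stress

  cells <- expand.grid(lambda = grid$lambda, spawn = grid$spawn,
                       n_0 = if (is.null(grid$n_0)) NA_real_ else grid$n_0,
                       KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, grid$replicates)

  tab <- cells
  tab$rmsd <- tab$f1_macro <- tab$hamming <- NA_real_
  for (ci in seq_len(nrow(cells))) {
    p <- base_params
    p$lambda <- cells$lambda[ci]
    p$spawn_rate <- cells$spawn[ci]
    if (!is.na(cells$n_0[ci])) p$n_0 <- cells$n_0[ci]
    sc <- replicate_scores(observed, inputs, p, rep_seeds, score_months,
                           thresholds)
    tab$rmsd[ci] <- sc$rmsd
    tab$f1_macro[ci] <- sc$f1
    tab$hamming[ci] <- sc$hamming
  }

  best <- which(tab$rmsd == min(tab$rmsd))
  if (length(best) > 1L) best <- best[which.max(tab$f1_macro[best])]
  best_params <- base_params
  best_params$lambda <- cells$lambda[best]
  best_params$spawn_rate <- cells$spawn[best]
  if (!is.na(cells$n_0[best])) best_params$n_0 <- cells$n_0[best]

  sc_best <- list(f1 = tab$f1_macro[best], rmsd = tab$rmsd[best],
                  hamming = tab$hamming[best],
                  n = sum(observed$month %in% score_months))
  structure(list(best_params = best_params,
                 report = mean_report(sc_best),
                 grid_table = tab,
                 score_months = score_months,
                 seed = seed),
            class = "amews_calibration")
}

#' @export
print.amews_calibration <- function(x, ...) {
  cat(sprintf("<amews_calibration> best lambda=%.3g spawn=%.3g n_0=%.3g\n",
              x$best_params$lambda, x$best_params$spawn_rate,
              x$best_params$n_0))
  print(x$report)
  invisible(x)
}

#' Temporal-split evaluation
#'
#' Trains (calibrates) on all observations before `split_month`, then
#' simulates through the test span with the frozen best parameters and
#' reports mean validation metrics separately for the train and test
#' spans.
#'
#' @inheritParams calibrate
#' @param split_month First test month (ISO `"YYYY-MM"`); observations
#'   before it form the training span.
#' @param test_months Optional explicit test months overriding the
#'   default `>= split_month` rule.
#' @return A list of class `amews_split`: `calibration`, `train_report`,
#'   `test_report`.
#' @export
temporal_split_eval <- function(observed, inputs, split_month, grid,
                                seed = 1L, base_params = sim_params(),
                                burn_in = 6L,
                                thresholds = ipc_default_thresholds(),
                                test_months = NULL) {
  validate_prevalence(observed)
  train <- observed[observed$month < split_month, , drop = FALSE]
  test <- if (is.null(test_months)) {
    observed[observed$month >= split_month, , drop = FALSE]
  } else {
    observed[observed$month %in% test_months, , drop = FALSE]
  }
  if (nrow(train) == 0L || nrow(test) == 0L) {
    stop("the split must leave both train and test non-empty", call. = FALSE)
  }
  if (length(unique(observed$ward_id)) < 2L) {
    warning("temporal split on a single ward; reports are fragile")
  }

  cal <- calibrate(train, inputs, grid, seed = seed,
                   base_params = base_params, burn_in = burn_in,
                   thresholds = thresholds)

  # frozen parameters, fresh replicate seeds, simulate through the test span
  set.seed(seed + 1L)
  rep_seeds <- sample.int(2147483646L, grid$replicates)
  all_months <- sort(unique(observed$month))
  train_score <- intersect(cal$score_months, unique(train$month))
  test_score <- sort(unique(test$month))
  inputs$stressors <- inputs$stressors[
    inputs$stressors$month <= max(all_months), , drop = FALSE]
  sc_train <- replicate_scores(train, inputs, cal$best_params, rep_seeds,
                               train_score, thresholds)
  sc_test <- replicate_scores(test, inputs, cal$best_params, rep_seeds,
                              test_score, thresholds)
  structure(list(calibration = cal,
                 train_report = mean_report(sc_train),
                 test_report = mean_report(sc_test)),
            class = "amews_split")
}

#' @export
print.amews_split <- function(x, ...) {
  cat("Temporal split evaluation\n-- train --\n")
  print(x$train_report)
  cat("-- test --\n")
  print(x$test_report)
  invisible(x)
}

#' Rolling leading-edge forecast evaluation
#'
#' Splits the months after an initial training span into consecutive
#' non-overlapping windows of `horizon` months (12 test months at horizon
#' 4 give exactly 3 windows). Before each window the model is re-calibrated
#' on everything observed so far, then simulated through the window with
#' frozen parameters. Reports per-window validation metrics plus the
#' pooled distribution of per-ward-month forecast errors.
#'
#' @inheritParams calibrate
#' @param horizon Forecast window length in months; 2 or 4 unless
#'   `allow_any_horizon`.
#' @param train_min Months reserved as the initial training span.
#' @param allow_any_horizon Permit horizons other than 2 or 4.
#' @return A list of class `amews_leading_edge`: `windows` (one scored row
#'   per window), `errors` (pooled per-ward-month forecast errors on the
#'   proportion scale), `calibrations`.
#' @export
leading_edge <- function(observed, inputs, horizon = 4L, seed = 1L,
                         grid = calibration_grid(),
                         base_params = sim_params(),
                         train_min = 12L, burn_in = 6L,
                         thresholds = ipc_default_thresholds(),
                         allow_any_horizon = FALSE) {
  if (!horizon %in% c(2L, 4L) && !allow_any_horizon) {
    stop("horizon must be 2 or 4 months (set allow_any_horizon to override)",
         call. = FALSE)
  }
  validate_prevalence(observed)
  months <- sort(unique(observed$month))
  n_win <- (length(months) - train_min) %/% horizon
  if (n_win < 1L) {
    stop("need at least train_min + horizon months of observations",
         call. = FALSE)
  }

  win_rows <- vector("list", n_win)
  err_rows <- vector("list", n_win)
  cals <- vector("list", n_win)
  for (wi in seq_len(n_win)) {
    test_idx <- train_min + (wi - 1L) * horizon + seq_len(horizon)
    test_months <- months[test_idx]
    train_obs <- observed[observed$month < test_months[1L], , drop = FALSE]
    cal <- calibrate(train_obs, inputs, grid, seed = seed + wi,
                     base_params = base_params, burn_in = burn_in,
                     thresholds = thresholds)
    cals[[wi]] <- cal

    set.seed(seed + 1000L + wi)
    rep_seeds <- sample.int(2147483646L, grid$replicates)
    inp <- inputs
    inp$stressors <- inputs$stressors[
      inputs$stressors$month <= max(test_months), , drop = FALSE]
    test_obs <- observed[observed$month %in% test_months, , drop = FALSE]
    sc <- replicate_scores(test_obs, inp, cal$best_params, rep_seeds,
                           test_months, thresholds)

    # pooled forecast errors from the mean predicted trajectory
    pred <- sc$mean_pred
    key <- paste(test_obs$ward_id, test_obs$month)
    pidx <- match(key, paste(pred$ward_id, pred$month))
    err_rows[[wi]] <- data.frame(
      window = wi, ward_id = test_obs$ward_id, month = test_obs$month,
      error = (pred$prevalence_pct[pidx] - test_obs$prevalence_pct) / 100,
      stringsAsFactors = FALSE)
    win_rows[[wi]] <- data.frame(
      window = wi, start = test_months[1L],
      end = test_months[length(test_months)],
      lambda = cal$best_params$lambda, f1_macro = sc$f1,
      hamming = sc$hamming, rmsd = sc$rmsd,
      valid = joint_validity(sc$f1, sc$rmsd), stringsAsFactors = FALSE)
  }
  structure(list(windows = do.call(rbind, win_rows),
                 errors = do.call(rbind, err_rows),
                 calibrations = cals),
            class = "amews_leading_edge")
}

#' @export
print.amews_leading_edge <- function(x, ...) {
  cat(sprintf("<amews_leading_edge> %d windows\n", nrow(x$windows)))
  print(x$windows, row.names = FALSE)
  invisible(x)
}
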