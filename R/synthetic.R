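#' Configuration of the synthetic sentinel-survey generator
#'
#' Emulates the structure of NDMA-style sentinel surveillance: a fixed
#' panel of 30 households per sentinel site observed monthly, child-level
#' malnutrition aggregated to ward-month prevalence, and ward-level
#' climate/market stressor series expressed as deviations from long-term
#' baselines. Capability profiles follow livelihood-zone archetypes
#' (pastoral households strong in own production off livestock, weak in
#' market access; mixed farmers the reverse), assets come from a rich/poor
#' two-component mixture, and the shock schedule injects drought anomalies
#' (in NDVI z-units) and staple-price spikes (relative deviations).
#'
#' @param n_wards Number of wards.
#' @param sites_per_ward Sentinel sites per ward.
#' @param households_per_site Households tracked per site (panel design
#'   default 30).
#' @param months Length of the monthly series (>= 12 for stressors).
#' @param start_month First month, ISO `"YYYY-MM"`.
#' @param zones Livelihood zone per ward (recycled); names must exist in
#'   `archetypes`.
#' @param archetypes Named list of capability mean 3-vectors
#'   `(own, network, market)` per zone.
#' @param cap_sd Gaussian spread of capabilities around the archetype mean
#'   (clipped to `[0, 1]`).
#' @param hp_shape Beta shape parameters of the health factor `h_p`.
#' @param ha_rich,ha_poor Beta shape parameters of the asset factor for the
#'   rich and poor mixture components.
#' @param rich_weight Mixture weight of the rich component (poor gets
#'   `1 - rich_weight`).
#' @param child_lambda,child_max Truncated-Poisson child-count
#'   distribution on `{1, ..., child_max}`.
#' @param ndvi_lt_mean,ndvi_lt_sd Long-term NDVI baseline per ward.
#' @param ndvi_amplitude Seasonal sinusoid amplitude of the NDVI series.
#' @param ndvi_noise_sd Month-to-month NDVI noise.
#' @param price_baseline Long-term staple price (currency per 100 g).
#' @param price_drift Monthly linear relative drift of the price.
#' @param price_noise_sd Relative month-to-month price noise.
#' @param shock_schedule Data frame with columns `type`
#'   (`"drought"`/`"price"`), `start`, `duration` (month indices) and
#'   `magnitude` (NDVI z-units for droughts, negative for deficits;
#'   relative price deviation for spikes). `NULL` for no shocks.
#' @param seed Generator seed.
#' @return A list of class `amews_generator_config`.
#' @export
generator_config <- function(n_wards = 5L,
                             sites_per_ward = 1L,
                             households_per_site = 30L,
                             months = 24L,
                             start_month = "2017-01",
                             zones = c("pastoral", "agro_pastoral", "mixed"),
                             archetypes = list(
                               pastoral = c(0.85, 0.75, 0.6),
                               agro_pastoral = c(0.8, 0.75, 0.7),
                               mixed = c(0.7, 0.75, 0.85)),
                             cap_sd = 0.1,
                             hp_shape = c(18, 2),
                             ha_rich = c(5, 2),
                             ha_poor = c(2, 5),
                             rich_weight = 0.4,
                             child_lambda = 2,
                             child_max = 6L,
                             ndvi_lt_mean = 0.45,
                             ndvi_lt_sd = 0.1,
                             ndvi_amplitude = 0.02,
                             ndvi_noise_sd = 0.005,
                             price_baseline = 5,
                             price_drift = 0.001,
                             price_noise_sd = 0.02,
                             shock_schedule = default_shock_schedule(),
                             seed = 1L) {
  cfg <- list(n_wards = as.integer(n_wards),
              sites_per_ward = as.integer(sites_per_ward),
              households_per_site = as.integer(households_per_site),
              months = as.integer(months), start_month = start_month,
              zones = rep(zones, length.out = n_wards),
              archetypes = archetypes, cap_sd = cap_sd,
              hp_shape = hp_shape, ha_rich = ha_rich, ha_poor = ha_poor,
              rich_weight = rich_weight,
              child_lambda = child_lambda, child_max = as.integer(child_max),
              ndvi_lt_mean = ndvi_lt_mean, ndvi_lt_sd = ndvi_lt_sd,
              ndvi_amplitude = ndvi_amplitude,
              ndvi_noise_sd = ndvi_noise_sd,
              price_baseline = price_baseline, price_drift = price_drift,
              price_noise_sd = price_noise_sd,
              shock_schedule = shock_schedule, seed = as.integer(seed))
  stopifnot(cfg$n_wards >= 1L, cfg$sites_per_ward >= 1L,
            cfg$households_per_site >= 1L, cfg$months >= 1L,
            cfg$rich_weight >= 0, cfg$rich_weight <= 1,
            cfg$child_max >= 1L, cfg$ndvi_lt_sd > 0,
            cfg$price_baseline > 0, cfg$cap_sd >= 0)
  if (!all(cfg$zones %in% names(cfg$archetypes))) {
    stop("every zone needs an archetype", call. = FALSE)
  }
  class(cfg) <- "amews_generator_config"
  cfg
}

#' Default shock schedule of the synthetic fixture
#'
#' Two six-month droughts (-3 NDVI z-units, the signature of consecutive
#' failed rainy seasons as in the 2016-17 East African drought), one per
#' simulated year, and a three-month staple-price spike (+80% over
#' baseline) between them, hitting all wards. Sized so the default
#' pipeline produces multi-phase IPC variation with episodes in which
#' strategy adaptation matters.
#'
#' @return A data frame with columns `type`, `start`, `duration`,
#'   `magnitude`.
#' @export
default_shock_schedule <- function() {
  data.frame(type = c("drought", "price", "drought"),
             start = c(5L, 12L, 17L),
             duration = c(6L, 3L, 6L),
             magnitude = c(-3, 0.8, -3),
             stringsAsFactors = FALSE)
}

#' Benign generator configuration
#'
#' A degenerate world with fully capable, healthy, asset-rich households
#' (small families), no shocks, no seasonality and no noise, so every
#' effectiveness factor is exactly 1. Under the default sufficiency
#' threshold the simulated prevalence is identically zero -- the
#' benign-world limit used to validate the engine.
#'
#' @param ... Overrides passed on to [generator_config()].
#' @export
benign_generator_config <- function(...) {
  generator_config(archetypes = list(ideal = c(1, 1, 1)),
                   zones = "ideal", cap_sd = 0,
                   hp_shape = NULL, ha_rich = NULL, ha_poor = NULL,
                   child_lambda = 1, child_max = 2L,
                   ndvi_amplitude = 0, ndvi_noise_sd = 0,
                   price_drift = 0, price_noise_sd = 0,
                   shock_schedule = NULL, ...)
}

month_seq <- function(start_month, n) {
  first <- as.Date(paste0(start_month, "-01"))
  format(seq(first, by = "month", length.out = n), "%Y-%m")
}

rbeta_or_one <- function(n, shape) {
  if (is.null(shape)) rep(1, n) else stats::rbeta(n, shape[1], shape[2])
}

#' Generate a synthetic household table
#'
#' Sites are scattered inside their ward's unit cell and households
#' clustered around their site centre, giving the planar density structure
#' the neighbourhood graph operates on. Capabilities are archetype means
#' plus Gaussian spread (clipped to `[0, 1]`); `h_a` is drawn from the
#' rich/poor Beta mixture; child counts from a truncated Poisson.
#'
#' @param config An [generator_config()] object.
#' @return A household data.frame matching the `households.csv` schema,
#'   with a `livelihood_zone` column.
#' @export
generate_households <- function(config) {
  stopifnot(inherits(config, "amews_generator_config"))
  set.seed(config$seed)
  per_ward <- config$sites_per_ward * config$households_per_site
  n <- config$n_wards * per_ward
  if (n == 0L) stop("configuration yields zero households", call. = FALSE)

  ward <- rep(sprintf("W%02d", seq_len(config$n_wards)), each = per_ward)
  zone <- rep(config$zones, each = per_ward)
  site <- rep(rep(seq_len(config$sites_per_ward),
                  each = config$households_per_site), config$n_wards)

  # site centres uniform in the ward cell, households clustered around them
  ward_i <- rep(seq_len(config$n_wards), each = per_ward)
  ctr_x <- stats::runif(config$n_wards * config$sites_per_ward, 0.15, 0.85)
  ctr_y <- stats::runif(config$n_wards * config$sites_per_ward, 0.15, 0.85)
  site_idx <- (ward_i - 1L) * config$sites_per_ward + site
  x <- (ward_i - 1L) + pmin(pmax(ctr_x[site_idx] +
                                   stats::rnorm(n, 0, 0.08), 0), 1)
  y <- pmin(pmax(ctr_y[site_idx] + stats::rnorm(n, 0, 0.08), 0), 1)

  arch <- do.call(rbind, config$archetypes[zone])
  caps <- pmin(pmax(arch + matrix(stats::rnorm(3L * n, 0, config$cap_sd),
                                  n, 3L), 0), 1)

  h_p <- rbeta_or_one(n, config$hp_shape)
  rich <- stats::runif(n) < config$rich_weight
  h_a <- ifelse(rich, rbeta_or_one(n, config$ha_rich),
                rbeta_or_one(n, config$ha_poor))

  pk <- stats::dpois(seq_len(config$child_max), config$child_lambda)
  n_children <- sample.int(config$child_max, n, replace = TRUE,
                           prob = pk / sum(pk))

  data.frame(id = sprintf("h%05d", seq_len(n)),
             ward_id = ward, x = x, y = y,
             cap_own = caps[, 1], cap_network = caps[, 2],
             cap_market = caps[, 3],
             h_p = h_p, h_a = h_a, n_children = n_children,
             livelihood_zone = zone, stringsAsFactors = FALSE)
}

#' Generate a synthetic ward-month stressor table
#'
#' NDVI is a seasonal sinusoid around the long-term mean plus noise, with
#' scheduled drought anomalies expressed in z-units of the long-term
#' standard deviation. The staple price drifts and fluctuates around the
#' 10-year baseline, with scheduled relative spikes. Long-term baselines
#' are emitted alongside, constant per ward.
#'
#' @param config An [generator_config()] object (needs `months >= 12`).
#' @return A stressor data.frame matching the `stressors.csv` schema.
#' @export
generate_stressors <- function(config) {
  stopifnot(inherits(config, "amews_generator_config"))
  if (config$months < 12L) stop("months must be >= 12", call. = FALSE)
  set.seed(config$seed + 1L)
  months <- month_seq(config$start_month, config$months)
  t_idx <- seq_len(config$months)

  drought_z <- numeric(config$months)
  price_spike <- numeric(config$months)
  sched <- config$shock_schedule
  if (!is.null(sched) && nrow(sched)) {
    for (r in seq_len(nrow(sched))) {
      span <- sched$start[r]:(sched$start[r] + sched$duration[r] - 1L)
      span <- span[span >= 1L & span <= config$months]
      if (sched$type[r] == "drought") {
        drought_z[span] <- drought_z[span] + sched$magnitude[r]
      } else if (sched$type[r] == "price") {
        price_spike[span] <- price_spike[span] + sched$magnitude[r]
      } else {
        stop("unknown shock type '", sched$type[r], "'", call. = FALSE)
      }
    }
  }

  out <- vector("list", config$n_wards)
  season <- config$ndvi_amplitude * sin(2 * pi * (t_idx - 1L) / 12)
  for (wi in seq_len(config$n_wards)) {
    ndvi <- config$ndvi_lt_mean + season +
      stats::rnorm(config$months, 0, config$ndvi_noise_sd) +
      drought_z * config$ndvi_lt_sd
    price <- config$price_baseline *
      (1 + config$price_drift * (t_idx - 1L) +
         stats::rnorm(config$months, 0, config$price_noise_sd) +
         price_spike)
    out[[wi]] <- data.frame(ward_id = sprintf("W%02d", wi), month = months,
                            ndvi = ndvi,
                            ndvi_lt_mean = config$ndvi_lt_mean,
                            ndvi_lt_sd = config$ndvi_lt_sd,
                            price = pmax(price, 0.01),
                            price_baseline = config$price_baseline,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate inputs plus model-generated "observed" prevalence
#'
#' Runs the simulation engine at known true parameters on a synthetic
#' household table and stressor series, and emits the resulting ward-month
#' prevalence as the observed table. Because the truth is known, the
#' output supports parameter-recovery, temporal-split and leading-edge
#' experiments without any external data.
#'
#' @param config An [generator_config()] object.
#' @param true_params The [sim_params()] generating the observations. The
#'   default uses a learning rate and spawn rate of 0.05 and a sufficiency
#'   threshold of 0.04 on the normalised per-child food scale (small
#'   enough that a well-matched strategy can feed a large family while a
#'   shocked, mismatched one cannot, see the package vignette), seeded
#'   from `config$seed`.
#' @param catalog Strategy catalog for the simulation.
#' @return A list with `households`, `stressors`, `observed` (prevalence
#'   data.frame) and `true_params`.
#' @export
generate_ground_truth <- function(config,
                                  true_params = NULL,
                                  catalog = strategy_catalog()) {
  stopifnot(inherits(config, "amews_generator_config"))
  if (is.null(true_params)) {
    true_params <- sim_params(lambda = 0.05, spawn_rate = 0.05, n_0 = 0.04,
                              seed = config$seed + 2L)
  }
  households <- generate_households(config)
  stressors <- generate_stressors(config)
  observed <- simulate_run(households, stressors, true_params,
                           catalog = catalog)
  list(households = households, stressors = stressors,
       observed = observed, true_params = true_params)
}
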