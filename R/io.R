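`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- schema validation ---------------------------------------------------

fail_rows <- function(col, rows, why) {
  stop("column '", col, "' ", why, " (row", if (length(rows) > 1L) "s",
       " ", paste(utils::head(rows, 10L), collapse = ", "),
       if (length(rows) > 10L) ", ...", ")", call. = FALSE)
}

check_range <- function(df, col, lo, hi) {
  v <- df[[col]]
  if (!is.numeric(v)) stop("column '", col, "' must be numeric",
                           call. = FALSE)
  bad <- which(is.na(v) | v < lo | v > hi)
  if (length(bad)) {
    fail_rows(col, bad, sprintf("out of range [%g, %g]", lo, hi))
  }
}

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

month_ok <- function(m) grepl("^[0-9]{4}-[0-9]{2}$", m)

#' @rdname read_households_csv
#' @param households A household data.frame to validate in place.
#' @export
validate_households <- function(households) {
  check_cols(households, c("id", "ward_id", "cap_own", "cap_network",
                           "cap_market", "h_p", "h_a", "n_children"),
             "household table")
  if (nrow(households) == 0L) stop("household table is empty", call. = FALSE)
  for (col in c("cap_own", "cap_network", "cap_market", "h_p", "h_a")) {
    check_range(households, col, 0, 1)
  }
  nc <- households$n_children
  bad <- which(is.na(nc) | nc < 1 | nc != round(nc))
  if (length(bad)) fail_rows("n_children", bad, "must be a positive integer")
  dup <- which(duplicated(households$id))
  if (length(dup)) fail_rows("id", dup, "is duplicated")
  invisible(households)
}

#' @rdname read_stressors_csv
#' @param stressors A stressor data.frame to validate in place.
#' @export
validate_stressors <- function(stressors) {
  check_cols(stressors, c("ward_id", "month", "ndvi", "ndvi_lt_mean",
                          "ndvi_lt_sd", "price", "price_baseline"),
             "stressor table")
  if (nrow(stressors) == 0L) stop("stressor table is empty", call. = FALSE)
  bad <- which(!month_ok(stressors$month))
  if (length(bad)) fail_rows("month", bad, "must be ISO YYYY-MM")
  dup <- which(duplicated(paste(stressors$ward_id, stressors$month)))
  if (length(dup)) fail_rows("(ward_id, month)", dup, "is duplicated")
  if (any(!is.finite(stressors$ndvi))) {
    fail_rows("ndvi", which(!is.finite(stressors$ndvi)), "must be finite")
  }
  if (any(stressors$ndvi_lt_sd <= 0)) {
    fail_rows("ndvi_lt_sd", which(stressors$ndvi_lt_sd <= 0),
              "must be positive")
  }
  if (any(stressors$price < 0)) {
    fail_rows("price", which(stressors$price < 0), "must be >= 0")
  }
  if (any(stressors$price_baseline <= 0)) {
    fail_rows("price_baseline", which(stressors$price_baseline <= 0),
              "must be positive")
  }
  # long-term baselines are a property of the ward, not the month
  for (col in c("ndvi_lt_mean", "ndvi_lt_sd", "price_baseline")) {
    nvar <- tapply(stressors[[col]], stressors$ward_id,
                   function(v) length(unique(v)))
    if (any(nvar > 1L)) {
      stop("column '", col, "' must be constant within each ward",
           call. = FALSE)
    }
  }
  invisible(stressors)
}

#' @rdname read_prevalence_csv
#' @param prevalence A prevalence data.frame to validate in place.
#' @export
validate_prevalence <- function(prevalence) {
  check_cols(prevalence, c("ward_id", "month", "prevalence_pct"),
             "prevalence table")
  if (nrow(prevalence) == 0L) stop("prevalence table is empty", call. = FALSE)
  bad <- which(!month_ok(prevalence$month))
  if (length(bad)) fail_rows("month", bad, "must be ISO YYYY-MM")
  check_range(prevalence, "prevalence_pct", 0, 100)
  dup <- which(duplicated(paste(prevalence$ward_id, prevalence$month)))
  if (length(dup)) fail_rows("(ward_id, month)", dup, "is duplicated")
  invisible(prevalence)
}

## ---- readers / writers ---------------------------------------------------

read_amews_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df
}

#' Read and validate a households table
#'
#' Columns: `id`, `ward_id`, `x`, `y`, `cap_own`, `cap_network`,
#' `cap_market` (capabilities in `[0,1]` per dimension), `h_p`, `h_a`
#' (health and asset factors in `[0,1]`), `n_children` (positive integer),
#' optionally `livelihood_zone`. UTF-8, `.` decimal separator; lines
#' starting with `#` are ignored. Violations are reported with the
#' offending column and row numbers.
#'
#' @param path CSV file path.
#' @return A validated data.frame.
#' @export
read_households_csv <- function(path) {
  df <- read_amews_csv(path)
  df$ward_id <- as.character(df$ward_id)
  df$id <- as.character(df$id)
  validate_households(df)
  df
}

#' Read and validate a stressor table
#'
#' Columns: `ward_id`, `month` (ISO `YYYY-MM`), `ndvi`, `ndvi_lt_mean`,
#' `ndvi_lt_sd`, `price`, `price_baseline`. One row per ward-month;
#' long-term baselines must be constant within each ward.
#'
#' @param path CSV file path.
#' @return A validated data.frame.
#' @export
read_stressors_csv <- function(path) {
  df <- read_amews_csv(path)
  df$ward_id <- as.character(df$ward_id)
  df$month <- as.character(df$month)
  validate_stressors(df)
  df
}

#' Read and validate a ward-month prevalence table
#'
#' Columns: `ward_id`, `month` (ISO `YYYY-MM`), `prevalence_pct` in
#' `[0, 100]`, optionally `ipc_phase`.
#'
#' @param path CSV file path.
#' @return A validated data.frame.
#' @export
read_prevalence_csv <- function(path) {
  df <- read_amews_csv(path)
  df$ward_id <- as.character(df$ward_id)
  df$month <- as.character(df$month)
  validate_prevalence(df)
  df
}

#' Write a table as an annotated CSV
#'
#' Writes the table with a `#`-prefixed header comment carrying the seed
#' and configuration hash of the producing run, so every numeric output
#' can be traced back to its manifest. The readers skip such comments.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed,config_hash Provenance recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_amews_csv <- function(df, path, seed = NA, config_hash = NA) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# amews %s seed=%s config=%s",
                     as.character(utils::packageVersion("amews")),
                     seed, config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

## ---- config --------------------------------------------------------------

#' Default configuration
#'
#' The YAML-serialisable configuration tree: `model` (behavioural
#' parameters), `catalog` (strategy grid), `stressors` (deviation-to-
#' factor conversion), `run` (months, seed, replicates) and `generator`
#' (synthetic-data settings).
#'
#' @return A nested list.
#' @export
default_config <- function() {
  list(model = list(lambda = 0.05, spawn_rate = 0.05, n_0 = 0.5, K = 2,
                    neighborhood_k = 8, epsilon = 0.05, ema_alpha = 0.3,
                    memory_prior = 0, max_size = 8, spawn_scale = 0.1),
       catalog = list(grid_step = 0.25),
       stressors = list(beta_c = 0.25, beta_m = 0.5,
                        floor_c = 0.1, floor_m = 0.1),
       run = list(months = 24, seed = 1, replicates = 20, burn_in = 6),
       generator = list(n_wards = 5, sites_per_ward = 1,
                        households_per_site = 30, months = 24,
                        start_month = "2017-01"))
}

#' Read a YAML configuration, filling unset values with the defaults
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  for (sec in names(user)) {
    if (is.list(user[[sec]]) && sec %in% names(cfg)) {
      for (k in names(user[[sec]])) cfg[[sec]][[k]] <- user[[sec]][[k]]
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  cfg
}

config_params <- function(cfg, seed = NULL) {
  m <- cfg$model
  sim_params(lambda = m$lambda, spawn_rate = m$spawn_rate, n_0 = m$n_0,
             K = m$K, neighborhood_k = m$neighborhood_k,
             epsilon = m$epsilon, ema_alpha = m$ema_alpha,
             memory_prior = m$memory_prior, max_size = m$max_size,
             spawn_scale = m$spawn_scale,
             seed = seed %||% cfg$run$seed)
}

config_spar <- function(cfg) {
  s <- cfg$stressors
  stressor_params(beta_c = s$beta_c, beta_m = s$beta_m,
                  floor_c = s$floor_c, floor_m = s$floor_m)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run exactly: package version,
#' seed, configuration hash, input-file checksums and a timestamp.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed of the run.
#' @param config Configuration list.
#' @param input_files Character vector of input file paths.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, seed, config,
                           input_files = character(0)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(package = "amews",
              version = as.character(utils::packageVersion("amews")),
              seed = seed,
              config_hash = config_hash(config),
              input_checksums = as.list(tools::md5sum(input_files)),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
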