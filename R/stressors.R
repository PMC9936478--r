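#' Stressor-to-factor conversion parameters
#'
#' Controls how raw climate (NDVI) and market (staple price) series are
#' converted into per-dimension multiplicative effectiveness factors.
#' Climate maps to the own-production dimension and the market stressor to
#' the buy/barter dimension by default; the local-networks dimension
#' carries no exogenous stressor.
#'
#' @param beta_c Climate sensitivity: factor lost per negative NDVI
#'   z-score unit.
#' @param beta_m Market sensitivity: factor lost per unit of positive
#'   relative price deviation.
#' @param floor_c,floor_m Lower bounds on the factors, guarding against a
#'   data artefact annihilating a dimension entirely.
#' @param climate_dim,market_dim Strategy dimension each stressor acts on.
#' @return A list of class `amews_stressor_params`.
#' @export
stressor_params <- function(beta_c = 0.25, beta_m = 0.5,
                            floor_c = 0.1, floor_m = 0.1,
                            climate_dim = "own_production",
                            market_dim = "buy_barter") {
  dims <- c("own_production", "local_networks", "buy_barter")
  stopifnot(beta_c >= 0, beta_m >= 0,
            floor_c > 0, floor_c < 1, floor_m > 0, floor_m < 1,
            climate_dim %in% dims, market_dim %in% dims)
  structure(list(beta_c = beta_c, beta_m = beta_m,
                 floor_c = floor_c, floor_m = floor_m,
                 climate_dim = climate_dim, market_dim = market_dim),
            class = "amews_stressor_params")
}

#' Climate effectiveness factor from an NDVI deviation
#'
#' Below-average greenness (a drought proxy) reduces the effectiveness of
#' own food production linearly in the standardised deviation:
#' `z = (ndvi - mean) / sd`, `factor = clip(1 + beta_c * min(z, 0), floor, 1)`.
#' Above-average greenness never raises the factor beyond 1.
#'
#' @param ndvi Observed monthly NDVI.
#' @param mean,sd Long-term ward-level NDVI mean and standard deviation
#'   (`sd > 0`).
#' @param beta_c Sensitivity per z-unit (>= 0).
#' @param floor Lower bound in `(0, 1)`.
#' @return Factor in `[floor, 1]`. Vectorised over `ndvi`.
#' @examples
#' climate_factor(0.3, mean = 0.5, sd = 0.1, beta_c = 0.25)  # z = -2 -> 0.5
#' @export
climate_factor <- function(ndvi, mean, sd, beta_c = 0.25, floor = 0.1) {
  if (any(!is.finite(ndvi)) || any(!is.finite(mean)) || any(!is.finite(sd))) {
    stop("non-finite NDVI inputs", call. = FALSE)
  }
  if (any(sd <= 0)) stop("sd must be positive", call. = FALSE)
  z <- (ndvi - mean) / sd
  pmin(pmax(1 + beta_c * pmin(z, 0), floor), 1)
}

#' Market effectiveness factor from a staple-price deviation
#'
#' Prices above the long-term baseline reduce the effectiveness of the
#' buy/barter dimension linearly in the relative deviation:
#' `r = (price - baseline) / baseline`,
#' `factor = clip(1 - beta_m * max(r, 0), floor, 1)`. Prices below baseline
#' never raise the factor beyond 1.
#'
#' @param price Observed monthly price (currency per 100 g staple, >= 0).
#' @param baseline Long-term (10-year) average price (> 0).
#' @param beta_m Sensitivity per unit relative deviation (>= 0).
#' @param floor Lower bound in `(0, 1)`.
#' @return Factor in `[floor, 1]`. Vectorised over `price`.
#' @examples
#' market_factor(10, baseline = 5, beta_m = 0.5)  # price doubled -> 0.5
#' @export
market_factor <- function(price, baseline, beta_m = 0.5, floor = 0.1) {
  if (any(price < 0)) stop("price must be >= 0", call. = FALSE)
  if (any(baseline <= 0)) stop("baseline must be positive", call. = FALSE)
  r <- (price - baseline) / baseline
  pmin(pmax(1 - beta_m * pmax(r, 0), floor), 1)
}

#' Apply a multiplicative shock to one strategy dimension
#'
#' Reduces the effectiveness of a single dimension by a given factor -- the
#' smaller the factor, the greater the impact: factor 0.2 reduces the
#' dimension's effectiveness by 80%. Other dimensions are untouched; the
#' operation composes multiplicatively.
#'
#' @param x Numeric 3-vector of effectiveness factors.
#' @param dimension One of `"own_production"`, `"local_networks"`,
#'   `"buy_barter"`.
#' @param factor Shock factor in `(0, 1]`.
#' @return The shocked 3-vector.
#' @examples
#' apply_shock(c(1, 1, 1), "own_production", 0.2)  # c(0.2, 1, 1)
#' @export
apply_shock <- function(x, dimension, factor) {
  dims <- c("own_production", "local_networks", "buy_barter")
  if (!dimension %in% dims) {
    stop("unknown dimension '", dimension, "'", call. = FALSE)
  }
  if (factor <= 0 || factor > 1) {
    stop("shock factor must lie in (0, 1]", call. = FALSE)
  }
  d <- match(dimension, dims)
  x[d] <- x[d] * factor
  x
}

#' Effectiveness factors for every ward-month
#'
#' Converts a stressor table into per-dimension effectiveness factors:
#' climate acts on `climate_dim`, the market stressor on `market_dim`, and
#' the remaining dimension stays at 1.
#'
#' @param stressors Stressor table with columns `ward_id`, `month`, `ndvi`,
#'   `ndvi_lt_mean`, `ndvi_lt_sd`, `price`, `price_baseline`.
#' @param spar A [stressor_params()] object.
#' @return A data.frame `ward_id`, `month`, `x_own`, `x_net`, `x_buy`.
#' @export
stressor_factors <- function(stressors, spar = stressor_params()) {
  validate_stressors(stressors)
  cf <- climate_factor(stressors$ndvi, stressors$ndvi_lt_mean,
                       stressors$ndvi_lt_sd, spar$beta_c, spar$floor_c)
  mf <- market_factor(stressors$price, stressors$price_baseline,
                      spar$beta_m, spar$floor_m)
  dims <- c("own_production", "local_networks", "buy_barter")
  xm <- matrix(1, nrow(stressors), 3L,
               dimnames = list(NULL, c("x_own", "x_net", "x_buy")))
  xm[, match(spar$climate_dim, dims)] <- cf
  xm[, match(spar$market_dim, dims)] <-
    xm[, match(spar$market_dim, dims)] * mf
  data.frame(ward_id = as.character(stressors$ward_id),
             month = as.character(stressors$month), xm,
             stringsAsFactors = FALSE)
}
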