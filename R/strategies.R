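#' Livelihood strategy vectors
#'
#' A livelihood strategy is a length-3 vector of reliance weights over the
#' three food-access dimensions -- own food production, local networks, and
#' buy/barter -- that sums to one. `(1, 0, 0)` is a strategy entirely reliant
#' on own food production.
#'
#' @param own_production,local_networks,buy_barter Non-negative reliance
#'   weights; they must sum to 1 (tolerance `1e-9`).
#' @return A named numeric vector of class `amews_strategy`.
#' @examples
#' strategy(1, 0, 0)
#' strategy(0.5, 0.25, 0.25)
#' @export
strategy <- function(own_production, local_networks, buy_barter) {
  s <- c(own_production = own_production,
         local_networks = local_networks,
         buy_barter = buy_barter)
  validate_strategy(s)
  class(s) <- "amews_strategy"
  s
}

#' @rdname strategy
#' @param s A numeric 3-vector.
#' @export
validate_strategy <- function(s) {
  if (length(s) != 3L || !is.numeric(s) || anyNA(s)) {
    stop("a strategy must be a numeric 3-vector", call. = FALSE)
  }
  if (any(s < 0)) stop("strategy weights must be non-negative", call. = FALSE)
  if (abs(sum(s) - 1) > 1e-9) {
    stop("strategy weights must sum to 1 (got ", format(sum(s)), ")",
         call. = FALSE)
  }
  invisible(s)
}

#' Simplex grid catalog of livelihood strategies
#'
#' Enumerates all strategies on a regular grid of the 2-simplex with the
#' given step, i.e. all 3-vectors with components in `{0, step, 2*step, ...}`
#' summing to one. The default step of 0.25 gives 15 strategies. A livelihood
#' zone mask can drop combinations that are implausible in a given local
#' context (e.g. high own-production weights in purely pastoral drylands
#' where cultivation is not an option).
#'
#' @param grid_step Grid resolution; must divide 1 into an integer number of
#'   steps (default 0.25).
#' @param zone_mask Optional logical vector (length = catalog size) or a
#'   predicate `function(s)` returning `TRUE` for strategies to keep.
#' @return A numeric matrix, one strategy per row, columns
#'   `own_production`, `local_networks`, `buy_barter`.
#' @examples
#' nrow(strategy_catalog())          # 15
#' nrow(strategy_catalog(0.5))       # 6
#' # drop strategies relying mostly on own production:
#' strategy_catalog(zone_mask = function(s) s[1] <= 0.5)
#' @export
strategy_catalog <- function(grid_step = 0.25, zone_mask = NULL) {
  n <- round(1 / grid_step)
  if (abs(n * grid_step - 1) > 1e-9 || n < 1) {
    stop("grid_step must evenly divide 1", call. = FALSE)
  }
  grid <- expand.grid(i = 0:n, j = 0:n)
  grid <- grid[grid$i + grid$j <= n, ]
  cat_m <- cbind(own_production = grid$i / n,
                 local_networks = grid$j / n,
                 buy_barter = (n - grid$i - grid$j) / n)
  cat_m <- cat_m[order(-cat_m[, 1], -cat_m[, 2]), , drop = FALSE]
  if (!is.null(zone_mask)) {
    keep <- if (is.function(zone_mask)) {
      apply(cat_m, 1L, zone_mask)
    } else {
      zone_mask
    }
    if (length(keep) != nrow(cat_m) || !is.logical(keep)) {
      stop("zone_mask must be a predicate or logical of catalog length",
           call. = FALSE)
    }
    cat_m <- cat_m[keep, , drop = FALSE]
  }
  if (nrow(cat_m) == 0L) stop("zone mask removed every strategy", call. = FALSE)
  rownames(cat_m) <- NULL
  cat_m
}

validate_catalog <- function(catalog) {
  if (!is.matrix(catalog) || ncol(catalog) != 3L || nrow(catalog) == 0L) {
    stop("catalog must be a non-empty matrix with 3 columns", call. = FALSE)
  }
  apply(catalog, 1L, validate_strategy)
  invisible(catalog)
}

# component-wise duplicate check at tolerance 1e-9
strategy_in_set <- function(s, set_m, tol = 1e-9) {
  if (nrow(set_m) == 0L) return(0L)
  d <- abs(sweep(set_m, 2L, as.numeric(s)))
  hit <- which(apply(d, 1L, max) <= tol)
  if (length(hit)) hit[1L] else 0L
}
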