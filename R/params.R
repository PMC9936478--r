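#' Simulation parameters
#'
#' Bundles the behavioural and numerical parameters of the household model.
#'
#' @param lambda Household learning rate: the per-round probability that a
#'   nutritionally insufficient household imitates the best-performing
#'   strategy among its geographic neighbours (hill climbing). Calibration
#'   box `[0.01, 0.1]`.
#' @param spawn_rate Per-round probability that an insufficient household
#'   generates a novel (mutated) strategy. Box `[0.01, 0.1]`.
#' @param learning_mode Only `"hill_climbing"` is implemented.
#' @param n_0 Global nutritional sufficiency threshold on the normalised
#'   food-per-child scale (a fully capable, unshocked single-child household
#'   on any pure strategy attains 1.0). A household with realised
#'   nutrition `n_s < n_0` is insufficient this round.
#' @param K Persistence window: a household is acutely malnourished when it
#'   has been insufficient for `K` consecutive rounds.
#' @param neighborhood_k Number of nearest same-ward households (planar
#'   distance) that form the social neighbourhood used for imitation.
#' @param epsilon Selection floor: strategies are selected with probability
#'   proportional to `memory + epsilon * mean(memory)`, so no strategy's
#'   selection probability collapses entirely to zero.
#' @param ema_alpha Smoothing weight of the exponential moving average that
#'   tracks each strategy's realised performance.
#' @param memory_prior Initial performance memory common to every strategy.
#'   The default 0 means untried strategies are explored only through the
#'   selection floor; an all-zero memory falls back to uniform selection.
#' @param max_size Cap on a household's strategy-set size. When the cap is
#'   exceeded the lowest-memory strategy is evicted.
#' @param spawn_scale Standard deviation of the symmetric perturbation used
#'   to mutate the active strategy when spawning (weights are truncated at 0
#'   and renormalised).
#' @param seed Integer seed for the single global RNG stream.
#' @return A list of class `amews_params`.
#' @examples
#' p <- sim_params(lambda = 0.05, seed = 1)
#' p$lambda
#' @export
sim_params <- function(lambda = 0.05,
                       spawn_rate = 0.05,
                       learning_mode = "hill_climbing",
                       n_0 = 0.5,
                       K = 2L,
                       neighborhood_k = 8L,
                       epsilon = 0.05,
                       ema_alpha = 0.3,
                       memory_prior = 0,
                       max_size = 8L,
                       spawn_scale = 0.1,
                       seed = 1L) {
  p <- list(lambda = lambda, spawn_rate = spawn_rate,
            learning_mode = learning_mode, n_0 = n_0, K = as.integer(K),
            neighborhood_k = as.integer(neighborhood_k), epsilon = epsilon,
            ema_alpha = ema_alpha, memory_prior = memory_prior,
            max_size = as.integer(max_size), spawn_scale = spawn_scale,
            seed = as.integer(seed))
  validate_params(p)
  class(p) <- "amews_params"
  p
}

validate_params <- function(p) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(p$lambda >= 0 && p$lambda <= 1, "lambda must be in [0, 1]")
  chk(p$spawn_rate >= 0 && p$spawn_rate <= 1, "spawn_rate must be in [0, 1]")
  chk(identical(p$learning_mode, "hill_climbing"),
      "learning_mode must be 'hill_climbing'")
  chk(p$n_0 > 0, "n_0 must be positive")
  chk(p$K >= 1L, "K must be >= 1")
  chk(p$neighborhood_k >= 0L, "neighborhood_k must be >= 0")
  chk(p$epsilon >= 0 && p$epsilon < 1, "epsilon must be in [0, 1)")
  chk(p$ema_alpha > 0 && p$ema_alpha <= 1, "ema_alpha must be in (0, 1]")
  chk(p$memory_prior >= 0, "memory_prior must be >= 0")
  chk(p$max_size >= 1L, "max_size must be >= 1")
  chk(p$spawn_scale > 0, "spawn_scale must be positive")
  invisible(p)
}

#' @export
print.amews_params <- function(x, ...) {
  cat("<amews_params>\n")
  cat(sprintf("  lambda=%.4g spawn_rate=%.4g mode=%s\n",
              x$lambda, x$spawn_rate, x$learning_mode))
  cat(sprintf("  n_0=%.3g K=%d neighborhood_k=%d\n",
              x$n_0, x$K, x$neighborhood_k))
  cat(sprintf("  epsilon=%.3g ema_alpha=%.3g memory_prior=%.3g max_size=%d\n",
              x$epsilon, x$ema_alpha, x$memory_prior, x$max_size))
  cat(sprintf("  spawn_scale=%.3g seed=%d\n", x$spawn_scale, x$seed))
  invisible(x)
}

# lambda/spawn outside the calibration box [0.01, 0.1] are legal (scenario
# transforms may leave it); callers that care use this to warn.
in_calibration_box <- function(value) value >= 0.01 && value <= 0.1
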