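#' Default IPC acute-malnutrition phase breakpoints
#'
#' Ascending prevalence breakpoints (percent GAM) separating the five IPC
#' acute-malnutrition phases. The defaults follow the published IPC AMN
#' bands: phase 1 below 5%, then 5-10, 10-15, 15-30, and 30%+ (phase 5).
#' Any four strictly increasing breakpoints can be supplied to match a
#' local dialect of the scale.
#'
#' @return Numeric vector of 4 breakpoints.
#' @export
ipc_default_thresholds <- function() c(5, 10, 15, 30)

#' Map prevalence to an IPC acute-malnutrition phase
#'
#' `phase = 1 + number of breakpoints <= W`, i.e. prevalence exactly on a
#' breakpoint falls in the higher phase.
#'
#' @param W Prevalence in percent, in `[0, 100]`.
#' @param thresholds Four strictly increasing breakpoints (percent).
#' @return Integer phase in 1..5.
#' @examples
#' prevalence_to_ipc(0)   # 1
#' prevalence_to_ipc(12)  # 3
#' prevalence_to_ipc(35)  # 5
#' @export
prevalence_to_ipc <- function(W, thresholds = ipc_default_thresholds()) {
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0)) {
    stop("thresholds must be 4 strictly increasing breakpoints",
         call. = FALSE)
  }
  if (any(W < 0 | W > 100)) {
    stop("prevalence must lie in [0, 100]", call. = FALSE)
  }
  as.integer(1L + vapply(W, function(w) sum(thresholds <= w), numeric(1)))
}

#' Hamming loss of a categorical prediction
#'
#' The fraction of units whose predicted phase differs from the observed
#' phase: one incorrect classification in four sites gives 0.25.
#'
#' @param observed,predicted Equal-length vectors of phases.
#' @return Scalar in `[0, 1]`.
#' @export
hamming_loss <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0L) {
    stop("observed and predicted must have equal positive length",
         call. = FALSE)
  }
  mean(observed != predicted)
}

#' Macro F1 score over IPC phases
#'
#' The unweighted mean over classes of the per-class F1 score (the balanced
#' mean of precision and recall). Classes present in either the observed or
#' the predicted vector enter the mean; a class with `precision + recall =
#' 0` (no true positives) contributes an F1 of 0; classes absent from both
#' vectors are excluded.
#'
#' @param observed,predicted Equal-length vectors of phases.
#' @return Scalar in `[0, 1]`.
#' @examples
#' macro_f1(c(1, 1, 2, 2), c(1, 2, 2, 2))  # 0.7333...
#' @export
macro_f1 <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0L) {
    stop("observed and predicted must have equal positive length",
         call. = FALSE)
  }
  classes <- sort(unique(c(observed, predicted)))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(observed == cl & predicted == cl)
    fp <- sum(observed != cl & predicted == cl)
    fn <- sum(observed == cl & predicted != cl)
    denom <- 2 * tp + fp + fn
    if (denom == 0) 0 else 2 * tp / denom
  }, numeric(1))
  mean(f1)
}

#' Root-mean-square deviation of predicted prevalence
#'
#' Measures systematic bias of the simulated prevalence against the
#' observed series. Computed on the proportion scale (0.10 for 10%), the
#' scale on which the joint-validity cut-off of 0.2 is defined.
#'
#' @param observed,predicted Equal-length numeric vectors of prevalence
#'   proportions in `[0, 1]`.
#' @return Scalar >= 0.
#' @export
rmsd <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0L) {
    stop("observed and predicted must have equal positive length",
         call. = FALSE)
  }
  sqrt(mean((observed - predicted)^2))
}

#' Joint validity rule
#'
#' A prediction is valid when it is both accurate and unbiased: strict
#' `macro F1 > 0.5` (the random-prediction baseline for the imbalanced
#' five-class problem lies between 0.3 and 0.4) and strict `RMSD < 0.2`
#' (proportion scale).
#'
#' @param f1 Macro F1 in `[0, 1]`.
#' @param rmsd RMSD on the proportion scale (>= 0).
#' @param f1_min,rmsd_max The two cut-offs.
#' @return Logical.
#' @examples
#' joint_validity(0.72, 0.01)  # TRUE
#' joint_validity(0.43, 0.03)  # FALSE
#' joint_validity(0.5, 0.2)    # FALSE (strict boundaries)
#' @export
joint_validity <- function(f1, rmsd, f1_min = 0.5, rmsd_max = 0.2) {
  stopifnot(f1 >= 0, f1 <= 1, rmsd >= 0)
  (f1 > f1_min) && (rmsd < rmsd_max)
}

#' Score predicted against observed ward-month prevalence
#'
#' Joins the two tables on (ward, month), classifies both sides on the IPC
#' acute-malnutrition scale, and reports macro F1, Hamming loss, RMSD
#' (proportion scale) and the joint validity verdict.
#'
#' @param observed,predicted Data frames with columns `ward_id`, `month`,
#'   `prevalence_pct`.
#' @param thresholds IPC breakpoints, see [prevalence_to_ipc()].
#' @return An object of class `amews_report`: list with `f1_macro`,
#'   `hamming`, `rmsd`, `valid`, `n`.
#' @export
validation_report <- function(observed, predicted,
                              thresholds = ipc_default_thresholds()) {
  key_o <- paste(observed$ward_id, observed$month)
  key_p <- paste(predicted$ward_id, predicted$month)
  idx <- match(key_o, key_p)
  if (anyNA(idx)) {
    stop("predicted table is missing ", sum(is.na(idx)),
         " observed ward-month(s)", call. = FALSE)
  }
  obs <- observed$prevalence_pct
  pred <- predicted$prevalence_pct[idx]
  obs_ph <- prevalence_to_ipc(obs, thresholds)
  pred_ph <- prevalence_to_ipc(pred, thresholds)
  f1 <- macro_f1(obs_ph, pred_ph)
  rm <- rmsd(obs / 100, pred / 100)
  structure(list(f1_macro = f1,
                 hamming = hamming_loss(obs_ph, pred_ph),
                 rmsd = rm,
                 valid = joint_validity(f1, rm),
                 n = length(obs)),
            class = "amews_report")
}

#' @export
print.amews_report <- function(x, ...) {
  cat("Validation report (", x$n, " ward-months)\n", sep = "")
  cat(sprintf("  macro F1     %.3f   (valid if > 0.5)\n", x$f1_macro))
  cat(sprintf("  Hamming loss %.3f\n", x$hamming))
  cat(sprintf("  RMSD         %.4f  (valid if < 0.2, proportion scale)\n",
              x$rmsd))
  cat("  jointly valid:", if (x$valid) "yes" else "no", "\n")
  invisible(x)
}
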