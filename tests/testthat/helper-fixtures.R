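# Fixture builders and independent oracles shared across test files.

# hand-built household table; all columns of the households.csv schema
make_households <- function(n = 12, wards = c("A", "B"),
                            caps = c(1, 1, 1), h_p = 1, h_a = 1,
                            n_children = 1) {
  data.frame(id = sprintf("h%03d", seq_len(n)),
             ward_id = rep(wards, length.out = n),
             x = rep(seq(0, 1, length.out = ceiling(n / length(wards))),
                     length.out = n),
             y = rep(c(0.2, 0.8), length.out = n),
             cap_own = rep(caps[1], n), cap_network = rep(caps[2], n),
             cap_market = rep(caps[3], n),
             h_p = rep(h_p, length.out = n),
             h_a = rep(h_a, length.out = n),
             n_children = rep(n_children, length.out = n),
             stringsAsFactors = FALSE)
}

# constant-condition stressor series: NDVI pinned at z_dev z-units from the
# long-term mean, price at ratio_dev relative deviation from baseline
make_stressors <- function(months = 6, wards = c("A", "B"),
                           z_dev = 0, ratio_dev = 0,
                           start_month = "2020-01") {
  mos <- format(seq(as.Date(paste0(start_month, "-01")), by = "month",
                    length.out = months), "%Y-%m")
  do.call(rbind, lapply(wards, function(w) {
    data.frame(ward_id = w, month = mos,
               ndvi = 0.45 + z_dev * 0.1, ndvi_lt_mean = 0.45,
               ndvi_lt_sd = 0.1,
               price = 5 * (1 + ratio_dev), price_baseline = 5,
               stringsAsFactors = FALSE)
  }))
}

# brute-force confusion-matrix oracle for the classification metrics,
# written independently of the package implementation
oracle_confusion_metrics <- function(observed, predicted) {
  classes <- sort(unique(c(observed, predicted)))
  per_class_f1 <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    tp <- fp <- fn <- 0
    for (i in seq_along(observed)) {
      if (predicted[i] == cl && observed[i] == cl) tp <- tp + 1
      if (predicted[i] == cl && observed[i] != cl) fp <- fp + 1
      if (predicted[i] != cl && observed[i] == cl) fn <- fn + 1
    }
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    per_class_f1[ci] <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
  }
  mism <- 0
  for (i in seq_along(observed)) {
    if (observed[i] != predicted[i]) mism <- mism + 1
  }
  list(macro_f1 = mean(per_class_f1),
       hamming = mism / length(observed))
}

# child-roster prevalence oracle: enumerate every child explicitly
oracle_prevalence <- function(children, malnourished) {
  roster <- rep(malnourished, times = children)
  100 * sum(roster) / length(roster)
}

default_inputs <- function(gt) {
  list(households = gt$households, stressors = gt$stressors)
}
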