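# Independent oracles used across test files.

# Brute-force AUC: average concordance over all (complete, incomplete) pairs
# of score = -HL, half credit for ties. Deliberately pairwise, never via the
# package's ROC path.
brute_force_auc <- function(half_lives, labels) {
  pos <- half_lives[labels == "complete"]
  neg <- half_lives[labels == "incomplete"]
  total <- 0
  for (a in pos) {
    for (b in neg) {
      total <- total + if (a < b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Hand product-limit estimator (no censoring handling subtleties needed when
# all censoring follows the last event).
brute_force_km <- function(time, event, t_eval) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  for (tt in ut[ut <= t_eval]) {
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# Fresh scratch directory under the session temp dir.
withr_like_tempdir <- function() {
  dir <- tempfile("dcpk-test-")
  dir.create(dir)
  dir
}

# Small helper building a marker series data frame for re-elevation tests.
series_df <- function(d1, d7 = NA, d30 = NA) {
  data.frame(nominal_day = c("D1", "D7", "D30"), value = c(d1, d7, d30))
}
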