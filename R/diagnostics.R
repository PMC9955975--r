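#' Dichotomize half-lives at a clinical cutoff
#'
#' A half-life strictly below the cutoff is "short" (the test-positive state,
#' predicting complete ablation); at or above the cutoff, including a
#' non-declining marker's `Inf`, it is "long".
#'
#' @param half_life_h Positive half-lives in hours; `Inf` allowed, `NA`
#'   propagates.
#' @param cutoff_h Positive cutoff in hours; default 48, the clinical
#'   dichotomization for first-day DCP half-lives.
#' @return Factor with levels `short`, `long`.
#' @examples
#' dichotomize(c(27.28, 54.6, 48, Inf))
#' @export
dichotomize <- function(half_life_h, cutoff_h = 48) {
  half_life_h <- as.numeric(half_life_h)
  if (!is.numeric(cutoff_h) || length(cutoff_h) != 1L || !is.finite(cutoff_h) ||
      cutoff_h <= 0) {
    stop("`cutoff_h` must be a single positive number", call. = FALSE)
  }
  if (any(!is.na(half_life_h) & half_life_h <= 0)) {
    stop("half-lives must be positive", call. = FALSE)
  }
  factor(ifelse(half_life_h < cutoff_h, "short", "long"),
         levels = c("short", "long"))
}

#' Cross-classify predicted half-life group against radiological response
#'
#' Builds the 2x2 confusion matrix with "short" half-life as test-positive
#' and complete radiological response as condition-positive: `tp` counts
#' short-and-complete, `fp` short-and-incomplete, `fn` long-and-complete,
#' `tn` long-and-incomplete.
#'
#' @param predicted Vector of `"short"`/`"long"` labels (or a factor from
#'   [dichotomize()]).
#' @param observed Vector of `"complete"`/`"incomplete"` response labels.
#' @return A list of class `confusion_matrix` with integer fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @examples
#' build_confusion(c("short", "short", "long"),
#'                 c("complete", "incomplete", "incomplete"))
#' @export
build_confusion <- function(predicted, observed) {
  predicted <- as.character(predicted)
  observed <- as.character(observed)
  if (length(predicted) == 0L) {
    stop("cannot build a confusion matrix from empty inputs", call. = FALSE)
  }
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must have the same length", call. = FALSE)
  }
  if (any(is.na(predicted)) || any(is.na(observed))) {
    stop("labels must not be missing", call. = FALSE)
  }
  if (!all(predicted %in% c("short", "long"))) {
    stop("`predicted` labels must be 'short' or 'long'", call. = FALSE)
  }
  if (!all(observed %in% c("complete", "incomplete"))) {
    stop("`observed` labels must be 'complete' or 'incomplete'", call. = FALSE)
  }
  structure(
    list(tp = sum(predicted == "short" & observed == "complete"),
         fp = sum(predicted == "short" & observed == "incomplete"),
         fn = sum(predicted == "long" & observed == "complete"),
         tn = sum(predicted == "long" & observed == "incomplete")),
    class = "confusion_matrix"
  )
}

#' @rdname build_confusion
#' @param tp,fp,fn,tn Nonnegative integer counts.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion-matrix counts must be nonnegative integers", call. = FALSE)
  }
  structure(setNames(as.list(as.integer(counts)), names(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(c("short HL", "long HL"),
                              c("complete", "incomplete")))
  print(m)
  invisible(x)
}

# Wilson score interval for a binomial proportion (no continuity correction).
wilson_ci <- function(x, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  c((centre - half) / denom, (centre + half) / denom)
}

#' Diagnostic accuracy metrics from a confusion matrix
#'
#' Sensitivity, specificity, accuracy, positive and negative predictive value
#' as proportions with Wilson-score confidence intervals. A metric whose
#' denominator is zero is undefined and reported as `NA`, never as 0.
#'
#' @param cm A `confusion_matrix` (from [build_confusion()] or
#'   [confusion_matrix()]).
#' @param conf_level Confidence level for the Wilson intervals; default 0.95.
#' @return A data frame with one row per metric: `metric`, `estimate`,
#'   `ci_low`, `ci_high`, `numerator`, `denominator`.
#' @examples
#' diagnostic_metrics(confusion_matrix(34, 2, 9, 18))
#' @export
diagnostic_metrics <- function(cm, conf_level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0) stop("confusion matrix is empty", call. = FALSE)
  rows <- list(
    sensitivity = c(cm$tp, cm$tp + cm$fn),
    specificity = c(cm$tn, cm$tn + cm$fp),
    accuracy    = c(cm$tp + cm$tn, total),
    ppv         = c(cm$tp, cm$tp + cm$fp),
    npv         = c(cm$tn, cm$tn + cm$fn)
  )
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    num <- rows[[nm]][1L]
    den <- rows[[nm]][2L]
    est <- if (den > 0) num / den else NA_real_
    ci <- if (den > 0) wilson_ci(num, den, conf_level) else c(NA_real_, NA_real_)
    data.frame(metric = nm, estimate = est, ci_low = ci[1L], ci_high = ci[2L],
               numerator = num, denominator = den, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# AUC as the Mann-Whitney concordance probability of score = -HL for the
# "complete" class, with half credit for ties. Works with -Inf scores.
auc_concordance <- function(half_lives_h, positive) {
  pos <- half_lives_h[positive]
  neg <- half_lives_h[!positive]
  cmp <- outer(pos, neg, function(a, b) {
    (a < b) + 0.5 * (a == b)   # exact for Inf, incl. ties at Inf
  })
  mean(cmp)
}

#' Empirical ROC analysis of half-lives against radiological response
#'
#' Treats shorter half-life as more indicative of complete response
#' (score = -HL), sweeps candidate cutoffs at the midpoints between adjacent
#' distinct observed half-lives (plus one below and one above the observed
#' range), and selects the cutoff maximizing Youden's J = sensitivity +
#' specificity - 1, breaking ties toward higher specificity (the lower
#' cutoff). The AUC is the Mann-Whitney concordance probability, with half
#' credit for ties; non-declining markers enter as the lowest possible score.
#'
#' @param half_lives_h Positive half-lives (hours); `Inf` allowed.
#' @param observed `"complete"`/`"incomplete"` response labels.
#' @return A list of class `roc_result`: `table` (data frame of `cutoff_h`,
#'   `sensitivity`, `specificity`, `youden_j`), `auc`, `optimal_cutoff_h`,
#'   `youden_j`, `n_complete`, `n_incomplete`.
#' @examples
#' roc_analysis(c(20, 30, 90, 100),
#'              c("complete", "complete", "incomplete", "incomplete"))
#' @export
roc_analysis <- function(half_lives_h, observed) {
  half_lives_h <- as.numeric(half_lives_h)
  observed <- as.character(observed)
  stopifnot(length(half_lives_h) == length(observed))
  if (any(is.na(half_lives_h)) || any(is.na(observed))) {
    stop("inputs must not be missing", call. = FALSE)
  }
  if (any(half_lives_h <= 0)) {
    stop("half-lives must be positive", call. = FALSE)
  }
  if (!all(observed %in% c("complete", "incomplete"))) {
    stop("`observed` labels must be 'complete' or 'incomplete'", call. = FALSE)
  }
  positive <- observed == "complete"
  if (!any(positive) || all(positive)) {
    stop("ROC analysis needs at least one complete and one incomplete case",
         call. = FALSE)
  }

  finite <- sort(unique(half_lives_h[is.finite(half_lives_h)]))
  cutoffs <- numeric(0)
  if (length(finite) > 0) {
    if (length(finite) > 1) {
      cutoffs <- (finite[-1] + finite[-length(finite)]) / 2
    }
    cutoffs <- c(finite[1L] / 2, cutoffs, finite[length(finite)] * 2)
  }
  if (any(is.infinite(half_lives_h)) || length(cutoffs) == 0) {
    cutoffs <- c(cutoffs, Inf)
  }

  tab <- do.call(rbind, lapply(cutoffs, function(cut) {
    short <- half_lives_h < cut
    data.frame(
      cutoff_h = cut,
      sensitivity = sum(short & positive) / sum(positive),
      specificity = sum(!short & !positive) / sum(!positive)
    )
  }))
  tab$youden_j <- tab$sensitivity + tab$specificity - 1
  # ties toward higher specificity, i.e. the lowest qualifying cutoff
  best <- which(tab$youden_j == max(tab$youden_j))
  best <- best[which.max(tab$specificity[best])]

  structure(
    list(table = tab,
         auc = auc_concordance(half_lives_h, positive),
         optimal_cutoff_h = tab$cutoff_h[best],
         youden_j = tab$youden_j[best],
         n_complete = sum(positive),
         n_incomplete = sum(!positive)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Empirical ROC: AUC = %.3f over %d complete / %d incomplete\n",
              x$auc, x$n_complete, x$n_incomplete))
  cat(sprintf("Optimal cutoff (Youden) = %.3g h (J = %.3f)\n",
              x$optimal_cutoff_h, x$youden_j))
  invisible(x)
}
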