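#' Kaplan-Meier recurrence-free survival curve
#'
#' Product-limit estimate of recurrence-free survival. Time is measured in
#' months from the end of ablation to first recurrence (event = 1) or
#' censoring (event = 0). When `group` is supplied a separate curve is
#' estimated per group.
#'
#' @param time_months Nonnegative follow-up times.
#' @param event Event indicators (1 = recurrence observed, 0 = censored).
#' @param group Optional grouping vector (e.g. `"short"`/`"long"` half-life).
#' @return A data frame of class `km_curve` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`. The curve starts at
#'   survival 1 before the first event time.
#' @examples
#' km_estimate(c(3, 6, 8, 8), c(1, 1, 0, 0))
#' @export
km_estimate <- function(time_months, event, group = NULL) {
  time_months <- as.numeric(time_months)
  event <- as.integer(event)
  if (length(time_months) == 0L) stop("no survival records", call. = FALSE)
  if (any(is.na(time_months)) || any(is.na(event))) {
    stop("survival times and events must not be missing", call. = FALSE)
  }
  if (any(time_months < 0)) {
    stop("survival times must be nonnegative", call. = FALSE)
  }
  if (!all(event %in% c(0L, 1L))) {
    stop("`event` must be 0/1", call. = FALSE)
  }
  if (is.null(group)) group <- rep("all", length(time_months))
  dat <- data.frame(time = time_months, event = event,
                    group = as.character(group), stringsAsFactors = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  smry <- summary(fit, censored = TRUE)
  grp <- if (is.null(smry$strata)) {
    rep(unique(dat$group), length(smry$time))
  } else {
    sub("^group=", "", as.character(smry$strata))
  }
  out <- data.frame(group = grp, time = smry$time, n_risk = smry$n.risk,
                    n_event = smry$n.event, n_censor = smry$n.censor,
                    survival = smry$surv, stringsAsFactors = FALSE)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability read off a Kaplan-Meier curve
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param t Time (months) at which to evaluate the step function.
#' @param group Group to evaluate; defaults to the only group present.
#' @return The estimated survival probability S(t).
#' @export
km_survival_at <- function(curve, t, group = NULL) {
  stopifnot(inherits(curve, "km_curve"))
  if (is.null(group)) {
    groups <- unique(curve$group)
    if (length(groups) > 1L) {
      stop("curve has several groups; specify `group`", call. = FALSE)
    }
    group <- groups
  }
  sub <- curve[curve$group == group & curve$time <= t, , drop = FALSE]
  if (nrow(sub) == 0L) return(1.0)
  sub$survival[which.max(sub$time)]
}

#' Two-sample log-rank test
#'
#' Compares recurrence-free survival between two groups with the standard
#' log-rank statistic: the squared sum of observed-minus-expected events in
#' one group over event times, divided by its hypergeometric variance, with
#' one degree of freedom.
#'
#' @inheritParams km_estimate
#' @param group Two-level grouping vector; both levels must be present.
#' @return A list of class `logrank_result`: `chi_square`, `df`, `p_value`,
#'   plus per-group observed and expected event counts.
#' @examples
#' logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("a", "a", "b", "b"))
#' @export
logrank_test <- function(time_months, event, group) {
  group <- as.character(group)
  levels <- unique(group)
  if (length(levels) != 2L || any(table(group) == 0L)) {
    stop("log-rank test needs two nonempty groups", call. = FALSE)
  }
  if (sum(event) == 0) {
    stop("log-rank test needs at least one event", call. = FALSE)
  }
  dat <- data.frame(time = as.numeric(time_months), event = as.integer(event),
                    group = group, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  structure(
    list(chi_square = unname(sd$chisq), df = 1L, p_value = p,
         observed = sd$obs, expected = sd$exp),
    class = "logrank_result"
  )
}

#' Cox proportional-hazards regression for recurrence-free survival
#'
#' Fits Cox models by maximizing the partial likelihood with the Efron
#' correction for tied event times. In `"univariate"` mode each covariate is
#' fit alone; in `"multivariate"` mode the covariates whose univariate Wald
#' p-value falls below `entry_p` are fit jointly. Hazard ratios are
#' `exp(beta)` with Wald 95% confidence intervals.
#'
#' @param data A data frame containing `time_months`, `event` and the
#'   covariate columns (numeric; binary indicators coded 0/1).
#' @param covariates Character vector of covariate column names.
#' @param mode `"univariate"`, `"multivariate"` or `"both"` (default).
#' @param entry_p Univariate p-value threshold for entry into the
#'   multivariate model; default 0.05.
#' @param conf_level Confidence level for the Wald intervals.
#' @return A data frame of class `cox_result`: `analysis` (univariate /
#'   multivariate), `term`, `hr`, `ci_low`, `ci_high`, `p_value`,
#'   `converged`.
#' @export
cox_fit <- function(data, covariates,
                    mode = c("both", "univariate", "multivariate"),
                    entry_p = 0.05, conf_level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(data),
            all(c("time_months", "event") %in% names(data)))
  absent <- setdiff(covariates, names(data))
  if (length(absent) > 0) {
    stop("covariates not found in the data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (sum(data$event) < 1) stop("Cox model needs at least one event",
                                call. = FALSE)
  for (cv in covariates) {
    if (!is.numeric(data[[cv]])) {
      stop(sprintf("covariate '%s' must be numeric", cv), call. = FALSE)
    }
    if (length(unique(data[[cv]][!is.na(data[[cv]])])) < 2L) {
      stop(sprintf("covariate '%s' is constant", cv), call. = FALSE)
    }
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  fit_one <- function(terms, label) {
    fml <- stats::as.formula(paste(
      "survival::Surv(time_months, event) ~",
      paste(terms, collapse = " + ")))
    fit <- tryCatch(
      survival::coxph(fml, data = data, ties = "efron"),
      warning = function(w) {
        f <- suppressWarnings(survival::coxph(fml, data = data,
                                              ties = "efron"))
        attr(f, "flagged") <- conditionMessage(w)
        f
      })
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    data.frame(
      analysis = label,
      term = names(beta),
      hr = exp(beta),
      ci_low = exp(beta - z * se),
      ci_high = exp(beta + z * se),
      p_value = 2 * stats::pnorm(-abs(beta / se)),
      converged = is.null(attr(fit, "flagged")),
      stringsAsFactors = FALSE
    )
  }

  uni <- do.call(rbind, lapply(covariates, function(cv) {
    fit_one(cv, "univariate")
  }))
  rownames(uni) <- NULL
  out <- uni
  if (mode %in% c("both", "multivariate")) {
    selected <- uni$term[uni$p_value < entry_p]
    selected <- intersect(covariates, selected)
    if (length(selected) > 0) {
      multi <- fit_one(selected, "multivariate")
      out <- rbind(uni, multi)
    } else if (mode == "multivariate") {
      stop("no covariate passes the univariate entry threshold",
           call. = FALSE)
    }
  }
  if (mode == "multivariate") out <- out[out$analysis == "multivariate", ]
  rownames(out) <- NULL
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Format a p-value in report style
#'
#' Three decimals with a floor of `<0.001`.
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}
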