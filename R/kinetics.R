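#' Configuration for half-life kinetics and eligibility
#'
#' Bundles the constants used by the two-point half-life statistic and the
#' eligibility cascade. DCP concentrations are in mAU/mL throughout; the
#' assay's upper limit of normal is 40 mAU/mL and baseline eligibility
#' requires at least twice that (80 mAU/mL), because a half-life cannot be
#' assessed reliably once the marker has plateaued near the normal range.
#'
#' @param half_life_constant Dimensionless constant of the half-life formula
#'   `HL = constant * delta_t / log10(C0/C1)`. Defaults to the exact
#'   `log10(2) = 0.30103...`; set to `0.3` to reproduce the rounded constant
#'   used in the clinical literature.
#' @param default_interval_h Hours between the baseline (C0) and first-day
#'   (C1) blood draws when a per-patient interval is not recorded. Default
#'   15 h, the typical overnight gap between end of ablation and the
#'   next-morning draw.
#' @param baseline_eligibility_threshold Minimum baseline DCP (mAU/mL) for
#'   half-life analysis; default 80 (twice the upper limit of normal).
#' @param normal_upper_limit Upper limit of the normal DCP range (mAU/mL);
#'   default 40.
#'
#' @return A list of class `kinetics_config`.
#' @examples
#' kinetics_config()
#' kinetics_config(half_life_constant = 0.3)
#' @export
kinetics_config <- function(half_life_constant = log10(2),
                            default_interval_h = 15,
                            baseline_eligibility_threshold = 80,
                            normal_upper_limit = 40) {
  if (!is.numeric(half_life_constant) || length(half_life_constant) != 1L ||
      !is.finite(half_life_constant) ||
      half_life_constant <= 0 || half_life_constant > 0.5) {
    stop("`half_life_constant` must be a single number in (0, 0.5]",
         call. = FALSE)
  }
  if (!is.numeric(default_interval_h) || default_interval_h <= 0) {
    stop("`default_interval_h` must be a positive number of hours",
         call. = FALSE)
  }
  if (normal_upper_limit <= 0 || baseline_eligibility_threshold <= 0) {
    stop("concentration thresholds must be positive", call. = FALSE)
  }
  if (baseline_eligibility_threshold < normal_upper_limit) {
    stop("`baseline_eligibility_threshold` must be >= `normal_upper_limit`",
         call. = FALSE)
  }
  structure(
    list(half_life_constant = half_life_constant,
         default_interval_h = default_interval_h,
         baseline_eligibility_threshold = baseline_eligibility_threshold,
         normal_upper_limit = normal_upper_limit),
    class = "kinetics_config"
  )
}

#' Two-point marker half-life
#'
#' Estimates the serum half-life of a tumor marker from two concentrations
#' bracketing a known interval, assuming first-order (exponential) clearance
#' `N(t) = N0 * (1/2)^(t / t_half)`. Inverting the decay law gives
#' `HL = constant * delta_t_h / log10(c0 / c1)` with `constant = log10(2)`;
#' the rounded constant 0.3 used in clinical reports is available via
#' `constant = 0.3`.
#'
#' A non-declining marker (`c1 >= c0`) has no finite clearance half-life; the
#' result carries `half_life_h = Inf` and status `"non_declining"`, which
#' downstream analyses classify as a long half-life. Missing inputs yield
#' status `"missing_input"` with `NA` half-life.
#'
#' @param c0 Baseline marker concentration(s), drawn before ablation. Must be
#'   positive where not `NA`.
#' @param c1 First-day post-ablation concentration(s). Must be positive where
#'   not `NA`.
#' @param delta_t_h Hours elapsed between the two draws; positive.
#' @param constant Half-life constant; defaults to exact `log10(2)`.
#' @param patient_id Optional identifiers carried into the result.
#'
#' @return A data frame of class `half_life_result` with columns
#'   `patient_id`, `c0`, `c1`, `delta_t_h`, `half_life_h`, `status`
#'   (`"finite"`, `"non_declining"` or `"missing_input"`) and `declination`
#'   (`c0 - c1`).
#' @examples
#' compute_half_life(100, 50, 24)                      # exactly 24 h
#' compute_half_life(177.85, 121.24, 15.13, constant = 0.3)
#' compute_half_life(100, 100, 24)                     # non-declining, Inf
#' @export
compute_half_life <- function(c0, c1, delta_t_h, constant = log10(2),
                              patient_id = NULL) {
  n <- max(length(c0), length(c1), length(delta_t_h))
  c0 <- rep_len(as.numeric(c0), n)
  c1 <- rep_len(as.numeric(c1), n)
  delta_t_h <- rep_len(as.numeric(delta_t_h), n)
  if (!is.numeric(constant) || length(constant) != 1L || constant <= 0) {
    stop("`constant` must be a single positive number", call. = FALSE)
  }
  bad <- function(x) !is.na(x) & x <= 0
  if (any(bad(c0)) || any(bad(c1))) {
    stop("marker concentrations must be positive", call. = FALSE)
  }
  if (any(bad(delta_t_h))) {
    stop("`delta_t_h` must be positive", call. = FALSE)
  }

  missing_in <- is.na(c0) | is.na(c1) | is.na(delta_t_h)
  hl <- rep(NA_real_, n)
  status <- rep("missing_input", n)

  declining <- !missing_in & c1 < c0
  hl[declining] <- constant * delta_t_h[declining] /
    log10(c0[declining] / c1[declining])
  status[declining] <- "finite"

  flat <- !missing_in & c1 >= c0
  hl[flat] <- Inf
  status[flat] <- "non_declining"

  if (is.null(patient_id)) patient_id <- as.character(seq_len(n))
  out <- data.frame(
    patient_id = rep_len(as.character(patient_id), n),
    c0 = c0, c1 = c1, delta_t_h = delta_t_h,
    half_life_h = hl, status = status,
    declination = c0 - c1,
    stringsAsFactors = FALSE
  )
  class(out) <- c("half_life_result", "data.frame")
  out
}

#' Eligibility cascade for half-life analysis
#'
#' Classifies each patient by whether a post-ablation half-life can be
#' assessed from their DCP levels, reproducing the two-stage exclusion used
#' in clinical flow diagrams: patients with a normal baseline
#' (`c0 < normal_upper_limit`) are excluded first; among the remainder,
#' those with a baseline below twice the upper limit of normal
#' (`c0 < baseline_eligibility_threshold`) are excluded because the marker
#' plateaus before a half-life is measurable, as are those whose first-day
#' value has already normalized (`c1 < normal_upper_limit`).
#'
#' Boundary values are eligible: the printed exclusion rules are strict
#' inequalities, so `c0 = 80` and `c1 = 40` pass.
#'
#' @param c0 Baseline DCP (mAU/mL), nonnegative.
#' @param c1 First-day post-ablation DCP (mAU/mL), nonnegative; may be `NA`
#'   when the baseline alone already excludes the patient.
#' @param config A [kinetics_config()].
#'
#' @return Character vector with one status per patient:
#'   `"eligible"`, `"ineligible_normal_baseline"`, `"ineligible_low_baseline"`,
#'   `"ineligible_normalized"` or `"missing_input"`.
#' @examples
#' assess_eligibility(c(39, 79, 150, 80), c(NA, 60, 39, 40))
#' @export
assess_eligibility <- function(c0, c1 = NA_real_, config = kinetics_config()) {
  stopifnot(inherits(config, "kinetics_config"))
  n <- max(length(c0), length(c1))
  c0 <- rep_len(as.numeric(c0), n)
  c1 <- rep_len(as.numeric(c1), n)
  if (any(!is.na(c0) & c0 < 0) || any(!is.na(c1) & c1 < 0)) {
    stop("marker concentrations must be nonnegative", call. = FALSE)
  }
  uln <- config$normal_upper_limit
  thr <- config$baseline_eligibility_threshold

  status <- rep("missing_input", n)
  known0 <- !is.na(c0)
  status[known0 & c0 < uln] <- "ineligible_normal_baseline"
  status[known0 & c0 >= uln & c0 < thr] <- "ineligible_low_baseline"
  high <- known0 & c0 >= thr
  status[high & !is.na(c1) & c1 < uln] <- "ineligible_normalized"
  status[high & !is.na(c1) & c1 >= uln] <- "eligible"
  status
}

#' Marker declination between two draws
#'
#' The signed absolute drop `c0 - c1`; a negative value means the marker rose
#' over the interval. `cohort_declination()` summarizes per-patient
#' declinations as mean and SD, the form in which cohort tables report them.
#'
#' @param c0,c1 Marker concentrations; `NA` propagates.
#' @return Numeric vector of differences.
#' @examples
#' compute_declination(177.85, 121.24)   #  56.61
#' compute_declination(121.24, 151.78)   # -30.54 (a rise)
#' @export
compute_declination <- function(c0, c1) {
  as.numeric(c0) - as.numeric(c1)
}

#' @rdname compute_declination
#' @param x Numeric vector of per-patient declinations.
#' @return For `cohort_declination()`: a named list with `mean`, `sd` and `n`
#'   over non-missing values.
#' @export
cohort_declination <- function(x) {
  x <- x[!is.na(x)]
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' Serial re-elevation of a marker after ablation
#'
#' Flags patients whose DCP rises again during follow-up: any non-missing
#' measurement after day 1 that strictly exceeds the day-1 value. A
#' re-elevation despite a favorable early half-life points to residual tumor.
#' Measurements recorded as lost are skipped, never imputed.
#'
#' @param series A data frame with columns `nominal_day` (one of `"D0"`,
#'   `"D1"`, `"D7"`, `"D30"`) and `value` (concentration, `NA` = lost).
#'   Must contain a non-missing `D1` row.
#'
#' @return A list with `flagged` (logical), `first_reelevation_day`
#'   (`"D7"`, `"D30"` or `NA`) and `reference_value` (the D1 concentration).
#' @examples
#' detect_reelevation(data.frame(
#'   nominal_day = c("D0", "D1", "D7", "D30"),
#'   value = c(177.85, 121.24, 151.78, 355.83)))
#' @export
detect_reelevation <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("nominal_day", "value") %in% names(series)))
  day_order <- c(D0 = 0, D1 = 1, D7 = 7, D30 = 30)
  day <- as.character(series$nominal_day)
  if (!all(day %in% names(day_order))) {
    stop("`nominal_day` must be one of D0, D1, D7, D30", call. = FALSE)
  }
  d1 <- series$value[day == "D1"]
  d1 <- d1[!is.na(d1)]
  if (length(d1) == 0L) {
    stop("re-elevation is not evaluable without a day-1 measurement",
         call. = FALSE)
  }
  ref <- d1[[1L]]
  later <- series[day_order[day] > 1 & !is.na(series$value), , drop = FALSE]
  later <- later[order(day_order[as.character(later$nominal_day)]), ,
                 drop = FALSE]
  above <- later$value > ref
  list(
    flagged = any(above),
    first_reelevation_day = if (any(above)) {
      as.character(later$nominal_day[which(above)[1L]])
    } else {
      NA_character_
    },
    reference_value = ref
  )
}
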