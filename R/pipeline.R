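#' Read and validate a cohort table
#'
#' Reads the one-row-per-patient cohort CSV used throughout the pipeline.
#' Required columns: `patient_id`, `dcp_d0`, `dcp_d1`, `response_1mo`
#' (`complete`/`incomplete`, empty = not assessed), `recurrence_months`,
#' `recurrence_event` (0/1). Optional: `dcp_d7`, `dcp_d30`,
#' `draw_interval_h` (hours between the baseline and day-1 draws),
#' `afp_d0`, `afp_d1` and any numeric covariate columns. Empty cells are
#' missing values.
#'
#' @param path Path to a CSV file.
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = c("", "NA", "Lost"))
  validate_cohort(cohort)
  cohort
}

#' @rdname read_cohort
#' @param cohort A cohort data frame.
#' @return `validate_cohort()` returns the cohort invisibly; schema
#'   violations raise one itemized error.
#' @export
validate_cohort <- function(cohort) {
  problems <- character(0)
  req <- c("patient_id", "dcp_d0", "dcp_d1", "response_1mo",
           "recurrence_months", "recurrence_event")
  miss <- setdiff(req, names(cohort))
  if (length(miss) > 0) {
    problems <- c(problems,
                  paste("missing required columns:",
                        paste(miss, collapse = ", ")))
  } else {
    if (anyDuplicated(cohort$patient_id)) {
      problems <- c(problems, "duplicated patient_id values")
    }
    for (col in intersect(c("dcp_d0", "dcp_d1", "dcp_d7", "dcp_d30",
                            "draw_interval_h", "afp_d0", "afp_d1"),
                          names(cohort))) {
      v <- cohort[[col]]
      if (!is.numeric(v) && !all(is.na(v))) {
        problems <- c(problems, paste0("column '", col, "' must be numeric"))
      } else if (any(!is.na(v) & v < 0)) {
        problems <- c(problems, paste0("column '", col, "' has negative values"))
      }
    }
    resp <- cohort$response_1mo
    if (!all(is.na(resp) | resp %in% c("complete", "incomplete"))) {
      problems <- c(problems,
                    "response_1mo must be 'complete', 'incomplete' or empty")
    }
    ev <- cohort$recurrence_event
    if (!all(is.na(ev) | ev %in% c(0, 1))) {
      problems <- c(problems, "recurrence_event must be 0/1 or empty")
    }
    tm <- cohort$recurrence_months
    if (is.numeric(tm) && any(!is.na(tm) & tm < 0)) {
      problems <- c(problems, "recurrence_months has negative values")
    }
  }
  if (length(problems) > 0) {
    stop("cohort schema validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(cohort)
}

#' Run the full half-life analysis pipeline
#'
#' Orchestrates the analysis from a cohort table: eligibility cascade,
#' two-point half-life estimation, dichotomization at the clinical cutoff,
#' diagnostic accuracy against the 1-month radiological response, empirical
#' ROC, serial re-elevation flags, the discordant-case listing, and
#' recurrence-free-survival stratification (Kaplan-Meier per half-life
#' group, log-rank test, Cox models). The result is deterministic in the
#' input and invariant to row order.
#'
#' @param cohort A cohort data frame (see [read_cohort()]) or a path to a
#'   cohort CSV.
#' @param cutoff_h Half-life dichotomization cutoff in hours; default 48.
#' @param constant Half-life constant; exact `log10(2)` by default, `0.3`
#'   for the rounded clinical convention.
#' @param config A [kinetics_config()]; its `half_life_constant` is
#'   overridden by `constant`.
#' @param covariates Extra numeric covariate columns to include in the Cox
#'   analysis alongside the short-half-life indicator.
#' @param cox_entry_p Univariate p-value threshold for entry into the
#'   multivariate Cox model.
#' @return A list of class `dcp_report`; see Details.
#' @details The report contains: `cascade` (named exclusion counts),
#'   `half_life` (per-patient table for analyzable patients), `confusion`,
#'   `metrics`, `roc`, `reelevation`, `discordant`, `km`, `logrank`, `cox`,
#'   and the `cutoff_h`/`constant` used. Cascade counts are conserved:
#'   every patient lands in exactly one exclusion bin or the analyzable set.
#' @export
run_pipeline <- function(cohort, cutoff_h = 48, constant = log10(2),
                         config = kinetics_config(),
                         covariates = NULL, cox_entry_p = 0.05) {
  if (is.character(cohort) && length(cohort) == 1L) {
    cohort <- read_cohort(cohort)
  }
  validate_cohort(cohort)
  config$half_life_constant <- constant
  cohort <- cohort[order(cohort$patient_id), , drop = FALSE]

  c0 <- cohort$dcp_d0
  c1 <- cohort$dcp_d1
  n_total <- nrow(cohort)

  missing_baseline <- is.na(c0)
  elig <- assess_eligibility(c0, c1, config)
  normal <- !missing_baseline & elig == "ineligible_normal_baseline"
  assessed <- !missing_baseline & !normal
  low <- assessed & elig == "ineligible_low_baseline"
  normalized <- assessed & elig == "ineligible_normalized"
  missing_d1 <- assessed & !low & is.na(c1)
  analyzable <- elig == "eligible"

  resp <- cohort$response_1mo
  complete <- assessed & !is.na(resp) & resp == "complete"
  incomplete <- assessed & !is.na(resp) & resp == "incomplete"
  recurred_12 <- !is.na(cohort$recurrence_event) &
    cohort$recurrence_event == 1 &
    !is.na(cohort$recurrence_months) & cohort$recurrence_months <= 12

  cascade <- c(
    total = n_total,
    missing_baseline = sum(missing_baseline),
    normal_baseline = sum(normal),
    response_assessed = sum(assessed),
    complete_response = sum(complete),
    incomplete_response = sum(incomplete),
    recurrence_free_12mo_complete = sum(complete & !recurred_12),
    low_baseline = sum(low),
    normalized = sum(normalized),
    missing_d1 = sum(missing_d1),
    analyzable = sum(analyzable)
  )
  if (cascade[["analyzable"]] == 0L) {
    stop("empty cohort: no patient is analyzable for half-life ",
         "(all excluded by the eligibility cascade)", call. = FALSE)
  }

  ana <- cohort[analyzable, , drop = FALSE]
  interval <- if ("draw_interval_h" %in% names(ana)) {
    ifelse(is.na(ana$draw_interval_h), config$default_interval_h,
           ana$draw_interval_h)
  } else {
    rep(config$default_interval_h, nrow(ana))
  }
  hl <- compute_half_life(ana$dcp_d0, ana$dcp_d1, interval,
                          constant = config$half_life_constant,
                          patient_id = ana$patient_id)
  hl$group <- dichotomize(hl$half_life_h, cutoff_h)
  hl$response_1mo <- ana$response_1mo

  labeled <- !is.na(hl$response_1mo)
  confusion <- build_confusion(hl$group[labeled], hl$response_1mo[labeled])
  metrics <- diagnostic_metrics(confusion)
  roc <- roc_analysis(hl$half_life_h[labeled], hl$response_1mo[labeled])

  reelev <- flag_cohort_reelevation(ana)
  hl$reelevated <- reelev$flagged[match(hl$patient_id, reelev$patient_id)]

  discordant_idx <- labeled &
    ((hl$group == "short" & hl$response_1mo == "incomplete") |
     (hl$group == "long" & hl$response_1mo == "complete"))
  discordant <- cbind(
    hl[discordant_idx,
       c("patient_id", "c0", "c1", "half_life_h", "group", "response_1mo",
         "reelevated"),
       drop = FALSE],
    dcp_d7 = if ("dcp_d7" %in% names(ana)) ana$dcp_d7[discordant_idx] else NA,
    dcp_d30 = if ("dcp_d30" %in% names(ana)) ana$dcp_d30[discordant_idx] else NA,
    recurrence_months = ana$recurrence_months[discordant_idx],
    recurrence_event = ana$recurrence_event[discordant_idx]
  )
  rownames(discordant) <- NULL

  surv_dat <- data.frame(
    patient_id = hl$patient_id,
    time_months = ana$recurrence_months,
    event = ana$recurrence_event,
    group = as.character(hl$group),
    short_hl = as.integer(hl$group == "short"),
    stringsAsFactors = FALSE
  )
  if (!is.null(covariates)) {
    for (cv in covariates) surv_dat[[cv]] <- ana[[cv]]
  }
  surv_dat <- surv_dat[!is.na(surv_dat$time_months) &
                       !is.na(surv_dat$event), , drop = FALSE]

  km <- logrank <- cox <- NULL
  if (nrow(surv_dat) > 0 && sum(surv_dat$event) > 0) {
    km <- km_estimate(surv_dat$time_months, surv_dat$event, surv_dat$group)
    if (length(unique(surv_dat$group)) == 2L) {
      logrank <- logrank_test(surv_dat$time_months, surv_dat$event,
                              surv_dat$group)
      cox_terms <- c("short_hl", covariates)
      cox_terms <- cox_terms[vapply(cox_terms, function(cv) {
        length(unique(surv_dat[[cv]][!is.na(surv_dat[[cv]])])) > 1L
      }, logical(1))]
      if (length(cox_terms) > 0) {
        cox <- cox_fit(surv_dat, cox_terms, mode = "both",
                       entry_p = cox_entry_p)
      }
    }
  }

  structure(
    list(cascade = cascade, half_life = hl, confusion = confusion,
         metrics = metrics, roc = roc, reelevation = reelev,
         discordant = discordant, survival_data = surv_dat, km = km,
         logrank = logrank, cox = cox,
         cutoff_h = cutoff_h, constant = config$half_life_constant),
    class = "dcp_report"
  )
}

# Re-elevation flags for every cohort row with a day-1 value and at least
# one later column present in the table.
flag_cohort_reelevation <- function(cohort) {
  has_d7 <- "dcp_d7" %in% names(cohort)
  has_d30 <- "dcp_d30" %in% names(cohort)
  out <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    if (is.na(cohort$dcp_d1[i])) {
      return(data.frame(patient_id = cohort$patient_id[i], flagged = NA,
                        first_reelevation_day = NA_character_,
                        reference_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    series <- data.frame(
      nominal_day = c("D1", if (has_d7) "D7", if (has_d30) "D30"),
      value = c(cohort$dcp_d1[i],
                if (has_d7) cohort$dcp_d7[i],
                if (has_d30) cohort$dcp_d30[i])
    )
    fl <- detect_reelevation(series)
    data.frame(patient_id = cohort$patient_id[i], flagged = fl$flagged,
               first_reelevation_day = fl$first_reelevation_day,
               reference_value = fl$reference_value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Discordant cases between half-life group and radiological response
#'
#' Cases where the dichotomized half-life disagrees with the 1-month
#' response: short half-life despite incomplete ablation (watch for marker
#' re-elevation) and long half-life despite complete response (watch for
#' early recurrence). Their count always equals `fp + fn` of the report's
#' confusion matrix.
#'
#' @param report A `dcp_report` from [run_pipeline()].
#' @return The discordant-case data frame.
#' @export
list_discordant <- function(report) {
  stopifnot(inherits(report, "dcp_report"))
  report$discordant
}

#' @export
print.dcp_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

# Human-readable multi-line summary of a report.
format_report <- function(report) {
  cs <- report$cascade
  pct <- function(num, den) {
    if (den == 0) return("-")
    sprintf("%.1f%%", 100 * num / den)
  }
  lines <- c(
    "DCP half-life analysis",
    "======================",
    sprintf("Enrolled patients:                 %d", cs[["total"]]),
    sprintf("  missing baseline DCP:            %d", cs[["missing_baseline"]]),
    sprintf("  normal baseline DCP (excluded):  %d (%s)",
            cs[["normal_baseline"]], pct(cs[["normal_baseline"]], cs[["total"]])),
    sprintf("Response-assessed:                 %d", cs[["response_assessed"]]),
    sprintf("  complete response:               %d (%s)",
            cs[["complete_response"]],
            pct(cs[["complete_response"]], cs[["response_assessed"]])),
    sprintf("  recurrence-free at 12 mo among complete: %d (%s)",
            cs[["recurrence_free_12mo_complete"]],
            pct(cs[["recurrence_free_12mo_complete"]], cs[["complete_response"]])),
    sprintf("  low baseline < threshold (excluded):     %d", cs[["low_baseline"]]),
    sprintf("  day-1 value normalized (excluded):       %d", cs[["normalized"]]),
    sprintf("  missing day-1 value (excluded):          %d", cs[["missing_d1"]]),
    sprintf("Half-life analyzable:              %d", cs[["analyzable"]]),
    ""
  )
  cm <- report$confusion
  lines <- c(lines,
    sprintf("Confusion at cutoff %g h (short HL = test positive):",
            report$cutoff_h),
    sprintf("  tp=%d fp=%d fn=%d tn=%d", cm$tp, cm$fp, cm$fn, cm$tn))
  for (i in seq_len(nrow(report$metrics))) {
    m <- report$metrics[i, ]
    lines <- c(lines, sprintf("  %-12s %5.1f%%  (95%% CI %.1f-%.1f%%)",
                              m$metric, 100 * m$estimate, 100 * m$ci_low,
                              100 * m$ci_high))
  }
  lines <- c(lines,
    sprintf("ROC: AUC = %.3f, optimal cutoff = %.4g h (Youden J = %.3f)",
            report$roc$auc, report$roc$optimal_cutoff_h, report$roc$youden_j),
    sprintf("Discordant cases: %d", nrow(report$discordant)))
  if (!is.null(report$logrank)) {
    lines <- c(lines,
      sprintf("Log-rank: chi-square = %.2f (df 1), p %s",
              report$logrank$chi_square,
              format_p(report$logrank$p_value)))
  }
  if (!is.null(report$cox)) {
    for (i in seq_len(nrow(report$cox))) {
      r <- report$cox[i, ]
      lines <- c(lines,
        sprintf("Cox (%s) %s: HR %.2f (95%% CI %.2f-%.2f), p %s",
                r$analysis, r$term, r$hr, r$ci_low, r$ci_high,
                format_p(r$p_value)))
    }
  }
  lines
}

#' Write a pipeline report to disk
#'
#' Emits the TSV bundle and a human-readable summary: `half_life.tsv`,
#' `metrics.tsv`, `roc.tsv`, `km.tsv`, `survival_models.tsv`,
#' `discordant.tsv` and `summary.txt`.
#'
#' @param report A `dcp_report`.
#' @param outdir Output directory, created if needed.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "dcp_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    path
  }
  files <- c(
    wr(report$half_life, "half_life.tsv"),
    wr(report$metrics, "metrics.tsv"),
    wr(report$roc$table, "roc.tsv"),
    wr(report$discordant, "discordant.tsv")
  )
  if (!is.null(report$km)) files <- c(files, wr(report$km, "km.tsv"))
  models <- data.frame(analysis = character(0), term = character(0),
                       estimate = numeric(0), ci_low = numeric(0),
                       ci_high = numeric(0), p = character(0))
  if (!is.null(report$logrank)) {
    models <- rbind(models, data.frame(
      analysis = "logrank", term = "group", estimate = report$logrank$chi_square,
      ci_low = NA_real_, ci_high = NA_real_,
      p = format_p(report$logrank$p_value)))
  }
  if (!is.null(report$cox)) {
    models <- rbind(models, data.frame(
      analysis = paste0("cox_", report$cox$analysis), term = report$cox$term,
      estimate = report$cox$hr, ci_low = report$cox$ci_low,
      ci_high = report$cox$ci_high, p = format_p(report$cox$p_value)))
  }
  files <- c(files, wr(models, "survival_models.tsv"))
  summary_path <- file.path(outdir, "summary.txt")
  writeLines(format_report(report), summary_path)
  invisible(c(files, summary_path))
}
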