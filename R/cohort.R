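#' @importFrom survival Surv survfit survdiff coxph
NULL

#' Per-patient TIL summary
#'
#' The per-patient TIL burden is the median of the per-patch inflammatory
#' cell counts (mean of the middle two for an even number of patches).
#'
#' @param patchCounts non-empty numeric vector of per-patch TIL counts.
#' @return the sample median.
#' @export
#' @examples
#' patientTilSummary(c(1, 2, 3, 10))   # 2.5
patientTilSummary <- function(patchCounts) {
  if (!length(patchCounts)) stop("a patient must have at least one patch")
  if (any(patchCounts < 0)) stop("TIL counts must be non-negative")
  stats::median(patchCounts)
}

#' Dichotomize per-patient summaries into high/low groups
#'
#' A patient is "high" when their summary value is strictly above the
#' cutoff; ties at the cutoff go to "low" (patients with an above-median
#' TIL count form the high group). With `cutoff = "cohort-median"` the
#' cutoff is the median of the summaries themselves, so ties at the cohort
#' median are low.
#'
#' @param values numeric per-patient summaries (>= 2 patients).
#' @param cutoff numeric cutoff or "cohort-median" (default).
#' @return factor with levels c("low", "high") and attribute "cutoff".
#'   Warns (and returns one empty group) when all values are identical
#'   under the cohort-median rule.
#' @export
#' @examples
#' dichotomize(c(1, 2, 3, 4))   # low low high high
dichotomize <- function(values, cutoff = "cohort-median") {
  if (length(values) < 2L) stop("need at least two patients")
  if (identical(cutoff, "cohort-median")) cutoff <- stats::median(values)
  if (!is.numeric(cutoff) || length(cutoff) != 1L)
    stop("cutoff must be a number or \"cohort-median\"")
  g <- factor(ifelse(values > cutoff, "high", "low"),
              levels = c("low", "high"))
  if (length(unique(g)) == 1L)
    warning("degenerate grouping: all patients fall on one side of the cutoff")
  attr(g, "cutoff") <- cutoff
  g
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function under right censoring.
#'
#' @param times positive survival times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return data.frame with columns time, n_risk, n_event, n_censor, surv;
#'   the curve starts at S(0) = 1 and is non-increasing.
#' @export
#' @examples
#' kmCurve(c(1, 2, 3), c(1, 0, 1))
kmCurve <- function(times, events) {
  if (length(times) != length(events))
    stop("times and events must have the same length")
  if (any(times <= 0)) stop("survival times must be positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

.check_two_groups <- function(times, events, groups) {
  if (length(times) != length(events) || length(times) != length(groups))
    stop("times, events and groups must have the same length")
  g <- factor(groups)
  if (nlevels(g) != 2L || any(table(g) == 0L))
    stop("exactly two non-empty groups are required")
  g
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square statistic (1 df) with its asymptotic
#' p-value, comparing the survival distributions of two groups.
#'
#' @param times positive survival times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param groups two-level grouping (factor or coercible).
#' @return list with `statistic` and `p`.
#' @export
logRank <- function(times, events, groups) {
  g <- .check_two_groups(times, events, groups)
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  chisq <- unname(sd_$chisq)
  list(statistic = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Hazard ratio between two groups
#'
#' Cox proportional-hazards point estimate with a Wald 95% confidence
#' interval, fit by partial-likelihood maximization. The low-TIL group is
#' the reference, so protective TILs yield HR < 1 for the high group.
#'
#' @inheritParams logRank
#' @param reference the reference level; default "low" when present,
#'   otherwise the first factor level.
#' @return list with `hr`, `lower`, `upper` (95% CI), `logHr`, `se`, `p`
#'   and `nEvents`.
#' @export
hazardRatio <- function(times, events, groups, reference = NULL) {
  g <- .check_two_groups(times, events, groups)
  if (is.null(reference))
    reference <- if ("low" %in% levels(g)) "low" else levels(g)[1]
  g <- stats::relevel(g, ref = reference)
  if (sum(events) < 1) stop("at least one event is required")
  fit <- tryCatch(
    survival::coxph(survival::Surv(times, events) ~ g),
    error = function(e) stop("proportional-hazards fit failed: ",
                             conditionMessage(e)))
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se))
    stop("proportional-hazards fit did not converge (non-finite estimate)")
  z <- stats::qnorm(0.975)
  list(hr = exp(beta), lower = exp(beta - z * se), upper = exp(beta + z * se),
       logHr = beta, se = se,
       p = 2 * stats::pnorm(-abs(beta / se)),
       nEvents = sum(events))
}

#' Log-rank significance sweep over all dichotomizing cutoffs
#'
#' Candidate cutoffs are the midpoints between consecutive distinct sorted
#' summary values — every distinct high/low dichotomy of the cohort. For
#' each cutoff the cohort is split (strictly greater = high) and the
#' two-group log-rank test computed. Cutoffs producing a group smaller than
#' `minGroupSize` are flagged, not dropped. P-values are raw (no
#' multiple-testing correction), as is conventional for this exploratory
#' sweep; interpret them accordingly.
#'
#' @param values per-patient summary values (>= 2 distinct).
#' @param times,events per-patient survival data aligned with `values`.
#' @param minGroupSize group size below which a cutoff is flagged;
#'   default 5.
#' @return data.frame with columns cutoff, statistic, p, n_low, n_high,
#'   flagged; cutoffs strictly increasing.
#' @export
cutoffSweep <- function(values, times, events, minGroupSize = 5) {
  sv <- sort(unique(values))
  if (length(sv) < 2L) stop("need at least two distinct summary values")
  cutoffs <- (sv[-length(sv)] + sv[-1]) / 2
  rows <- lapply(cutoffs, function(ct) {
    g <- factor(ifelse(values > ct, "high", "low"),
                levels = c("low", "high"))
    lr <- logRank(times, events, g)
    data.frame(cutoff = ct, statistic = lr$statistic, p = lr$p,
               n_low = sum(g == "low"), n_high = sum(g == "high"))
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$n_low < minGroupSize | out$n_high < minGroupSize
  out
}

#' Read / write a cohort table
#'
#' Long-format CSV contract: one row per patch with columns patient_id,
#' patch_id, til_count, time_months, event (and optionally extra columns,
#' preserved).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readCohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "patch_id", "til_count", "time_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort CSV is missing columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname readCohort
#' @param cohort data.frame in the cohort schema.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Full TIL survival-stratification analysis
#'
#' Aggregates per-patch TIL counts to a per-patient median, dichotomizes at
#' the cohort median (or a supplied cutoff), and runs the two-group survival
#' comparison: Kaplan-Meier curves per group, the log-rank test, the Cox
#' hazard ratio (high vs. low), and optionally the all-cutoffs significance
#' sweep.
#'
#' @param cohort long-format data.frame as from [readCohort()] or
#'   [generateCohort()].
#' @param cutoff numeric cutoff or "cohort-median" (default).
#' @param sweep also run [cutoffSweep()]; default TRUE.
#' @param minGroupSize passed to the sweep.
#' @return list of class "CohortResult": `patients` (per-patient table with
#'   summary value and group), `cutoff`, `km` (list of per-group KM tables),
#'   `logRank`, `hazardRatio`, `sweep` (or NULL).
#' @export
analyzeCohort <- function(cohort, cutoff = "cohort-median", sweep = TRUE,
                          minGroupSize = 5) {
  need <- c("patient_id", "til_count", "time_months", "event")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  split_ <- split(cohort, cohort$patient_id)
  patients <- do.call(rbind, lapply(split_, function(df) {
    if (length(unique(df$time_months)) != 1L ||
        length(unique(df$event)) != 1L)
      stop("survival time/event must be constant within a patient")
    data.frame(patient_id = df$patient_id[1],
               n_patches = nrow(df),
               til_median = patientTilSummary(df$til_count),
               time_months = df$time_months[1],
               event = df$event[1])
  }))
  rownames(patients) <- NULL
  grp <- dichotomize(patients$til_median, cutoff)
  patients$group <- as.character(grp)
  km <- lapply(split(patients, patients$group), function(df)
    kmCurve(df$time_months, df$event))
  lr <- NULL; hr <- NULL
  if (all(c("low", "high") %in% patients$group)) {
    lr <- logRank(patients$time_months, patients$event, patients$group)
    hr <- hazardRatio(patients$time_months, patients$event, patients$group)
  }
  sw <- NULL
  if (sweep && length(unique(patients$til_median)) >= 2L)
    sw <- cutoffSweep(patients$til_median, patients$time_months,
                      patients$event, minGroupSize)
  structure(list(patients = patients, cutoff = attr(grp, "cutoff"),
                 km = km, logRank = lr, hazardRatio = hr, sweep = sw),
            class = "CohortResult")
}

#' @export
print.CohortResult <- function(x, ...) {
  cat(sprintf("CohortResult: %d patients, cutoff %.3g (%d low / %d high)\n",
              nrow(x$patients), x$cutoff,
              sum(x$patients$group == "low"),
              sum(x$patients$group == "high")))
  if (!is.null(x$logRank))
    cat(sprintf("  log-rank: chi-square %.3f, p = %.4g\n",
                x$logRank$statistic, x$logRank$p))
  if (!is.null(x$hazardRatio))
    cat(sprintf("  hazard ratio (high vs low): %.3f (95%% CI %.3f-%.3f)\n",
                x$hazardRatio$hr, x$hazardRatio$lower, x$hazardRatio$upper))
  if (!is.null(x$sweep))
    cat(sprintf("  sweep: %d cutoffs, min p = %.4g\n",
                nrow(x$sweep), min(x$sweep$p)))
  invisible(x)
}
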