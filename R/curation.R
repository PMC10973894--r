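#' Day-level validity filter for wearable step records
#'
#' Retains exactly the days with at least 10 hours (600 minutes) of device
#' wear, a step count between 100 and 45000 inclusive, and (when ages are
#' supplied) participant age of at least 18 years. Days with a missing wear
#' time are removed and counted in the audit, not raised as errors. The
#' filter is order-preserving and idempotent.
#'
#' @param records data frame of daily records with columns `person_id`,
#'   `date`, `steps`, `wear_minutes`.
#' @param ages optional data frame with columns `person_id` and
#'   `birth_date` used to apply the adult-age filter day by day.
#' @param min_wear_minutes minimum valid wear time, minutes (default 600,
#'   i.e. 10 hours).
#' @param step_range inclusive validity bounds on daily steps.
#' @param min_age minimum age in years.
#'
#' @return The retained records, in input order, with an `"audit"`
#'   attribute counting removed days by reason (each removed day is
#'   attributed to the first failing rule, in the order missing wear,
#'   under-age, low wear, low steps, high steps).
#' @export
filter_valid_days <- function(records, ages = NULL,
                              min_wear_minutes = 600,
                              step_range = c(100, 45000),
                              min_age = 18) {
  stopifnot(all(c("person_id", "date", "steps", "wear_minutes") %in% names(records)))
  n <- nrow(records)
  missing_wear <- is.na(records$wear_minutes)
  under_age <- rep(FALSE, n)
  if (!is.null(ages)) {
    stopifnot(all(c("person_id", "birth_date") %in% names(ages)))
    bd <- ages$birth_date[match(records$person_id, ages$person_id)]
    age_at <- as.numeric(records$date - as.Date(bd)) / 365.25
    under_age <- !is.na(age_at) & age_at < min_age
  }
  low_wear <- !missing_wear & records$wear_minutes < min_wear_minutes
  low_steps <- !is.na(records$steps) & records$steps < step_range[1]
  high_steps <- !is.na(records$steps) & records$steps > step_range[2]

  reason <- rep(NA_character_, n)
  reason[high_steps] <- "high_steps"
  reason[low_steps] <- "low_steps"
  reason[low_wear] <- "low_wear"
  reason[under_age] <- "under_age"
  reason[missing_wear] <- "missing_wear"
  keep <- is.na(reason)

  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  audit <- c(
    n_in = n, n_out = sum(keep),
    missing_wear = sum(reason == "missing_wear", na.rm = TRUE),
    under_age = sum(reason == "under_age", na.rm = TRUE),
    low_wear = sum(reason == "low_wear", na.rm = TRUE),
    low_steps = sum(reason == "low_steps", na.rm = TRUE),
    high_steps = sum(reason == "high_steps", na.rm = TRUE)
  )
  attr(out, "audit") <- audit
  out
}

# Calendar-month (or person-anchored 30.4375-day block) bounds for a given
# month index relative to a person's monitoring start date.
.month_bounds <- function(t0, index, anchor) {
  if (anchor == "calendar") {
    y0 <- data.table::year(t0)
    m0 <- data.table::month(t0)
    total <- (y0 * 12L + (m0 - 1L)) + index
    y <- total %/% 12L
    m <- total %% 12L + 1L
    start <- as.Date(sprintf("%04d-%02d-01", y, m))
    nxt <- total + 1L
    end <- as.Date(sprintf("%04d-%02d-01", nxt %/% 12L, nxt %% 12L + 1L))
  } else {
    start <- t0 + round(index * .MONTH_DAYS)
    end <- t0 + round((index + 1) * .MONTH_DAYS)
  }
  list(start = start, end = end)
}

#' Monthly mean daily step counts
#'
#' Aggregates day-filtered step records into one exposure record per
#' person-month; months with fewer than 15 valid days of monitoring are
#' removed. The month grid is the calendar months of the person's record
#' dates by default, or person-anchored 30.44-day blocks from the first
#' valid day.
#'
#' @param valid_days output of [filter_valid_days()].
#' @param min_valid_days minimum number of valid days for a month to
#'   contribute an exposure value (default 15).
#' @param anchor `"calendar"` (default) or `"person"`.
#'
#' @return A `monthly_exposure` data frame with columns `person_id`,
#'   `month_index` (months since each person's monitoring start),
#'   `mean_steps`, `n_valid_days`, `month_start`, `month_end`
#'   (half-open calendar bounds), plus a `"monitoring_start"` attribute
#'   mapping each person to their first valid day.
#' @export
monthly_means <- function(valid_days, min_valid_days = 15,
                          anchor = c("calendar", "person")) {
  anchor <- match.arg(anchor)
  dt <- as.data.table(valid_days)
  if (nrow(dt) == 0L) {
    out <- data.frame(
      person_id = character(), month_index = integer(),
      mean_steps = numeric(), n_valid_days = integer(),
      month_start = as.Date(character()), month_end = as.Date(character())
    )
    attr(out, "monitoring_start") <-
      data.frame(person_id = character(), start_date = as.Date(character()))
    class(out) <- c("monthly_exposure", "data.frame")
    return(out)
  }
  starts <- dt[, .(start_date = min(date)), by = person_id]
  dt <- merge(dt, starts, by = "person_id")
  if (anchor == "calendar") {
    ym <- data.table::year(dt$date) * 12L + data.table::month(dt$date) - 1L
    ym0 <- data.table::year(dt$start_date) * 12L +
      data.table::month(dt$start_date) - 1L
    dt[, month_index := ym - ym0]
  } else {
    dt[, month_index := as.integer(floor(as.numeric(date - start_date) / .MONTH_DAYS))]
  }
  dt[, steps := as.numeric(steps)]
  agg <- dt[, .(mean_steps = mean(steps), n_valid_days = .N),
            by = .(person_id, month_index)]
  agg <- agg[n_valid_days >= min_valid_days]
  agg <- merge(agg, starts, by = "person_id")
  setorder(agg, person_id, month_index)
  bounds <- .month_bounds(agg$start_date, agg$month_index, anchor)
  out <- data.frame(
    person_id = agg$person_id, month_index = agg$month_index,
    mean_steps = agg$mean_steps, n_valid_days = agg$n_valid_days,
    month_start = bounds$start, month_end = bounds$end
  )
  attr(out, "monitoring_start") <- setDF(starts)
  attr(out, "anchor") <- anchor
  class(out) <- c("monthly_exposure", "data.frame")
  out
}

#' Assemble the analytic cohort with the incident-obesity landmark
#'
#' Applies the eligibility and outcome rules: baseline BMI is the BMI
#' record closest to monitoring start within a window; persons with no
#' baseline BMI, baseline BMI of 30 or more, or a first obese BMI record
#' before the landmark (default 6 months) are excluded; the event is the
#' first BMI record of 30 or greater at or after the landmark; censoring
#' time is the later of the last exposure month end and the last BMI
#' record. Time zero is each person's first valid monitoring day.
#'
#' @param monthly a [monthly_means()] result.
#' @param bmi data frame with columns `person_id`, `date`, `bmi`.
#' @param genetics optional data frame keyed by `person_id` (e.g. score and
#'   principal components); its columns are carried onto the cohort.
#' @param covariates optional data frame of baseline covariates keyed by
#'   `person_id`; also defines the input person universe for attrition
#'   accounting.
#' @param baseline_window_days half-width of the window around monitoring
#'   start within which a BMI record can serve as baseline (default 180).
#' @param landmark_years events before this time are treated as prevalent
#'   and the person excluded (default 0.5 years).
#'
#' @return An object of class `analytic_cohort`: a list with `cohort`
#'   (one row per analysed person: `person_id`, `baseline_bmi`,
#'   `baseline_steps`, `event`, `time`, covariate and genetics columns),
#'   `monthly` (exposure series of analysed persons), `attrition`
#'   (ordered per-rule exclusion counts summing to the input count),
#'   `monitoring_start`, and `landmark_years`.
#' @export
assemble_cohort <- function(monthly, bmi, genetics = NULL, covariates = NULL,
                            baseline_window_days = 180, landmark_years = 0.5) {
  ms <- attr(monthly, "monitoring_start")
  if (is.null(ms)) stop("assemble_cohort: monthly exposure lacks monitoring_start; use monthly_means()")
  mdt <- as.data.table(monthly)
  bdt <- as.data.table(bmi)
  bdt[, date := as.Date(date)]

  universe <- if (!is.null(covariates)) {
    unique(covariates$person_id)
  } else {
    unique(c(mdt$person_id, bdt$person_id))
  }
  n_input <- length(universe)

  with_months <- unique(mdt$person_id)
  excl_no_months <- setdiff(universe, with_months)

  msd <- data.table(person_id = ms$person_id, t0 = as.Date(ms$start_date))
  bdt <- merge(bdt[person_id %in% with_months], msd, by = "person_id")
  bdt[, tt := as.numeric(date - t0) / 365.25]

  # baseline BMI: record closest to monitoring start within the window
  # (ties broken toward the earlier record)
  bw <- bdt[abs(as.numeric(date - t0)) <= baseline_window_days]
  bw[, absdiff := abs(as.numeric(date - t0))]
  setorderv(bw, c("person_id", "absdiff", "date"))
  baseline <- unique(bw, by = "person_id")[, .(person_id, baseline_bmi = bmi)]

  # first obese record and last BMI date
  ob <- bdt[bmi >= 30]
  setorderv(ob, c("person_id", "date"))
  first_obese <- unique(ob, by = "person_id")[, .(person_id, t_obese = tt)]
  last_bmi <- bdt[, .(t_last_bmi = max(tt)), by = person_id]

  # first-month exposure and last exposure month end
  setorderv(mdt, c("person_id", "month_index"))
  first_month <- unique(mdt, by = "person_id")[, .(person_id, baseline_steps = mean_steps)]
  mend <- merge(mdt[, .(end = max(month_end)), by = person_id], msd,
                by = "person_id")
  mend[, t_last_exp := as.numeric(end - t0) / 365.25]

  tab <- Reduce(function(a, b) merge(a, b, by = "person_id", all.x = TRUE),
                list(data.table(person_id = with_months), baseline,
                     first_obese, last_bmi, first_month,
                     mend[, .(person_id, t_last_exp)]))
  tab[, reason := ""]
  tab[is.na(baseline_bmi), reason := "no_baseline_bmi"]
  tab[reason == "" & baseline_bmi >= 30, reason := "baseline_obese"]
  tab[reason == "" & !is.na(t_obese) & t_obese < landmark_years,
      reason := "early_event"]
  tab[, event := reason == "" & !is.na(t_obese)]
  tab[, time := ifelse(event, t_obese, pmax(t_last_exp, t_last_bmi))]
  tab[reason == "" & time <= 0, reason := "no_follow_up"]

  cohort <- tab[reason == "",
                .(person_id, baseline_bmi, baseline_steps, event, time)]
  attrition <- data.frame(
    rule = c("input", "no_valid_months", "no_baseline_bmi", "baseline_obese",
             "early_event", "no_follow_up", "analytic"),
    n = c(
      n_input, length(excl_no_months),
      sum(tab$reason == "no_baseline_bmi"), sum(tab$reason == "baseline_obese"),
      sum(tab$reason == "early_event"), sum(tab$reason == "no_follow_up"),
      nrow(cohort)
    )
  )

  if (!is.null(covariates)) {
    cohort <- merge(cohort, as.data.table(covariates), by = "person_id",
                    all.x = TRUE, sort = TRUE)
  }
  if (!is.null(genetics)) {
    cohort <- merge(cohort, as.data.table(genetics), by = "person_id",
                    all.x = TRUE, sort = TRUE)
  }
  setorder(cohort, person_id)
  keep_monthly <- monthly[monthly$person_id %in% cohort$person_id, , drop = FALSE]
  attr(keep_monthly, "monitoring_start") <- ms
  attr(keep_monthly, "anchor") <- attr(monthly, "anchor")
  class(keep_monthly) <- class(monthly)

  structure(
    list(
      cohort = setDF(cohort), monthly = keep_monthly, attrition = attrition,
      monitoring_start = ms, landmark_years = landmark_years
    ),
    class = "analytic_cohort"
  )
}

#' @export
print.analytic_cohort <- function(x, ...) {
  cat("Analytic cohort:", nrow(x$cohort), "persons,",
      sum(x$cohort$event), "incident events\n")
  cat("Attrition:\n")
  print(x$attrition, row.names = FALSE)
  invisible(x)
}
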