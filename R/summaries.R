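# Reporting surface: stepwise attrition accounting by
# time-since-admission bin, the day-count long-stay comparator, monthly
# algorithm comparisons, and point prevalence of a drug class within
# observable time.

attrition_count_cols <- c(
  "n_residents", "n_admission_episodes", "total_days", "unenrolled_days",
  "enrolled_days", "snf_days", "hospital_days", "observable_days",
  "n_residents_observable", "n_admission_episodes_observable",
  "n_observable_episodes")

#' Stepwise attrition summary of a flagged day grid
#'
#' Mirrors the stepwise accounting of NH person-time: per
#' time-since-admission bin and overall, the number of residents and
#' admission episodes touching the bin, total days, days unenrolled vs
#' enrolled in Parts A/B/D (Step 2), enrolled days in SNF care (Step 3)
#' and in hospital (Step 4) — a single day can contribute to both — the
#' remaining observable medication days (Step 5), residents / admission
#' episodes with at least one observable day, and the number of distinct
#' observable episodes touching the bin. Percentages are appended via
#' [attrition_percentages()].
#'
#' @param days fully flagged day grid.
#' @param bins bin table, default [nh_time_bins()].
#' @return data.table with one row per bin plus an `"all"` row.
#' @export
#' @examples
#' fx <- make_fixture("figure1_schematic")
#' days <- classify_days(expand_to_days(build_episodes(fx)), fx)
#' summarize_attrition(days)
summarize_attrition <- function(days, bins = nh_time_bins()) {
  days <- data.table::as.data.table(days)
  if (nrow(days)) {
    if (anyNA(days$enrolled) || anyNA(days$snf) || anyNA(days$hospital)) {
      stop("summarize_attrition: flags not fully populated", call. = FALSE)
    }
    d <- assign_time_bins(days, bins)
    d[, observable := as.integer(enrolled == 1L & snf == 0L & hospital == 0L)]
    obs <- build_observable_episodes(d[observable == 1L])
    d[, obs_ep := NA_character_]
    if (nrow(obs)) {
      d[obs, obs_ep := i.observable_episode_id,
        on = .(resident_id, episode_id, date >= start_date, date <= end_date)]
    }
  } else {
    d <- data.table::copy(days)
    d[, `:=`(bin = character(0), observable = integer(0), obs_ep = character(0))]
  }

  agg <- function(dd, label) data.table(
    bin = label,
    n_residents = data.table::uniqueN(dd$resident_id),
    n_admission_episodes = data.table::uniqueN(dd$episode_id),
    total_days = nrow(dd),
    unenrolled_days = sum(dd$enrolled == 0L),
    enrolled_days = sum(dd$enrolled == 1L),
    snf_days = sum(dd$enrolled == 1L & dd$snf == 1L),
    hospital_days = sum(dd$enrolled == 1L & dd$hospital == 1L),
    observable_days = sum(dd$observable == 1L),
    n_residents_observable = data.table::uniqueN(dd$resident_id[dd$observable == 1L]),
    n_admission_episodes_observable = data.table::uniqueN(dd$episode_id[dd$observable == 1L]),
    n_observable_episodes = data.table::uniqueN(dd$obs_ep[dd$observable == 1L]))

  rows <- lapply(bins$label, function(lb) agg(d[bin == lb], lb))
  out <- data.table::rbindlist(c(rows, list(agg(d, "all"))))
  attrition_percentages(out)
}

#' Append stepwise percentages to attrition counts
#'
#' Given attrition counts (any table carrying `total_days`,
#' `unenrolled_days`, `enrolled_days`, `snf_days`, `hospital_days`,
#' `observable_days`), appends the published-style percentages, rounded
#' to one decimal half away from zero: observable share of enrolled days
#' and of all days, unenrolled share of all days, and SNF / hospital
#' shares of enrolled days. Zero denominators yield `NA` (absent), never
#' zero.
#'
#' @param counts attrition count table (percent columns, if present, are
#'   recomputed).
#' @return the table with `pct_*` columns (a copy).
#' @export
#' @examples
#' attrition_percentages(data.frame(total_days = 2685903261,
#'   unenrolled_days = 1217033772, enrolled_days = 1468869489,
#'   snf_days = 386022155, hospital_days = 29012885,
#'   observable_days = 1063746842))
attrition_percentages <- function(counts) {
  out <- data.table::copy(data.table::as.data.table(counts))
  bad <- out[enrolled_days > total_days | unenrolled_days < 0 |
             enrolled_days < 0 | observable_days < 0]
  if (nrow(bad)) {
    stop("attrition_percentages: counts must be nonnegative with enrolled <= total",
         call. = FALSE)
  }
  out[, `:=`(
    pct_observable_of_enrolled = pct_round(observable_days, enrolled_days),
    pct_observable_of_total = pct_round(observable_days, total_days),
    pct_unenrolled_of_total = pct_round(unenrolled_days, total_days),
    pct_snf_of_enrolled = pct_round(snf_days, enrolled_days),
    pct_hospital_of_enrolled = pct_round(hospital_days, enrolled_days))]
  out[]
}

#' Aggregate attrition rows over several bins
#'
#' Sums the day counts of the selected bin rows into one row (resident /
#' episode counts are not summable across bins and are returned as `NA`)
#' and recomputes percentages — e.g. the first 100 days after admission
#' are the `"1-30"`, `"31-60"` and `"61-100"` bins combined.
#'
#' @param summary output of [summarize_attrition()] (or any table in its
#'   layout).
#' @param labels bin labels to combine.
#' @param label label for the combined row.
#' @return a one-row data.table.
#' @export
aggregate_attrition_bins <- function(summary, labels, label = "combined") {
  s <- data.table::as.data.table(summary)[bin %in% labels]
  if (!nrow(s)) stop("aggregate_attrition_bins: no rows match the given labels", call. = FALSE)
  day_cols <- c("total_days", "unenrolled_days", "enrolled_days", "snf_days",
                "hospital_days", "observable_days", "n_observable_episodes")
  day_cols <- intersect(day_cols, names(s))
  out <- s[, lapply(.SD, sum), .SDcols = day_cols]
  out[, bin := label]
  for (col in setdiff(attrition_count_cols, day_cols)) out[, (col) := NA_integer_]
  data.table::setcolorder(out, c("bin", intersect(attrition_count_cols, names(out))))
  attrition_percentages(out)
}

#' Day-count long-stay classifier ("method 2" style)
#'
#' The standard long-stay convention classifies an NH admission episode
#' as long-stay once it reaches a day-index cutoff (101 days by the CMS
#' convention, because Part A covers at most the first 100 SNF days).
#' The classification deliberately ignores the observability flags —
#' contrasting it with observable-time accounting is the point. Exact
#' published long-stay rule sets differ in details not restated here
#' (qualifying assessments, cumulative vs consecutive days); this
#' classifier is the day-index approximation with configurable
#' attribution.
#'
#' @param days day grid with `day_index`.
#' @param cutoff first long-stay day index (default 101).
#' @param attribution `"from_cutoff"` (long-stay person-time = days at or
#'   beyond the cutoff in qualifying episodes, the default) or
#'   `"whole_episode"` (every day of a qualifying episode).
#' @return data.table with `resident_id`, `episode_id`, `long_stay`,
#'   `qualifying_date` (the episode's cutoff-th day when reached),
#'   `n_long_stay_days`; attributes `cutoff` and `attribution`.
#' @export
classify_long_stay_method2 <- function(days, cutoff = 101L,
                                       attribution = c("from_cutoff", "whole_episode")) {
  attribution <- match.arg(attribution)
  cutoff <- as.integer(cutoff)
  if (is.na(cutoff) || cutoff < 1L) stop("cutoff must be >= 1", call. = FALSE)
  days <- data.table::as.data.table(days)
  out <- if (nrow(days)) {
    days[, {
      reached <- max(day_index) >= cutoff
      list(long_stay = as.integer(reached),
           qualifying_date = if (reached) date[day_index == cutoff][1L]
                             else data.table::as.IDate(NA),
           n_long_stay_days = if (!reached) 0L
                              else if (attribution == "from_cutoff") sum(day_index >= cutoff)
                              else .N)
    }, by = .(resident_id, episode_id)]
  } else {
    data.table(resident_id = character(0), episode_id = character(0),
               long_stay = integer(0),
               qualifying_date = data.table::as.IDate(integer(0)),
               n_long_stay_days = integer(0))
  }
  data.table::setattr(out, "cutoff", cutoff)
  data.table::setattr(out, "attribution", attribution)
  out[]
}

# day rows counting as long-stay person-time under a classification
long_stay_day_rows <- function(days, classifications) {
  cutoff <- attr(classifications, "cutoff")
  attribution <- attr(classifications, "attribution")
  days <- data.table::as.data.table(days)
  q <- data.table::as.data.table(classifications)[long_stay == 1L,
                                                  .(resident_id, episode_id)]
  d <- days[q, on = .(resident_id, episode_id), nomatch = NULL]
  if (attribution == "from_cutoff") d <- d[day_index >= cutoff]
  d
}

#' Compare person-time algorithms within one calendar month
#'
#' For a given month, counts the unique residents with at least one
#' qualifying day and the number of qualifying days under each supplied
#' day grid (e.g. entry-anchored and admission-assessment-anchored), and
#' under the day-count long-stay classifier; also reports the share of
#' long-stay person-time in the month that is medication-unobservable.
#'
#' @param day_grids named list of day grids (one per anchoring).
#' @param observable_days observable-day grid (from
#'   [select_observable_days()]) on the same basis as the grid named by
#'   `long_stay_source`.
#' @param classifications output of [classify_long_stay_method2()]
#'   computed on the `long_stay_source` grid.
#' @param month calendar month, `"YYYY-MM"`.
#' @param long_stay_source name of the element of `day_grids` the
#'   classifier was run on (default the first element).
#' @param study_start,study_end study window; the month must lie inside
#'   it (defaults to the date range spanned by the grids).
#' @return list of class `"nh_comparison"`: `month`, `counts` (data.table
#'   `algorithm` / `n_residents` / `n_days`), and
#'   `long_stay_unobservable_pct`.
#' @export
compare_algorithms <- function(day_grids, observable_days, classifications,
                               month, long_stay_source = names(day_grids)[1],
                               study_start = NULL, study_end = NULL) {
  stopifnot(is.list(day_grids), length(day_grids) >= 1, !is.null(names(day_grids)))
  all_dates <- unlist(lapply(day_grids, function(g) as.integer(g$date)))
  if (is.null(study_start)) study_start <- data.table::as.IDate(min(all_dates))
  if (is.null(study_end)) study_end <- data.table::as.IDate(max(all_dates))
  m0 <- month_start(month); m1 <- month_end(month)
  if (m1 < as_nh_date(study_start) || m0 > as_nh_date(study_end)) {
    stop(sprintf("month %s lies outside the study window %s..%s",
                 month, study_start, study_end), call. = FALSE)
  }
  month_count <- function(d, label) {
    dm <- data.table::as.data.table(d)[date >= m0 & date <= m1]
    data.table(algorithm = label,
               n_residents = data.table::uniqueN(dm$resident_id),
               n_days = nrow(dm))
  }
  counts <- data.table::rbindlist(c(
    lapply(names(day_grids), function(nm) month_count(day_grids[[nm]], nm)),
    list(month_count(long_stay_day_rows(day_grids[[long_stay_source]],
                                        classifications),
                     sprintf("long_stay_%d", attr(classifications, "cutoff"))))))
  ls_month <- long_stay_day_rows(day_grids[[long_stay_source]],
                                 classifications)[date >= m0 & date <= m1]
  obs <- data.table::as.data.table(observable_days)
  unobs <- if (nrow(ls_month)) {
    hit <- obs[ls_month, on = .(resident_id, episode_id, date), which = TRUE]
    sum(is.na(hit))
  } else 0L
  structure(list(month = month, counts = counts,
                 long_stay_unobservable_pct = pct_round(unobs, nrow(ls_month))),
            class = "nh_comparison")
}

#' @export
print.nh_comparison <- function(x, ...) {
  cat(sprintf("<nh_comparison> %s\n", x$month))
  print(x$counts)
  cat(sprintf("  long-stay person-time unobservable: %s%%\n",
              format(x$long_stay_unobservable_pct)))
  invisible(x)
}

#' Point prevalence of a drug class within observable time
#'
#' Numerator: residents with at least one dispensing whose days-supply
#' coverage interval `[fill, fill + supply - 1]` intersects one of their
#' observable days in the month. Denominator: residents with at least one
#' observable day in the month. Dispensings with nonpositive days supply
#' are rejected with a warning.
#'
#' @param dispensings dispensing table (`resident_id`, `fill_date`,
#'   `days_supply`).
#' @param observable_days observable-day grid.
#' @param month calendar month `"YYYY-MM"`.
#' @return proportion in \[0, 1\] (`NA` when no resident has an
#'   observable day in the month).
#' @export
point_prevalence <- function(dispensings, observable_days, month) {
  disp <- data.table::as.data.table(dispensings)
  obs <- data.table::as.data.table(observable_days)
  m0 <- month_start(month); m1 <- month_end(month)
  obs_m <- obs[date >= m0 & date <= m1]
  denom <- data.table::uniqueN(obs_m$resident_id)
  if (denom == 0L) return(NA_real_)
  if (!nrow(disp)) return(0)
  bad <- disp[days_supply <= 0L | is.na(days_supply)]
  if (nrow(bad)) {
    warning(sprintf("point_prevalence: rejected %d dispensing(s) with nonpositive days supply",
                    nrow(bad)), call. = FALSE)
    disp <- disp[days_supply > 0L & !is.na(days_supply)]
  }
  if (!nrow(disp)) return(0)
  disp[, `:=`(cov_start = as_nh_date(fill_date, "fill_date"))]
  disp[, cov_end := data.table::as.IDate(as.integer(cov_start) + days_supply - 1L)]
  hit <- obs_m[disp, on = .(resident_id, date >= cov_start, date <= cov_end),
               nomatch = NULL, .(resident_id)]
  data.table::uniqueN(hit$resident_id) / denom
}

#' Published stepwise day counts for the 2013-2020 US nursing-home cohort
#'
#' Stepwise attrition counts reported for the national 2013-2020 US
#' Medicare fee-for-service nursing-home cohort (admission-anchored
#' basis), by time-since-admission bin: total NH days, days unenrolled /
#' enrolled in Parts A, B and D, enrolled days in SNF care and in
#' hospital, observable medication days, and the resident / episode
#' counts. Shipped as plain CSV in `inst/extdata`; useful as a worked
#' example for the summary arithmetic (see [attrition_percentages()]).
#'
#' @return data.table in the [summarize_attrition()] count layout.
#' @export
#' @examples
#' attrition_percentages(nh_published_counts())
nh_published_counts <- function() {
  path <- system.file("extdata", "us_nh_cohort_2013_2020_step_counts.csv",
                      package = "nhobs", mustWork = TRUE)
  data.table::fread(path, colClasses = list(character = "bin"))
}
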