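# Steps 2-4: expand episodes to a resident-day grid and set the three
# observability flags (FFS+Part D enrollment, SNF coverage, inpatient
# hospitalization).
#
# Stay-day convention: Part A stays cover the half-open interval
# [admit, discharge), so length_of_stay = discharge - admit and the
# discharge day belongs to the next care setting. `include_discharge_day`
# switches to closed intervals for sensitivity analyses.

#' Impute missing Part A discharge dates from length of stay
#'
#' Stay records with a blank discharge date get
#' `discharge_date = admit_date + length_of_stay` (the identity under the
#' half-open stay-day convention). Rows with both fields present are
#' untouched. Rows missing both the discharge date and the length of stay
#' cannot be placed on the day grid; they are removed and returned in the
#' `rejected` attribute, with a warning.
#'
#' @param stays Part A stay data.table.
#' @return the stays table with complete discharge dates; attributes
#'   `n_imputed` (count of imputed rows) and `rejected` (removed rows).
#' @export
#' @examples
#' fx <- make_fixture("missing_discharge")
#' impute_part_a_discharge(fx$part_a_stays)
impute_part_a_discharge <- function(stays) {
  st <- data.table::copy(data.table::as.data.table(stays))
  if (!nrow(st)) {
    data.table::setattr(st, "n_imputed", 0L)
    data.table::setattr(st, "rejected", st[0])
    return(st[])
  }
  st[, admit_date := as_nh_date(admit_date, "admit_date")]
  bad <- st[is.na(discharge_date) & is.na(length_of_stay)]
  if (nrow(bad)) {
    warning(sprintf("impute_part_a_discharge: rejected %d stay(s) missing both discharge date and length of stay",
                    nrow(bad)), call. = FALSE)
    st <- st[!(is.na(discharge_date) & is.na(length_of_stay))]
  }
  to_fix <- which(is.na(st$discharge_date))
  if (length(to_fix)) {
    data.table::set(st, to_fix, "discharge_date",
                    data.table::as.IDate(as.integer(st$admit_date[to_fix]) +
                                         as.integer(st$length_of_stay[to_fix])))
    message(sprintf("impute_part_a_discharge: imputed %d discharge date(s) from length of stay",
                    length(to_fix)))
  }
  data.table::setattr(st, "n_imputed", length(to_fix))
  data.table::setattr(st, "rejected", bad)
  st[]
}

#' Expand finalized episodes to a resident-day grid
#'
#' Emits one row per calendar day per episode: `resident_id`,
#' `episode_id`, `date`, `day_index` (1 on the episode start date), and
#' the three flag columns initialised to `NA` until the `flag_*`
#' functions run. Episodes are closed date intervals, so an episode
#' contributes `end - start + 1` rows; with
#' `count_discharge_day = FALSE`, episodes ending in a final discharge
#' lose their last day (an episode reduced below one day contributes no
#' rows).
#'
#' @param episodes finalized, pairwise-disjoint episodes (one anchoring);
#'   overlap is a precondition error — merge first.
#' @param count_discharge_day logical; count the discharge day as an NH
#'   day (default `TRUE`).
#' @return day-grid data.table.
#' @export
expand_to_days <- function(episodes, count_discharge_day = TRUE) {
  eps <- data.table::as.data.table(episodes)
  empty <- data.table(resident_id = character(0), episode_id = character(0),
                      date = data.table::as.IDate(integer(0)),
                      day_index = integer(0), enrolled = NA_integer_[0],
                      snf = NA_integer_[0], hospital = NA_integer_[0])
  if (!nrow(eps)) return(empty)
  has_overlap <- eps[order(resident_id, start_date),
                     .(bad = .N > 1 &&
                         any(as.integer(start_date)[-1] <=
                             cummax(as.integer(end_date))[-.N])),
                     by = resident_id][, any(bad)]
  if (has_overlap) {
    stop("expand_to_days: overlapping episodes within a resident; run merge_overlapping_episodes() first",
         call. = FALSE)
  }
  if (!count_discharge_day) {
    eps <- data.table::copy(eps)
    eps[end_reason == "final_discharge",
        end_date := data.table::as.IDate(as.integer(end_date) - 1L)]
    eps <- eps[end_date >= start_date]
    if (!nrow(eps)) return(empty)
  }
  days <- eps[, .(date = data.table::as.IDate(
                    seq.int(as.integer(start_date), as.integer(end_date)))),
              by = .(resident_id, episode_id)]
  days[, day_index := seq_len(.N), by = .(resident_id, episode_id)]
  days[, `:=`(enrolled = NA_integer_, snf = NA_integer_,
              hospital = NA_integer_)]
  days[]
}

#' Remove out-of-facility gap days from a day grid
#'
#' Episodes bridged by a reentry within the 30-day window retain, by
#' default, the days between the return-anticipated discharge and the
#' reentry (they are usually removed downstream as hospital days anyway).
#' This applies the stricter convention
#' (`drop_out_of_facility_gaps = TRUE`): grid days falling inside a
#' bridged gap are removed outright. `day_index` keeps its
#' days-since-episode-start meaning, so remaining dates within an
#' episode are no longer necessarily consecutive.
#'
#' @param days day grid.
#' @param gaps gap table (`resident_id`, `gap_start`, `gap_end`), as in
#'   the `bridged_gaps` attribute of [build_admission_episodes()].
#' @return the day grid without gap days.
#' @export
drop_gap_days <- function(days, gaps) {
  days <- data.table::as.data.table(days)
  gaps <- data.table::as.data.table(gaps)
  if (!nrow(days) || !nrow(gaps)) return(days)
  days[, idx := .I]
  hit <- days[gaps, on = .(resident_id, date >= gap_start, date <= gap_end),
              x.idx, nomatch = NULL]
  out <- if (length(hit)) days[-unique(hit)] else days
  out[, idx := NULL]
  out[]
}

#' Flag resident-days meeting the Medicare enrollment criteria
#'
#' A day is enrolled when its calendar month carries Part A, Part B and
#' Part D coverage and no managed-care flag. Months absent from the
#' enrollment table are conservatively unenrolled: observability is never
#' claimed without evidence. With `granularity = "daily"` the enrollment
#' table instead holds date intervals (`start_date`, `end_date`, same
#' four indicators) and days are matched by interval.
#'
#' @param days day-grid data.table.
#' @param enrollment monthly enrollment table (see [nh_tables()]), or a
#'   daily-interval table when `granularity = "daily"`.
#' @param granularity `"month"` (default) or `"daily"`.
#' @return the day grid with `enrolled` populated (a copy).
#' @export
flag_enrollment <- function(days, enrollment, granularity = c("month", "daily")) {
  granularity <- match.arg(granularity)
  days <- data.table::copy(data.table::as.data.table(days))
  enr <- data.table::as.data.table(enrollment)
  if (!nrow(days)) { days[, enrolled := integer(0)]; return(days[]) }
  days[, enrolled := 0L]
  if (!nrow(enr)) return(days[])
  if (granularity == "month") {
    dup <- enr[, .N, by = .(resident_id, year_month)][N > 1]
    if (nrow(dup)) {
      stop(sprintf("flag_enrollment: duplicate resident-month rows: %s",
                   paste(sprintf("%s/%s", dup$resident_id, dup$year_month),
                         collapse = ", ")), call. = FALSE)
    }
    ok <- enr[part_a == 1L & part_b == 1L & part_d == 1L & managed_care == 0L,
              .(resident_id, year_month)]
    days[, ym := month_key(date)]
    days[ok, enrolled := 1L, on = c("resident_id", ym = "year_month")]
    days[, ym := NULL]
  } else {
    ok <- enr[part_a == 1L & part_b == 1L & part_d == 1L & managed_care == 0L]
    ok[, `:=`(start_date = as_nh_date(start_date, "start_date"),
              end_date = as_nh_date(end_date, "end_date"))]
    days[, idx := .I]
    hit <- days[ok, on = .(resident_id, date >= start_date, date <= end_date),
                x.idx, nomatch = NULL]
    if (length(hit)) data.table::set(days, unique(hit), "enrolled", 1L)
    days[, idx := NULL]
  }
  days[]
}

#' Flag resident-days covered by Part A stays
#'
#' Sets the `snf` or `hospital` flag to 1 on every grid day that falls
#' inside a stay of the requested type, under the half-open convention
#' `admit <= day < discharge` (`include_discharge_day = TRUE` makes the
#' interval closed). Overlapping stays of the same type act as their
#' union. Stays with a discharge date before the admission date are
#' rejected (returned in the `rejected` attribute, with a warning);
#' stays with a missing discharge date are a precondition error — impute
#' first.
#'
#' @param days day-grid data.table.
#' @param stays imputed Part A stay table.
#' @param type `"snf"` or `"inpatient"` (flags `snf` / `hospital`).
#' @param include_discharge_day logical, default `FALSE`.
#' @return the day grid with the corresponding flag populated (a copy).
#' @export
flag_part_a_stays <- function(days, stays, type = c("snf", "inpatient"),
                              include_discharge_day = FALSE) {
  type <- match.arg(type)
  col <- if (type == "snf") "snf" else "hospital"
  days <- data.table::copy(data.table::as.data.table(days))
  if (!nrow(days)) { days[, (col) := integer(0)]; return(days[]) }
  data.table::set(days, NULL, col, 0L)
  st <- data.table::as.data.table(stays)
  st <- st[stay_type == type]
  if (!nrow(st)) return(days[])
  if (anyNA(st$discharge_date)) {
    stop("flag_part_a_stays: missing discharge dates; run impute_part_a_discharge() first",
         call. = FALSE)
  }
  bad <- st[discharge_date < admit_date]
  if (nrow(bad)) {
    warning(sprintf("flag_part_a_stays: rejected %d %s stay(s) with discharge before admission",
                    nrow(bad), type), call. = FALSE)
    st <- st[discharge_date >= admit_date]
  }
  days[, idx := .I]
  hit <- if (include_discharge_day) {
    days[st, on = .(resident_id, date >= admit_date, date <= discharge_date),
         x.idx, nomatch = NULL]
  } else {
    days[st, on = .(resident_id, date >= admit_date, date < discharge_date),
         x.idx, nomatch = NULL]
  }
  if (length(hit)) data.table::set(days, unique(hit), col, 1L)
  days[, idx := NULL]
  data.table::setattr(days, "rejected", bad)
  days[]
}

#' Run Steps 2-4 on a day grid in one call
#'
#' Imputes missing Part A discharge dates, then populates the `enrolled`,
#' `snf` and `hospital` flags. Flag assignments are independent: the
#' result does not depend on the order in which the three flags are set.
#'
#' @param days day grid from [expand_to_days()].
#' @param tables an [nh_tables()] bundle.
#' @param include_discharge_day see [flag_part_a_stays()].
#' @param enrollment_granularity see [flag_enrollment()].
#' @return fully flagged day grid.
#' @export
#' @examples
#' fx <- make_fixture("figure1_schematic")
#' days <- expand_to_days(build_episodes(fx))
#' classify_days(days, fx)
classify_days <- function(days, tables, include_discharge_day = FALSE,
                          enrollment_granularity = "month") {
  stays <- impute_part_a_discharge(tables$part_a_stays)
  days <- flag_enrollment(days, tables$enrollment,
                          granularity = enrollment_granularity)
  days <- flag_part_a_stays(days, stays, "snf",
                            include_discharge_day = include_discharge_day)
  days <- flag_part_a_stays(days, stays, "inpatient",
                            include_discharge_day = include_discharge_day)
  days[]
}
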