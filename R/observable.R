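# Step 5: remove unobservable days and rebuild maximal contiguous
# periods of observable medication use time.

#' Default time-since-admission bins
#'
#' The reporting bins partition `day_index >= 1`: days 1-30, 31-60,
#' 61-100, and 101+ since NH admission (day 101 being the conventional
#' long-stay boundary, since Part A covers at most the first 100 SNF
#' days).
#'
#' @return data.table with `label`, `lower`, `upper` (upper `NA` for the
#'   open 101+ bin).
#' @export
#' @examples
#' nh_time_bins()
nh_time_bins <- function() {
  data.table(label = c("1-30", "31-60", "61-100", "101+"),
             lower = c(1L, 31L, 61L, 101L),
             upper = c(30L, 60L, 100L, NA_integer_))
}

#' Label each day with its time-since-admission bin
#'
#' @param days day grid with `day_index` populated.
#' @param bins bin table as from [nh_time_bins()].
#' @return the day grid with a `bin` column (a copy).
#' @export
assign_time_bins <- function(days, bins = nh_time_bins()) {
  days <- data.table::copy(data.table::as.data.table(days))
  if (!nrow(days)) { days[, bin := character(0)]; return(days[]) }
  if (anyNA(days$day_index) || any(days$day_index < 1L)) {
    stop("assign_time_bins: day_index must be a positive integer", call. = FALSE)
  }
  breaks <- c(bins$lower, Inf)
  days[, bin := bins$label[findInterval(day_index, breaks)]]
  days[]
}

#' Keep only days with observable medication use
#'
#' A day is observable when the resident is enrolled (`enrolled = 1`) and
#' the day is neither SNF-covered (`snf = 0`) nor spent hospitalized
#' (`hospital = 0`). Removal counts by reason are attached as attribute
#' `removal_counts`: `unenrolled` counts days failing the enrollment
#' criterion; `snf` and `hospital` count *enrolled* days carrying the
#' respective flag, mirroring stepwise attrition accounting, so a single
#' enrolled day in SNF care during a hospitalization increments both.
#'
#' @param days fully flagged day grid.
#' @return observable-day subset of the grid (attribute
#'   `removal_counts`).
#' @export
select_observable_days <- function(days) {
  days <- data.table::as.data.table(days)
  if (nrow(days) &&
      (anyNA(days$enrolled) || anyNA(days$snf) || anyNA(days$hospital))) {
    stop("select_observable_days: flags not fully populated; run classify_days() first",
         call. = FALSE)
  }
  counts <- c(
    unenrolled = sum(days$enrolled == 0L),
    snf = sum(days$enrolled == 1L & days$snf == 1L),
    hospital = sum(days$enrolled == 1L & days$hospital == 1L)
  )
  out <- days[enrolled == 1L & snf == 0L & hospital == 0L]
  data.table::setattr(out, "removal_counts", counts)
  out[]
}

#' Rebuild maximal contiguous observable episodes
#'
#' Within each (resident, parent NH episode), maximal runs of consecutive
#' calendar dates among the observable days become one observable episode
#' each — no gap, even a single day, is bridged, and runs never span two
#' parent episodes (so a discharge/readmission boundary always splits,
#' even across adjacent dates). The day counts over all episodes sum to
#' the number of input rows.
#'
#' @param days output of [select_observable_days()].
#' @return data.table with `resident_id`, `episode_id`,
#'   `observable_episode_id`, `start_date`, `end_date`, `n_days`.
#' @export
#' @examples
#' fx <- make_fixture("figure1_schematic")
#' days <- classify_days(expand_to_days(build_episodes(fx)), fx)
#' build_observable_episodes(select_observable_days(days))
build_observable_episodes <- function(days) {
  days <- data.table::as.data.table(days)
  if (!nrow(days)) {
    return(data.table(resident_id = character(0), episode_id = character(0),
                      observable_episode_id = character(0),
                      start_date = data.table::as.IDate(integer(0)),
                      end_date = data.table::as.IDate(integer(0)),
                      n_days = integer(0)))
  }
  d <- days[order(resident_id, episode_id, date)]
  # consecutive dates share a constant (date - running index) offset
  d[, run_id := cumsum(c(1L, diff(as.integer(date)) != 1L)),
    by = .(resident_id, episode_id)]
  out <- d[, .(start_date = min(date), end_date = max(date), n_days = .N),
           by = .(resident_id, episode_id, run_id)]
  out[, observable_episode_id := sprintf("%s-O%02d", episode_id, run_id)]
  out[, run_id := NULL]
  data.table::setcolorder(out, c("resident_id", "episode_id",
                                 "observable_episode_id", "start_date",
                                 "end_date", "n_days"))
  out[]
}
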