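# Step 1: nursing-home episode construction from MDS-style records.
#
# Two anchorings are supported. Entry-anchored episodes pair each MDS
# entry record with the next discharge record and capture the maximum
# MDS-based NH time. Admission-assessment-anchored episodes require an
# admission assessment and apply the A0310F end rules: codes 10/12 end
# the episode outright; code 11 (return anticipated) ends it only if no
# reentry occurs within 30 days.

new_episode_table <- function(resident_id = character(0),
                              anchor = character(0),
                              start_date = data.table::as.IDate(integer(0)),
                              end_date = data.table::as.IDate(integer(0)),
                              end_reason = character(0),
                              admission_assessment_date = data.table::as.IDate(integer(0))) {
  data.table(resident_id = resident_id, anchor = anchor,
             start_date = data.table::as.IDate(start_date),
             end_date = data.table::as.IDate(end_date),
             end_reason = end_reason,
             admission_assessment_date = data.table::as.IDate(admission_assessment_date))
}

# canonical within-day processing order: an entry precedes an assessment
# precedes a discharge on the same calendar date, so an entry/discharge
# tie yields a 1-day episode
kind_rank <- function(kind) {
  match(kind, c("entry", "admission_assessment", "other_assessment", "discharge"))
}

sort_mds <- function(records) {
  rec <- data.table::as.data.table(records)
  rec[, event_date := as_nh_date(event_date, "event_date")]
  rec[order(resident_id, event_date, kind_rank(record_kind))]
}

#' Build entry-anchored nursing-home episodes
#'
#' Each MDS entry record opens an episode that ends at the next discharge
#' record on or after it; an entry with no subsequent discharge is taken
#' to mean the resident was still in the NH, and the episode closes at
#' the last day of the study period (`end_reason = "study_end"`).
#' Discharge records with no preceding entry are skipped; their count is
#' attached as attribute `n_orphan_discharges` and reported via
#' `message()`.
#'
#' Episodes from consecutive entries may overlap (two entries before one
#' discharge both pair with that discharge); resolve with
#' [merge_overlapping_episodes()].
#'
#' @param records MDS-style record table (see [nh_tables()]).
#' @param study_end last day of the study period.
#' @return an episode data.table (`resident_id`, `anchor`, `start_date`,
#'   `end_date`, `end_reason`, `admission_assessment_date`).
#' @export
build_entry_episodes <- function(records, study_end) {
  study_end <- as_nh_date(study_end, "study_end")
  rec <- sort_mds(records)
  if (!nrow(rec)) return(new_episode_table())

  out <- rec[, {
    entries <- sort(as.integer(event_date[record_kind == "entry"]))
    discharges <- sort(as.integer(event_date[record_kind == "discharge"]))
    if (length(entries)) {
      # first discharge on/after each entry
      idx <- findInterval(entries - 1L, discharges) + 1L
      has_d <- idx <= length(discharges)
      end <- ifelse(has_d, discharges[pmin(idx, length(discharges))],
                    as.integer(study_end))
      list(start_date = data.table::as.IDate(entries),
           end_date = data.table::as.IDate(as.integer(end)),
           end_reason = ifelse(has_d, "final_discharge", "study_end"))
    } else {
      list(start_date = data.table::as.IDate(integer(0)),
           end_date = data.table::as.IDate(integer(0)),
           end_reason = character(0))
    }
  }, by = resident_id]
  out[, `:=`(anchor = "entry",
             admission_assessment_date = data.table::as.IDate(NA))]
  data.table::setcolorder(out, c("resident_id", "anchor", "start_date",
                                 "end_date", "end_reason",
                                 "admission_assessment_date"))

  n_orphan <- rec[, {
    e <- as.integer(event_date[record_kind == "entry"])
    d <- as.integer(event_date[record_kind == "discharge"])
    first_e <- if (length(e)) min(e) else NA_integer_
    list(n = if (is.na(first_e)) length(d) else sum(d < first_e))
  }, by = resident_id][, sum(n)]
  if (n_orphan > 0) {
    message(sprintf("build_entry_episodes: skipped %d discharge record(s) with no preceding entry", n_orphan))
  }
  data.table::setattr(out, "n_orphan_discharges", n_orphan)
  out[]
}

#' Build admission-assessment-anchored nursing-home episodes
#'
#' Episodes require an MDS admission assessment. The episode start is the
#' nearest entry record on or before the assessment (falling back to the
#' assessment date when none exists). An episode ends at:
#'
#' * a discharge with A0310F = 10 or 12 (return not anticipated), or
#' * a discharge with A0310F = 11 (return anticipated) with no reentry
#'   within 30 days — a reentry record dated at most 30 days after the
#'   discharge (`reentry - discharge <= 30`, both endpoints inclusive)
#'   continues the same episode, a later return requires a new admission
#'   assessment to open a new episode.
#'
#' An admission assessment with no entry and no discharge is closed at
#' `study_end` like any open episode. Discharges with a missing or
#' non-11 disposition code end the episode as a final discharge.
#' Multiple admission assessments within one continuing episode do not
#' split it: only the first anchors.
#'
#' @inheritParams build_entry_episodes
#' @param reentry_window maximum discharge-to-reentry gap, in days, that
#'   continues the same episode (default 30, per MDS/CMS guidance).
#' @return an episode data.table; `admission_assessment_date` carries the
#'   anchoring assessment.
#' @export
build_admission_episodes <- function(records, study_end, reentry_window = 30L) {
  study_end <- as_nh_date(study_end, "study_end")
  rec <- sort_mds(records)
  if (!nrow(rec)) {
    out <- new_episode_table()
    data.table::setattr(out, "bridged_gaps",
                        data.table(resident_id = character(0),
                                   gap_start = data.table::as.IDate(integer(0)),
                                   gap_end = data.table::as.IDate(integer(0))))
    return(out)
  }

  n_orphan <- 0L
  gap_res <- character(0); gap_s <- integer(0); gap_e <- integer(0)
  out <- rec[, {
    kinds <- record_kind; dates <- as.integer(event_date); codes <- disposition_code
    starts <- integer(0); ends <- integer(0); reasons <- character(0)
    assess <- integer(0)
    state <- "out"; pending_entry <- NA_integer_
    cur_start <- NA_integer_; cur_assess <- NA_integer_; pend_disc <- NA_integer_

    close_ep <- function(end, reason) {
      starts <<- c(starts, cur_start); ends <<- c(ends, end)
      reasons <<- c(reasons, reason); assess <<- c(assess, cur_assess)
      state <<- "out"; cur_start <<- NA_integer_; cur_assess <<- NA_integer_
    }
    open_ep <- function(assess_date) {
      cur_start <<- if (!is.na(pending_entry)) pending_entry else assess_date
      cur_assess <<- assess_date; pending_entry <<- NA_integer_; state <<- "in"
    }

    for (i in seq_along(kinds)) {
      k <- kinds[i]; d <- dates[i]
      if (k == "entry") {
        if (state == "awaiting") {
          if (d - pend_disc <= reentry_window) {
            state <- "in"                         # reentry: same episode
            if (d - pend_disc >= 2L) {            # out-of-facility gap days
              gap_res <<- c(gap_res, resident_id[1L])
              gap_s <<- c(gap_s, pend_disc + 1L)
              gap_e <<- c(gap_e, d - 1L)
            }
          } else {
            close_ep(pend_disc, "reentry_window_expired")
            pending_entry <- d                    # candidate start for next episode
          }
        } else if (state == "out") {
          pending_entry <- d
        }                                         # entry while "in": no-op
      } else if (k == "admission_assessment") {
        if (state == "awaiting") {
          close_ep(pend_disc, "reentry_window_expired")
          open_ep(d)
        } else if (state == "out") {
          open_ep(d)
        }                                         # later assessments do not re-anchor
      } else if (k == "discharge") {
        if (state == "in") {
          if (!is.na(codes[i]) && codes[i] == 11L) {
            state <- "awaiting"; pend_disc <- d
          } else {
            close_ep(d, "final_discharge")
          }
        } else if (state == "out") {
          n_orphan <<- n_orphan + 1L
        }                                         # extra discharge while awaiting: no-op
      }
    }
    if (state == "in") close_ep(as.integer(study_end), "study_end")
    if (state == "awaiting") close_ep(pend_disc, "reentry_window_expired")

    list(start_date = data.table::as.IDate(starts),
         end_date = data.table::as.IDate(ends),
         end_reason = reasons,
         admission_assessment_date = data.table::as.IDate(assess))
  }, by = resident_id]

  if (n_orphan > 0) {
    message(sprintf("build_admission_episodes: skipped %d discharge record(s) outside any anchored episode", n_orphan))
  }
  out[, anchor := "admission_assessment"]
  data.table::setcolorder(out, c("resident_id", "anchor", "start_date",
                                 "end_date", "end_reason",
                                 "admission_assessment_date"))
  data.table::setattr(out, "n_orphan_discharges", n_orphan)
  data.table::setattr(out, "bridged_gaps",
                      data.table(resident_id = gap_res,
                                 gap_start = data.table::as.IDate(gap_s),
                                 gap_end = data.table::as.IDate(gap_e)))
  out[]
}

#' Merge overlapping nursing-home episodes
#'
#' Two episodes of the same resident and anchor type overlap when one's
#' start (entry) date falls on or before the other's end (discharge)
#' date; overlap chains collapse to a single episode spanning the first
#' start to the last end. Adjacent-but-disjoint episodes (start the day
#' after an end) are not merged. The merged episode keeps the end reason
#' of the member contributing the final end date and the earliest
#' admission assessment date. Merging is idempotent and insensitive to
#' input order.
#'
#' @param episodes episode data.table as built by the `build_*` functions.
#' @return merged, pairwise-disjoint episode data.table, sorted by
#'   resident, anchor and start date.
#' @export
merge_overlapping_episodes <- function(episodes) {
  eps <- data.table::as.data.table(episodes)
  if (!nrow(eps)) return(new_episode_table())
  eps <- eps[order(resident_id, anchor, start_date, end_date)]
  eps[, cum_end := shift(cummax(as.integer(end_date))),
      by = .(resident_id, anchor)]
  eps[, new_run := is.na(cum_end) | as.integer(start_date) > cum_end]
  eps[, grp := cumsum(new_run), by = .(resident_id, anchor)]
  merged <- eps[, .(
    start_date = min(start_date),
    end_date = max(end_date),
    end_reason = end_reason[which.max(as.integer(end_date))],
    admission_assessment_date =
      if (all(is.na(admission_assessment_date))) data.table::as.IDate(NA)
      else min(admission_assessment_date, na.rm = TRUE)
  ), by = .(resident_id, anchor, grp)]
  merged[, grp := NULL]
  data.table::setcolorder(merged, c("resident_id", "anchor", "start_date",
                                    "end_date", "end_reason",
                                    "admission_assessment_date"))
  merged[]
}

#' Truncate episodes at death and clip to the study window
#'
#' Applies the final Step-1 rules: any episode ending after the
#' resident's recorded death is truncated to the death date
#' (`end_reason = "death"`); episodes that start after death are dropped
#' with a warning; ends beyond `study_end` are clipped to `study_end`.
#' Surviving episodes get a stable `episode_id`
#' (`<resident_id>-E<sequence>` in start-date order).
#'
#' @param episodes merged episode data.table.
#' @param deaths data.table with `resident_id`, `death_date` (residents
#'   without a row are assumed alive through `study_end`).
#' @param study_end last day of the study period.
#' @return finalized episode data.table with `episode_id`.
#' @export
finalize_episodes <- function(episodes, deaths, study_end) {
  study_end <- as_nh_date(study_end, "study_end")
  eps <- data.table::copy(data.table::as.data.table(episodes))
  if (!nrow(eps)) {
    out <- new_episode_table()
    out[, episode_id := character(0)]
    return(out[])
  }
  deaths <- data.table::as.data.table(deaths)
  if (nrow(deaths)) {
    eps[deaths, death_date := i.death_date, on = "resident_id"]
  } else {
    eps[, death_date := data.table::as.IDate(NA)]
  }
  dropped <- eps[!is.na(death_date) & start_date > death_date]
  if (nrow(dropped)) {
    warning(sprintf("finalize_episodes: dropped %d episode(s) starting after the recorded death date (residents: %s)",
                    nrow(dropped),
                    paste(unique(dropped$resident_id), collapse = ", ")),
            call. = FALSE)
    eps <- eps[is.na(death_date) | start_date <= death_date]
  }
  eps[!is.na(death_date) & end_date > death_date,
      `:=`(end_date = death_date, end_reason = "death")]
  eps[end_date > study_end, `:=`(end_date = study_end, end_reason = "study_end")]
  eps[, death_date := NULL]
  eps <- eps[order(resident_id, anchor, start_date)]
  eps[, episode_id := sprintf("%s-E%02d", resident_id, seq_len(.N)),
      by = .(resident_id, anchor)]
  eps[]
}

#' Build, merge and finalize episodes in one call
#'
#' Convenience wrapper running the full Step-1 chain for one anchoring.
#'
#' @param tables an [nh_tables()] bundle.
#' @param anchor `"admission_assessment"` (default, the reporting basis)
#'   or `"entry"`.
#' @param reentry_window see [build_admission_episodes()].
#' @return finalized episode data.table with `episode_id`.
#' @export
#' @examples
#' fx <- make_fixture("figure1_schematic")
#' build_episodes(fx)
build_episodes <- function(tables,
                           anchor = c("admission_assessment", "entry"),
                           reentry_window = 30L) {
  anchor <- match.arg(anchor)
  raw <- if (anchor == "entry") {
    build_entry_episodes(tables$mds, tables$study_end)
  } else {
    build_admission_episodes(tables$mds, tables$study_end, reentry_window)
  }
  out <- finalize_episodes(merge_overlapping_episodes(raw), tables$deaths,
                           tables$study_end)
  data.table::setattr(out, "bridged_gaps", attr(raw, "bridged_gaps"))
  out
}
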