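# Hand-auditable fixtures. Each is tiny (<= 2 residents), fully enrolled
# unless stated, and carries its hand-computed expected observable-day
# total as attribute "expected_observable_days" (admission-anchored,
# default conventions).

mds_row <- function(rid, kind, date, code = NA_integer_) data.table(
  resident_id = rid, record_kind = kind,
  event_date = data.table::as.IDate(date), disposition_code = as.integer(code))

stay_row <- function(rid, type, admit, discharge, los = NULL) {
  a <- data.table::as.IDate(admit)
  d <- data.table::as.IDate(discharge)
  data.table(resident_id = rid, stay_type = type, admit_date = a,
             discharge_date = d,
             length_of_stay = if (is.null(los)) as.integer(d - a) else as.integer(los))
}

enrollment_full <- function(ids, start, end) {
  months <- format(seq(as.Date(start), as.Date(end), by = "1 month"), "%Y-%m")
  grid <- data.table::CJ(resident_id = ids, year_month = months)
  grid[, `:=`(part_a = 1L, part_b = 1L, part_d = 1L, managed_care = 0L)]
  grid[]
}

#' Deterministic hand-auditable fixture cohorts
#'
#' Returns a small linked-table set whose observable-day arithmetic can be
#' checked by hand. Available fixtures (admission-anchored expected
#' observable days in parentheses, also attached as attribute
#' `expected_observable_days`):
#'
#' * `"figure1_schematic"` (157): one resident, entry 2017-03-01 with a
#'   20-day SNF lead-in, a 7-day mid-stay hospitalization (May 10-16), and
#'   a terminal discharge 2017-08-31. The 184-day episode loses 27 flagged
#'   days, leaving observable runs of 50 (Mar 21 - May 9) and 107
#'   (May 17 - Aug 31) days.
#' * `"reentry_30d"` (210): resident R1 has a return-anticipated discharge
#'   (A0310F = 11) with reentry exactly 30 days later (same episode, 120
#'   observable days); R2 the same with a 31-day gap, splitting into a
#'   32-day and a 58-day episode (90 observable days).
#' * `"overlap_merge"` (41 entry-anchored, 31 admission-anchored): two
#'   entry/discharge pairs where the second entry (Jan 20) precedes the
#'   first discharge (Jan 31); entry-anchored episodes merge to
#'   Jan 1 - Feb 10.
#' * `"open_episode"` (61): entry 2020-11-01 with no discharge record; the
#'   episode closes at study end 2020-12-31.
#' * `"death_truncation"` (41): an episode truncated from Jun 1 back to a
#'   death on Apr 10 (41 days); a second resident whose recorded death
#'   precedes the episode start, which is dropped.
#' * `"missing_discharge"` (78): a 92-day episode whose 14-day SNF
#'   lead-in stay has a blanked discharge date (length of stay 14), so
#'   imputation must restore discharge = admit + 14 before flagging.
#'
#' @param name fixture identifier.
#' @return an [nh_tables()] bundle with attribute
#'   `expected_observable_days`.
#' @export
#' @examples
#' fx <- make_fixture("figure1_schematic")
#' attr(fx, "expected_observable_days")
make_fixture <- function(name) {
  catalog <- c("figure1_schematic", "reentry_30d", "overlap_merge",
               "open_episode", "death_truncation", "missing_discharge")
  if (!is.character(name) || length(name) != 1L || !(name %in% catalog)) {
    stop(sprintf("unknown fixture '%s'; available fixtures: %s",
                 as.character(name)[1], paste(catalog, collapse = ", ")),
         call. = FALSE)
  }
  fx <- switch(name,
    figure1_schematic = {
      mds <- rbind(
        mds_row("F1", "entry", "2017-03-01"),
        mds_row("F1", "admission_assessment", "2017-03-03"),
        mds_row("F1", "discharge", "2017-08-31", 10L))
      stays <- rbind(
        stay_row("F1", "snf", "2017-03-01", "2017-03-21"),
        stay_row("F1", "inpatient", "2017-05-10", "2017-05-17"))
      tb <- nh_tables(mds, enrollment_full("F1", "2017-01-01", "2017-12-31"),
                      stays, empty_dispensings(), empty_deaths(),
                      "2017-01-01", "2017-12-31")
      structure(tb, expected_observable_days = 157L)
    },
    reentry_30d = {
      mds <- rbind(
        mds_row("R1", "entry", "2017-01-01"),
        mds_row("R1", "admission_assessment", "2017-01-01"),
        mds_row("R1", "discharge", "2017-02-01", 11L),
        mds_row("R1", "entry", "2017-03-03"),          # 30-day gap: same episode
        mds_row("R1", "discharge", "2017-04-30", 10L),
        mds_row("R2", "entry", "2017-01-01"),
        mds_row("R2", "admission_assessment", "2017-01-01"),
        mds_row("R2", "discharge", "2017-02-01", 11L),
        mds_row("R2", "entry", "2017-03-04"),          # 31-day gap: new admission
        mds_row("R2", "admission_assessment", "2017-03-05"),
        mds_row("R2", "discharge", "2017-04-30", 10L))
      tb <- nh_tables(mds, enrollment_full(c("R1", "R2"), "2017-01-01", "2017-12-31"),
                      empty_stays(), empty_dispensings(), empty_deaths(),
                      "2017-01-01", "2017-12-31")
      structure(tb, expected_observable_days = 210L)
    },
    overlap_merge = {
      mds <- rbind(
        mds_row("O1", "entry", "2017-01-01"),
        mds_row("O1", "admission_assessment", "2017-01-02"),
        mds_row("O1", "discharge", "2017-01-31", 10L),
        mds_row("O1", "entry", "2017-01-20"),
        mds_row("O1", "discharge", "2017-02-10", 10L))
      tb <- nh_tables(mds, enrollment_full("O1", "2017-01-01", "2017-12-31"),
                      empty_stays(), empty_dispensings(), empty_deaths(),
                      "2017-01-01", "2017-12-31")
      structure(tb, expected_observable_days = 31L)
    },
    open_episode = {
      mds <- rbind(
        mds_row("P1", "entry", "2020-11-01"),
        mds_row("P1", "admission_assessment", "2020-11-02"))
      tb <- nh_tables(mds, enrollment_full("P1", "2020-01-01", "2020-12-31"),
                      empty_stays(), empty_dispensings(), empty_deaths(),
                      "2020-01-01", "2020-12-31")
      structure(tb, expected_observable_days = 61L)
    },
    death_truncation = {
      mds <- rbind(
        mds_row("D1", "entry", "2017-03-01"),
        mds_row("D1", "admission_assessment", "2017-03-01"),
        mds_row("D1", "discharge", "2017-06-01", 10L),
        mds_row("D2", "entry", "2017-05-01"),
        mds_row("D2", "admission_assessment", "2017-05-01"),
        mds_row("D2", "discharge", "2017-06-01", 10L))
      deaths <- data.table(
        resident_id = c("D1", "D2"),
        death_date = data.table::as.IDate(c("2017-04-10", "2017-04-10")))
      tb <- nh_tables(mds, enrollment_full(c("D1", "D2"), "2017-01-01", "2017-12-31"),
                      empty_stays(), empty_dispensings(), deaths,
                      "2017-01-01", "2017-12-31")
      structure(tb, expected_observable_days = 41L)
    },
    missing_discharge = {
      mds <- rbind(
        mds_row("M1", "entry", "2017-05-01"),
        mds_row("M1", "admission_assessment", "2017-05-01"),
        mds_row("M1", "discharge", "2017-07-31", 10L))
      stays <- stay_row("M1", "snf", "2017-05-01", NA, los = 14L)
      tb <- nh_tables(mds, enrollment_full("M1", "2017-01-01", "2017-12-31"),
                      stays, empty_dispensings(), empty_deaths(),
                      "2017-01-01", "2017-12-31")
      structure(tb, expected_observable_days = 78L)
    })
  fx
}
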