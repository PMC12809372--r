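#' Bundle the four linked claims tables
#'
#' Container for a linked synthetic (or user-supplied) cohort: MDS-style
#' tracking/assessment records, monthly enrollment summary, Part A stay
#' records, drug dispensings, and a death-date table, together with the
#' study window that bounds every date.
#'
#' @param mds data.table with columns `resident_id`, `record_kind`
#'   (`entry` / `discharge` / `admission_assessment` / `other_assessment`),
#'   `event_date`, `disposition_code` (10/11/12, present only on
#'   discharges).
#' @param enrollment data.table with `resident_id`, `year_month`
#'   ("YYYY-MM"), `part_a`, `part_b`, `part_d`, `managed_care` (0/1).
#' @param part_a_stays data.table with `resident_id`, `stay_type`
#'   (`snf` / `inpatient`), `admit_date`, `discharge_date` (may be NA),
#'   `length_of_stay`.
#' @param dispensings data.table with `resident_id`, `drug_class`,
#'   `fill_date`, `days_supply`.
#' @param deaths data.table with `resident_id`, `death_date`.
#' @param study_start,study_end study window.
#' @return a list with class `"nh_tables"`.
#' @export
nh_tables <- function(mds, enrollment, part_a_stays, dispensings, deaths,
                      study_start, study_end) {
  structure(list(
    mds = data.table::as.data.table(mds),
    enrollment = data.table::as.data.table(enrollment),
    part_a_stays = data.table::as.data.table(part_a_stays),
    dispensings = data.table::as.data.table(dispensings),
    deaths = data.table::as.data.table(deaths),
    study_start = as_nh_date(study_start, "study_start"),
    study_end = as_nh_date(study_end, "study_end")
  ), class = "nh_tables")
}

#' @export
print.nh_tables <- function(x, ...) {
  cat(sprintf("<nh_tables> %s .. %s\n", x$study_start, x$study_end))
  cat(sprintf("  mds: %d records (%d residents) | enrollment: %d resident-months\n",
              nrow(x$mds), data.table::uniqueN(x$mds$resident_id),
              nrow(x$enrollment)))
  cat(sprintf("  part_a_stays: %d (%d snf, %d inpatient) | dispensings: %d | deaths: %d\n",
              nrow(x$part_a_stays), sum(x$part_a_stays$stay_type == "snf"),
              sum(x$part_a_stays$stay_type == "inpatient"),
              nrow(x$dispensings), nrow(x$deaths)))
  invisible(x)
}

empty_mds <- function() data.table(
  resident_id = character(0), record_kind = character(0),
  event_date = data.table::as.IDate(integer(0)), disposition_code = integer(0))

empty_enrollment <- function() data.table(
  resident_id = character(0), year_month = character(0),
  part_a = integer(0), part_b = integer(0), part_d = integer(0),
  managed_care = integer(0))

empty_stays <- function() data.table(
  resident_id = character(0), stay_type = character(0),
  admit_date = data.table::as.IDate(integer(0)),
  discharge_date = data.table::as.IDate(integer(0)),
  length_of_stay = integer(0))

empty_dispensings <- function() data.table(
  resident_id = character(0), drug_class = character(0),
  fill_date = data.table::as.IDate(integer(0)), days_supply = integer(0))

empty_deaths <- function() data.table(
  resident_id = character(0), death_date = data.table::as.IDate(integer(0)))

#' Generate a linked synthetic nursing-home cohort
#'
#' Simulates the four linked tables consumed by the episode builder and
#' day classifier, with the structural features the algorithm must handle:
#' Part A skilled-nursing lead-ins capped at 100 days, mid-episode
#' hospitalizations (optionally followed by fresh post-acute SNF stays),
#' discharge-with-return-anticipated/reentry pairs on both sides of the
#' 30-day boundary, monthly enrollment churn and managed-care flags,
#' deaths shortly after final discharge or inside open episodes, and a
#' configurable fraction of Part A stays with blanked discharge dates.
#'
#' Identical parameters (including the seed) reproduce identical tables.
#'
#' @param params a [sim_params()] object.
#' @return an [nh_tables()] bundle.
#' @export
#' @examples
#' cohort <- generate_cohort(sim_params(n_residents = 5, seed = 7))
#' cohort
generate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(params$seed)

  s0 <- as.integer(params$study_start)
  s1 <- as.integer(params$study_end)
  window_days <- s1 - s0 + 1L

  mds_l <- list(); stay_l <- list(); disp_l <- list(); death_l <- list()
  ids <- if (params$n_residents > 0) sprintf("R%06d", seq_len(params$n_residents)) else character(0)

  for (rid in ids) {
    n_adm <- 1L + rpois(1L, max(params$admission_rate - 1, 0))
    entry <- s0 + floor(runif(1) * max(window_days - 30L, 1L))
    adm_done <- 0L
    open_ended <- FALSE
    last_end <- NA_integer_
    rec_kind <- character(0); rec_date <- integer(0); rec_code <- integer(0)
    st_type <- character(0); st_admit <- integer(0); st_disc <- integer(0)
    st_los <- integer(0)

    add_rec <- function(kind, d, code = NA_integer_) {
      rec_kind <<- c(rec_kind, kind); rec_date <<- c(rec_date, as.integer(d))
      rec_code <<- c(rec_code, as.integer(code))
    }
    add_stay <- function(type, a, d) {
      a <- as.integer(a); d <- as.integer(d)
      if (a > s1 || d <= a) return(invisible(NULL))
      # a stay still running at study end has no discharge date in the
      # source record; length of stay is carried for imputation
      st_type <<- c(st_type, type); st_admit <<- c(st_admit, a)
      st_disc <<- c(st_disc, if (d > s1) NA_integer_ else d)
      st_los <<- c(st_los, d - a)
    }

    while (adm_done < n_adm && entry <= s1 && !open_ended) {
      L <- draw_duration(params$los_distribution, 1L, field = "los_distribution")
      end <- entry + L - 1L
      add_rec("entry", entry)
      assess <- min(entry + sample(0:7, 1L), end, s1)
      add_rec("admission_assessment", assess)

      # Part A SNF lead-in at admission, capped at 100 covered days and
      # never outlasting the NH episode itself
      if (runif(1) < params$snf_leadin_prob) {
        k <- min(draw_duration(params$snf_leadin_distribution, 1L, min_days = 0L,
                               field = "snf_leadin_distribution"), 100L, L)
        if (k > 0L) add_stay("snf", entry, entry + k)
      }

      continuation <- NA_integer_
      if (L >= 10L && runif(1) < params$reentry_prob) {
        d_int <- entry + 1L + floor(runif(1) * (L - 3L))
        g <- draw_duration(params$reentry_gap_distribution, 1L,
                           field = "reentry_gap_distribution")
        if (d_int + g <= s1) {
          add_rec("discharge", d_int, 11L)
          # the absence itself is usually a hospital transfer
          add_stay("inpatient", d_int, d_int + g)
          if (g <= 30L) {
            add_rec("entry", d_int + g)  # reentry: same episode continues
            end <- max(end, d_int + g)
          } else {
            end <- d_int          # reentry window expired: new admission later
            continuation <- d_int + g
          }
        }
      }

      # inpatient hospitalizations during the episode (rate per person-year)
      span <- end - entry + 1L
      n_h <- rpois(1L, params$hosp_rate * span / 365)
      if (n_h > 0L) {
        for (j in seq_len(n_h)) {
          ha <- entry + floor(runif(1) * span)
          hl <- draw_duration(params$hosp_length_distribution, 1L,
                              field = "hosp_length_distribution")
          add_stay("inpatient", ha, ha + hl)
          if (ha + hl <= end && runif(1) < params$post_hosp_snf_prob) {
            k2 <- min(draw_duration(params$snf_leadin_distribution, 1L, min_days = 0L,
                                    field = "snf_leadin_distribution"), 100L,
                      end - (ha + hl) + 1L)
            if (k2 > 0L) add_stay("snf", ha + hl, ha + hl + k2)
          }
        }
      }

      if (is.na(continuation)) {
        if (end > s1) {
          open_ended <- TRUE            # still in the NH at study end
          last_end <- s1
        } else {
          add_rec("discharge", end, sample(c(10L, 12L), 1L))
          last_end <- end
        }
        adm_done <- adm_done + 1L
        entry <- last_end + 31L + floor(runif(1) * 335)  # gap to next admission
      } else {
        last_end <- end
        adm_done <- adm_done + 1L
        entry <- continuation
      }
    }

    if (runif(1) < params$death_prob && !is.na(last_end)) {
      dd <- if (open_ended) {
        # death inside the open episode
        last_entry <- max(rec_date[rec_kind == "entry"])
        last_entry + floor(runif(1) * max(s1 - last_entry, 1L))
      } else {
        last_end + sample(0:30, 1L)
      }
      dd <- min(dd, s1)
      death_l[[length(death_l) + 1L]] <- data.table(
        resident_id = rid, death_date = data.table::as.IDate(as.integer(dd)))
    }

    mds_l[[length(mds_l) + 1L]] <- data.table(
      resident_id = rid, record_kind = rec_kind,
      event_date = data.table::as.IDate(rec_date), disposition_code = rec_code)
    if (length(st_type)) {
      stay_l[[length(stay_l) + 1L]] <- data.table(
        resident_id = rid, stay_type = st_type,
        admit_date = data.table::as.IDate(st_admit),
        discharge_date = data.table::as.IDate(st_disc),
        length_of_stay = st_los)
    }

    # dispensings: drug users fill repeatedly while in the NH
    if (runif(1) < params$dispensing_prob) {
      entries <- sort(rec_date[rec_kind == "entry"])
      if (length(entries)) {
        fd <- integer(0); sup <- integer(0)
        d <- entries[1L]
        stop_at <- min(if (is.na(last_end)) s1 else max(last_end, entries[length(entries)]), s1)
        while (d <= stop_at) {
          s <- sample(c(7L, 14L, 30L, 90L), 1L, prob = c(.15, .15, .5, .2))
          fd <- c(fd, d); sup <- c(sup, s)
          d <- d + s + sample(0:3, 1L)
        }
        disp_l[[length(disp_l) + 1L]] <- data.table(
          resident_id = rid, drug_class = params$drug_class,
          fill_date = data.table::as.IDate(fd), days_supply = sup)
      }
    }
  }

  mds <- if (length(mds_l)) data.table::rbindlist(mds_l) else empty_mds()
  stays <- if (length(stay_l)) data.table::rbindlist(stay_l) else empty_stays()
  disp <- if (length(disp_l)) data.table::rbindlist(disp_l) else empty_dispensings()
  deaths <- if (length(death_l)) data.table::rbindlist(death_l) else empty_deaths()
  data.table::setkey(mds, resident_id, event_date)

  enrollment <- simulate_enrollment(ids, params)
  stays <- inject_missing_discharges(stays, params$missing_discharge_frac,
                                     seed = params$seed + 1L)

  nh_tables(mds, enrollment, stays, disp, deaths,
            params$study_start, params$study_end)
}

# monthly A/B/D + managed-care indicators for every resident-month of the study
simulate_enrollment <- function(ids, params) {
  if (!length(ids)) return(empty_enrollment())
  months <- format(seq(as.Date(params$study_start), as.Date(params$study_end),
                       by = "1 month"), "%Y-%m")
  grid <- data.table::CJ(resident_id = ids, year_month = months)
  n <- nrow(grid)
  grid[, `:=`(part_a = 1L, part_b = 1L, part_d = 1L,
              managed_care = as.integer(runif(n) < params$managed_care_prob))]
  gap <- runif(n) < params$enrollment_gap_prob
  if (any(gap)) {
    which_part <- sample(c("part_a", "part_b", "part_d"), sum(gap),
                         replace = TRUE, prob = c(.2, .2, .6))
    for (p in c("part_a", "part_b", "part_d")) {
      rows <- which(gap)[which_part == p]
      if (length(rows)) data.table::set(grid, rows, p, 0L)
    }
  }
  grid[]
}

#' Blank the discharge date on a fraction of Part A stays
#'
#' Removes the discharge date from exactly `round(fraction * n)` stay
#' records (chosen by seeded sampling), keeping length of stay so the
#' dates can be re-imputed downstream by [impute_part_a_discharge()].
#' Input order is preserved.
#'
#' @param stays Part A stay data.table.
#' @param fraction proportion of rows to blank, in \[0, 1\].
#' @param seed integer seed for the row selection.
#' @return the stays table with blanked discharge dates (a copy).
#' @export
#' @examples
#' st <- make_fixture("figure1_schematic")$part_a_stays
#' inject_missing_discharges(st, 1, seed = 1)
inject_missing_discharges <- function(stays, fraction, seed = 1L) {
  check_prob(fraction, "fraction")
  stays <- data.table::copy(data.table::as.data.table(stays))
  n_blank <- round(fraction * nrow(stays))
  if (n_blank > 0L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    rows <- sample(nrow(stays), n_blank)
    data.table::set(stays, rows, "discharge_date", data.table::as.IDate(NA))
  }
  stays[]
}
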