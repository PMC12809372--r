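ep_row <- function(rid, start, end, eid = paste0(rid, "-E01"),
                   reason = "final_discharge") data.table::data.table(
  resident_id = rid, anchor = "admission_assessment",
  start_date = data.table::as.IDate(start),
  end_date = data.table::as.IDate(end),
  end_reason = reason,
  admission_assessment_date = data.table::as.IDate(NA),
  episode_id = eid)

stay <- function(rid, type, admit, discharge, los = NULL) data.table::data.table(
  resident_id = rid, stay_type = type,
  admit_date = data.table::as.IDate(admit),
  discharge_date = data.table::as.IDate(discharge),
  length_of_stay = if (is.null(los)) {
    as.integer(data.table::as.IDate(discharge) - data.table::as.IDate(admit))
  } else as.integer(los))

enr_month <- function(rid, ym, a = 1L, b = 1L, d = 1L, mc = 0L)
  data.table::data.table(resident_id = rid, year_month = ym, part_a = a,
                         part_b = b, part_d = d, managed_care = mc)

test_that("discharge-date imputation follows discharge = admit + length of stay", {
  st <- rbind(stay("A", "snf", "2016-05-01", NA, los = 14),
              stay("A", "snf", "2016-07-01", "2016-07-10"),
              stay("A", "snf", "2016-08-01", NA, los = 0))
  out <- quiet(impute_part_a_discharge(st))
  expect_identical(as.character(out$discharge_date),
                   c("2016-05-15", "2016-07-10", "2016-08-01"))
  expect_identical(attr(out, "n_imputed"), 2L)

  both_missing <- rbind(st, stay("A", "snf", "2016-09-01", NA, los = NA))
  expect_warning(out2 <- suppressMessages(impute_part_a_discharge(both_missing)),
                 "rejected 1")
  expect_identical(nrow(out2), 3L)
  expect_identical(nrow(attr(out2, "rejected")), 1L)
})

test_that("day expansion yields one row per calendar day with 1-based day index", {
  d3 <- expand_to_days(ep_row("A", "2016-01-01", "2016-01-03"))
  expect_identical(nrow(d3), 3L)
  expect_identical(d3$day_index, 1:3)
  expect_identical(nrow(expand_to_days(ep_row("A", "2016-01-01", "2016-01-01"))), 1L)

  eps <- rbind(ep_row("A", "2016-01-01", "2016-02-15"),
               ep_row("A", "2016-04-01", "2016-04-20", "A-E02"),
               ep_row("B", "2016-06-05", "2016-06-05", "B-E01"))
  days <- expand_to_days(eps)
  expect_identical(nrow(days),
                   sum(as.integer(eps$end_date) - as.integer(eps$start_date) + 1L))
  expect_true(all(days$day_index ==
                  as.integer(days$date) -
                  rep(as.integer(eps$start_date), times = c(46L, 20L, 1L)) + 1L))
})

test_that("overlapping episodes are rejected by day expansion", {
  eps <- rbind(ep_row("A", "2016-01-01", "2016-02-15"),
               ep_row("A", "2016-02-10", "2016-03-01", "A-E02"))
  expect_error(expand_to_days(eps), "merge_overlapping_episodes")
})

test_that("dropping the discharge day removes only final-discharge end dates", {
  eps <- rbind(ep_row("A", "2016-01-01", "2016-01-10"),
               ep_row("B", "2016-01-01", "2016-01-10", "B-E01", reason = "study_end"),
               ep_row("C", "2016-01-05", "2016-01-05", "C-E01"))
  days <- expand_to_days(eps, count_discharge_day = FALSE)
  expect_identical(nrow(days[days$resident_id == "A"]), 9L)
  expect_identical(nrow(days[days$resident_id == "B"]), 10L)  # not a discharge
  expect_identical(nrow(days[days$resident_id == "C"]), 0L)   # 1-day episode vanishes
})

test_that("enrollment flags require A+B+D without managed care, monthly granularity", {
  days <- expand_to_days(ep_row("A", "2016-01-15", "2016-03-15"))
  enr <- rbind(enr_month("A", "2016-01"),
               enr_month("A", "2016-03", d = 0L))  # February absent
  fl <- flag_enrollment(days, enr)
  jan <- fl[format(as.Date(fl$date), "%Y-%m") == "2016-01"]
  feb <- fl[format(as.Date(fl$date), "%Y-%m") == "2016-02"]
  mar <- fl[format(as.Date(fl$date), "%Y-%m") == "2016-03"]
  expect_true(all(jan$enrolled == 1L))
  expect_true(all(feb$enrolled == 0L))  # missing month: conservatively unenrolled
  expect_true(all(mar$enrolled == 0L))  # no Part D
  mc <- flag_enrollment(days, rbind(enr_month("A", "2016-01", mc = 1L)))
  expect_true(all(mc$enrolled == 0L))   # managed care excluded
})

test_that("duplicate resident-month rows are an error naming the duplicates", {
  days <- expand_to_days(ep_row("A", "2016-01-01", "2016-01-10"))
  dup <- rbind(enr_month("A", "2016-01"), enr_month("A", "2016-01", d = 0L))
  expect_error(flag_enrollment(days, dup), "A/2016-01")
})

test_that("daily-interval enrollment input matches the monthly broadcast", {
  days <- expand_to_days(ep_row("A", "2016-01-15", "2016-03-15"))
  monthly <- rbind(enr_month("A", "2016-01"), enr_month("A", "2016-02"))
  daily <- data.table::data.table(
    resident_id = "A", start_date = "2016-01-01", end_date = "2016-02-29",
    part_a = 1L, part_b = 1L, part_d = 1L, managed_care = 0L)
  expect_identical(flag_enrollment(days, monthly)$enrolled,
                   flag_enrollment(days, daily, granularity = "daily")$enrolled)
})

test_that("stay flags use the half-open [admit, discharge) convention", {
  days <- flag_enrollment(expand_to_days(ep_row("A", "2016-05-01", "2016-05-20")),
                          enr_month("A", "2016-05"))
  fl <- flag_part_a_stays(days, stay("A", "snf", "2016-05-01", "2016-05-15"), "snf")
  expect_identical(sum(fl$snf), 14L)
  expect_identical(fl$snf[fl$date == data.table::as.IDate("2016-05-14")], 1L)
  expect_identical(fl$snf[fl$date == data.table::as.IDate("2016-05-15")], 0L)

  closed <- flag_part_a_stays(days, stay("A", "snf", "2016-05-01", "2016-05-15"),
                              "snf", include_discharge_day = TRUE)
  expect_identical(sum(closed$snf), 15L)

  outside <- flag_part_a_stays(days, stay("A", "inpatient", "2016-09-01", "2016-09-10"),
                               "inpatient")
  expect_identical(sum(outside$hospital), 0L)
})

test_that("overlapping stays of one type flag the brute-force union of days", {
  days <- flag_enrollment(expand_to_days(ep_row("A", "2016-05-01", "2016-06-30")),
                          rbind(enr_month("A", "2016-05"), enr_month("A", "2016-06")))
  stays <- rbind(stay("A", "snf", "2016-05-03", "2016-05-20"),
                 stay("A", "snf", "2016-05-15", "2016-06-05"))
  fl <- flag_part_a_stays(days, stays, "snf")
  union_days <- oracle_day_union(stays$admit_date,
                                 data.table::as.IDate(as.integer(stays$discharge_date) - 1L))
  expect_identical(as.integer(fl$date[fl$snf == 1L]), union_days)
})

test_that("invalid stays are rejected and unimputed stays are a precondition error", {
  days <- expand_to_days(ep_row("A", "2016-05-01", "2016-05-20"))
  bad <- stay("A", "snf", "2016-05-10", "2016-05-02")
  expect_warning(fl <- flag_part_a_stays(days, bad, "snf"), "discharge before admission")
  expect_identical(sum(fl$snf), 0L)
  expect_error(flag_part_a_stays(days, stay("A", "snf", "2016-05-01", NA, los = 5), "snf"),
               "impute_part_a_discharge")
})

test_that("flag assignment is order-independent and each flag touches only its column", {
  tb <- generate_cohort(random_sim_params(8))
  eps <- quiet(build_episodes(tb))
  days <- expand_to_days(eps)
  stays <- quiet(impute_part_a_discharge(tb$part_a_stays))
  orders <- list(c("e", "s", "h"), c("h", "s", "e"), c("s", "h", "e"))
  results <- lapply(orders, function(ord) {
    g <- days
    for (step in ord) {
      g <- switch(step,
                  e = flag_enrollment(g, tb$enrollment),
                  s = flag_part_a_stays(g, stays, "snf"),
                  h = flag_part_a_stays(g, stays, "inpatient"))
    }
    g[order(resident_id, episode_id, date)]
  })
  expect_identical(results[[1]], results[[2]])
  expect_identical(results[[1]], results[[3]])
})

test_that("adding stays or enrollment months only ever turns flags on", {
  tb <- generate_cohort(random_sim_params(17))
  eps <- quiet(build_episodes(tb))
  days <- expand_to_days(eps)
  stays <- quiet(impute_part_a_discharge(tb$part_a_stays))
  base_snf <- flag_part_a_stays(days, stays, "snf")
  extra <- rbind(stays,
                 stay(tb$mds$resident_id[1], "snf", "2016-03-01", "2016-03-20"))
  more <- flag_part_a_stays(days, extra, "snf")
  expect_true(all(more$snf >= base_snf$snf))

  full <- flag_enrollment(days, tb$enrollment)
  fewer <- flag_enrollment(days, tb$enrollment[-1])
  expect_true(all(full$enrolled >= fewer$enrolled))
})
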