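mds <- function(rid, kind, date, code = NA_integer_) data.table::data.table(
  resident_id = rid, record_kind = kind,
  event_date = data.table::as.IDate(date), disposition_code = as.integer(code))

test_that("entry-anchored episodes pair entries with the next discharge", {
  rec <- rbind(mds("A", "entry", "2015-03-01"),
               mds("A", "discharge", "2015-04-15", 10))
  eps <- build_entry_episodes(rec, "2015-12-31")
  expect_identical(nrow(eps), 1L)
  expect_identical(as.character(eps$start_date), "2015-03-01")
  expect_identical(as.character(eps$end_date), "2015-04-15")
  expect_identical(eps$end_reason, "final_discharge")

  open <- build_entry_episodes(mds("B", "entry", "2020-11-01"), "2020-12-31")
  expect_identical(as.character(open$end_date), "2020-12-31")
  expect_identical(open$end_reason, "study_end")

  tie <- build_entry_episodes(rbind(mds("C", "entry", "2016-05-05"),
                                    mds("C", "discharge", "2016-05-05", 12)),
                              "2016-12-31")
  expect_identical(tie$start_date, tie$end_date)  # 1-day episode
})

test_that("two entries before one discharge merge to the day-set union", {
  rec <- rbind(mds("A", "entry", "2016-01-01"),
               mds("A", "entry", "2016-01-10"),
               mds("A", "discharge", "2016-02-01", 10))
  merged <- merge_overlapping_episodes(build_entry_episodes(rec, "2016-12-31"))
  expect_identical(nrow(merged), 1L)
  got <- seq(as.integer(merged$start_date), as.integer(merged$end_date))
  expect_identical(got, oracle_day_union(c("2016-01-01", "2016-01-10"),
                                         c("2016-02-01", "2016-02-01")))
})

test_that("orphan discharges are skipped with an audit count", {
  rec <- rbind(mds("A", "discharge", "2016-01-05", 10),
               mds("A", "entry", "2016-02-01"),
               mds("A", "discharge", "2016-03-01", 10))
  expect_message(eps <- build_entry_episodes(rec, "2016-12-31"), "skipped 1")
  expect_identical(attr(eps, "n_orphan_discharges"), 1L)
  expect_identical(nrow(eps), 1L)
})

test_that("overlap merging matches the examples and the brute-force day union", {
  eps <- rbind(
    data.table::data.table(resident_id = "A", anchor = "entry",
                           start_date = data.table::as.IDate("2016-01-01"),
                           end_date = data.table::as.IDate("2016-01-31"),
                           end_reason = "final_discharge",
                           admission_assessment_date = data.table::as.IDate(NA)),
    data.table::data.table(resident_id = "A", anchor = "entry",
                           start_date = data.table::as.IDate("2016-01-20"),
                           end_date = data.table::as.IDate("2016-02-10"),
                           end_reason = "final_discharge",
                           admission_assessment_date = data.table::as.IDate(NA)))
  m <- merge_overlapping_episodes(eps)
  expect_identical(nrow(m), 1L)
  expect_identical(as.character(m$start_date), "2016-01-01")
  expect_identical(as.character(m$end_date), "2016-02-10")

  disjoint <- data.table::copy(eps)
  disjoint[2, `:=`(start_date = data.table::as.IDate("2016-02-01"),
                   end_date = data.table::as.IDate("2016-02-05"))]
  expect_identical(nrow(merge_overlapping_episodes(disjoint)), 2L)

  # random interval sets: merged day set == brute-force union; idempotent;
  # order-insensitive
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(2:8, 1)
    starts <- as.integer(data.table::as.IDate("2016-01-01")) + sample(0:120, n, TRUE)
    ends <- starts + sample(0:40, n, TRUE)
    rand <- data.table::data.table(
      resident_id = "R", anchor = "entry",
      start_date = data.table::as.IDate(starts),
      end_date = data.table::as.IDate(ends),
      end_reason = "final_discharge",
      admission_assessment_date = data.table::as.IDate(NA))
    m1 <- merge_overlapping_episodes(rand)
    union_days <- oracle_day_union(m1$start_date, m1$end_date)
    expect_identical(union_days, oracle_day_union(starts, ends))
    expect_identical(sum(as.integer(m1$end_date) - as.integer(m1$start_date) + 1L),
                     length(union_days))  # pairwise disjoint
    expect_identical(merge_overlapping_episodes(m1)[], m1[])  # idempotent
    shuffled <- rand[sample(.N)]
    expect_identical(merge_overlapping_episodes(shuffled)[], m1[])
  }
})

test_that("admission anchoring applies the 30-day reentry rule", {
  base <- function(rid, reentry_date) rbind(
    mds(rid, "entry", "2016-01-01"),
    mds(rid, "admission_assessment", "2016-01-05"),
    mds(rid, "discharge", "2016-03-01", 11),
    mds(rid, "entry", reentry_date),
    mds(rid, "discharge", "2016-06-01", 10))

  within <- build_admission_episodes(base("A", "2016-03-25"), "2016-12-31")
  expect_identical(nrow(within), 1L)
  expect_identical(as.character(within$end_date), "2016-06-01")
  expect_identical(within$start_date, data.table::as.IDate("2016-01-01"))
  expect_identical(as.character(within$admission_assessment_date), "2016-01-05")

  beyond <- quiet(build_admission_episodes(base("A", "2016-04-05"), "2016-12-31"))
  expect_identical(nrow(beyond), 1L)  # no second admission assessment
  expect_identical(as.character(beyond$end_date), "2016-03-01")
  expect_identical(beyond$end_reason, "reentry_window_expired")

  # exactly 30 days continues; 31 splits (needs a new assessment to restart)
  day30 <- build_admission_episodes(base("A", "2016-03-31"), "2016-12-31")
  expect_identical(nrow(day30), 1L)
  expect_identical(as.character(day30$end_date), "2016-06-01")
  day31 <- quiet(build_admission_episodes(base("A", "2016-04-01"), "2016-12-31"))
  expect_identical(day31$end_reason, "reentry_window_expired")
})

test_that("a code-11 discharge with no reentry record ends the episode at discharge", {
  rec <- rbind(mds("A", "entry", "2016-01-01"),
               mds("A", "admission_assessment", "2016-01-02"),
               mds("A", "discharge", "2016-02-15", 11))
  eps <- build_admission_episodes(rec, "2016-12-31")
  expect_identical(as.character(eps$end_date), "2016-02-15")
  expect_identical(eps$end_reason, "reentry_window_expired")
})

test_that("bridged reentry gaps are recorded for the stricter day convention", {
  rec <- rbind(mds("A", "entry", "2016-01-01"),
               mds("A", "admission_assessment", "2016-01-01"),
               mds("A", "discharge", "2016-02-01", 11),
               mds("A", "entry", "2016-02-20"),
               mds("A", "discharge", "2016-04-01", 10))
  eps <- build_admission_episodes(rec, "2016-12-31")
  gaps <- attr(eps, "bridged_gaps")
  expect_identical(nrow(gaps), 1L)
  expect_identical(as.character(gaps$gap_start), "2016-02-02")
  expect_identical(as.character(gaps$gap_end), "2016-02-19")
})

test_that("finalize truncates at death, drops post-death episodes, clips to study end", {
  eps <- data.table::data.table(
    resident_id = c("A", "B", "C"), anchor = "entry",
    start_date = data.table::as.IDate(c("2016-03-01", "2016-03-01", "2016-06-01")),
    end_date = data.table::as.IDate(c("2016-06-01", "2016-04-01", "2016-08-01")),
    end_reason = "final_discharge",
    admission_assessment_date = data.table::as.IDate(NA))
  deaths <- data.table::data.table(
    resident_id = c("A", "B", "C"),
    death_date = data.table::as.IDate(c("2016-04-10", "2016-05-01", "2016-05-15")))
  expect_warning(fin <- finalize_episodes(eps, deaths, "2016-12-31"),
                 "dropped 1")
  a <- fin[fin$resident_id == "A"]
  expect_identical(as.character(a$end_date), "2016-04-10")
  expect_identical(a$end_reason, "death")
  expect_identical(fin[fin$resident_id == "B"]$end_reason, "final_discharge")
  expect_false("C" %in% fin$resident_id)  # started after death
})

test_that("every episode carries exactly one end reason and reasons partition the count", {
  for (seed in c(3, 14)) {
    res <- run_chain(generate_cohort(random_sim_params(seed)))
    reasons <- c("final_discharge", "reentry_window_expired", "study_end", "death")
    expect_true(all(res$episodes$end_reason %in% reasons))
    expect_identical(sum(table(factor(res$episodes$end_reason, levels = reasons))),
                     as.integer(nrow(res$episodes)))
  }
})

test_that("admission-anchored days (gaps dropped) are contained in entry-anchored days", {
  for (seed in c(5, 23, 41)) {
    tb <- generate_cohort(random_sim_params(seed))
    adm <- run_chain(tb, drop_gaps = TRUE)
    ent <- run_chain(tb, anchor = "entry")
    for (rid in unique(adm$days$resident_id)) {
      a_days <- as.integer(adm$days$date[adm$days$resident_id == rid])
      e_days <- as.integer(ent$days$date[ent$days$resident_id == rid])
      expect_true(all(a_days %in% e_days),
                  info = sprintf("seed %d resident %s", seed, rid))
    }
  }
})
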