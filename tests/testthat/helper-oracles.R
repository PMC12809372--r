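# Independent brute-force oracles. These deliberately avoid the package's
# interval-join machinery: day sets are enumerated one day at a time and
# flags decided by scanning every record for that resident.

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# union of closed [start, end] intervals as an explicit sorted day vector
oracle_day_union <- function(starts, ends) {
  if (is.character(starts)) starts <- data.table::as.IDate(starts)
  if (is.character(ends)) ends <- data.table::as.IDate(ends)
  sort(unique(unlist(mapply(
    function(s, e) seq(as.integer(s), as.integer(e)),
    starts, ends, SIMPLIFY = FALSE))))
}

# drop bookkeeping attributes before identity comparisons
strip_attrs <- function(dt) {
  dt <- data.table::copy(dt)
  for (a in c("removal_counts", "rejected", "n_imputed", "n_orphan_discharges",
              "bridged_gaps")) {
    data.table::setattr(dt, a, NULL)
  }
  dt[]
}

# per-day flag grid for finalized episodes: literal per-resident,
# per-day, per-record scan
oracle_flag_grid <- function(episodes, tables, include_discharge_day = FALSE) {
  eps <- as.data.frame(episodes)
  enr <- as.data.frame(tables$enrollment)
  st <- as.data.frame(tables$part_a_stays)
  miss <- is.na(st$discharge_date)
  st$discharge_date[miss] <- st$admit_date[miss] + st$length_of_stay[miss]
  rows <- vector("list", nrow(eps))
  for (i in seq_len(nrow(eps))) {
    rid <- eps$resident_id[i]
    er <- enr[enr$resident_id == rid, , drop = FALSE]
    sn <- st[st$resident_id == rid & st$stay_type == "snf", , drop = FALSE]
    ho <- st[st$resident_id == rid & st$stay_type == "inpatient", , drop = FALSE]
    dd <- seq(as.integer(eps$start_date[i]), as.integer(eps$end_date[i]))
    ymd <- format(as.Date(dd, origin = "1970-01-01"), "%Y-%m")
    enrolled <- snf <- hosp <- integer(length(dd))
    covers <- function(stays, d) {
      if (!nrow(stays)) return(0L)
      a <- as.integer(stays$admit_date); e <- as.integer(stays$discharge_date)
      as.integer(if (include_discharge_day) any(d >= a & d <= e) else any(d >= a & d < e))
    }
    for (j in seq_along(dd)) {
      row <- er[er$year_month == ymd[j], , drop = FALSE]
      enrolled[j] <- as.integer(nrow(row) == 1 && row$part_a == 1 &&
                                row$part_b == 1 && row$part_d == 1 &&
                                row$managed_care == 0)
      snf[j] <- covers(sn, dd[j])
      hosp[j] <- covers(ho, dd[j])
    }
    rows[[i]] <- data.frame(resident_id = rid, episode_id = eps$episode_id[i],
                            date = dd, day_index = seq_along(dd),
                            enrolled = enrolled, snf = snf, hospital = hosp,
                            stringsAsFactors = FALSE)
  }
  g <- do.call(rbind, c(rows, list(data.frame(
    resident_id = character(0), episode_id = character(0), date = integer(0),
    day_index = integer(0), enrolled = integer(0), snf = integer(0),
    hospital = integer(0)))))
  g <- g[order(g$resident_id, g$episode_id, g$date), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# run-length reconstruction by walking sorted observable days
oracle_runs <- function(obs_days) {
  d <- as.data.frame(obs_days)
  d <- d[order(d$resident_id, d$episode_id, d$date), , drop = FALSE]
  out <- list()
  if (nrow(d)) {
    start <- prev <- as.integer(d$date[1]); key <- paste(d$resident_id[1], d$episode_id[1])
    rid <- d$resident_id[1]; eid <- d$episode_id[1]
    for (i in seq_len(nrow(d))[-1]) {
      k <- paste(d$resident_id[i], d$episode_id[i]); cur <- as.integer(d$date[i])
      if (k != key || cur != prev + 1L) {
        out[[length(out) + 1L]] <- data.frame(resident_id = rid, episode_id = eid,
                                              start = start, end = prev,
                                              n_days = prev - start + 1L)
        start <- cur; key <- k; rid <- d$resident_id[i]; eid <- d$episode_id[i]
      }
      prev <- cur
    }
    out[[length(out) + 1L]] <- data.frame(resident_id = rid, episode_id = eid,
                                          start = start, end = prev,
                                          n_days = prev - start + 1L)
  }
  res <- do.call(rbind, c(out, list(data.frame(
    resident_id = character(0), episode_id = character(0), start = integer(0),
    end = integer(0), n_days = integer(0)))))
  rownames(res) <- NULL
  res
}

# package day grid coerced for comparison against the oracle (bookkeeping
# attributes dropped; only the data matter)
grid_as_frame <- function(days) {
  g <- as.data.frame(days[order(days$resident_id, days$episode_id, days$date),
                          c("resident_id", "episode_id", "date", "day_index",
                            "enrolled", "snf", "hospital")])
  g <- data.frame(resident_id = g$resident_id, episode_id = g$episode_id,
                  date = as.integer(g$date), day_index = g$day_index,
                  enrolled = g$enrolled, snf = g$snf, hospital = g$hospital,
                  stringsAsFactors = FALSE)
  rownames(g) <- NULL
  g
}

# expand observable episodes back to day rows (one row per run per day)
runs_to_days <- function(runs) {
  back <- runs[, .(date = data.table::as.IDate(
    seq.int(as.integer(start_date), as.integer(end_date)))),
    by = .(resident_id, episode_id, observable_episode_id)]
  back[, observable_episode_id := NULL]
  data.table::setorder(back, resident_id, episode_id, date)
  back[]
}

# randomised generator settings over a one-year window (sizes well under
# the 50-resident oracle budget)
random_sim_params <- function(seed) {
  set.seed(seed)
  sim_params(
    n_residents = sample(1:8, 1),
    study_start = "2016-01-01", study_end = "2016-12-31",
    admission_rate = runif(1, 1, 2.5),
    snf_leadin_prob = runif(1),
    hosp_rate = runif(1, 0, 3),
    reentry_prob = runif(1, 0, 0.5),
    enrollment_gap_prob = runif(1, 0, 0.3),
    managed_care_prob = runif(1, 0, 0.5),
    death_prob = runif(1, 0, 0.5),
    missing_discharge_frac = runif(1),
    seed = seed)
}

# full in-memory chain without the pipeline wrapper
run_chain <- function(tables, anchor = "admission_assessment",
                      drop_gaps = FALSE) {
  quiet({
    eps <- build_episodes(tables, anchor = anchor)
    days <- expand_to_days(eps)
    if (drop_gaps) days <- drop_gap_days(days, attr(eps, "bridged_gaps"))
    days <- classify_days(days, tables)
    obs <- select_observable_days(days)
    list(episodes = eps, days = days, obs = obs,
         obs_eps = build_observable_episodes(obs))
  })
}
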