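# End-to-end pipeline with a partitioned-execution contract: residents
# are split by a stable id hash into partitions processed independently
# and appended, so results are invariant to the partition count (every
# algorithm step is per-resident).

#' Pipeline configuration
#'
#' Collects every switch of the end-to-end run. Exactly one of
#' `input_dir` (directory of linked tables, see [read_tables()]) or
#' `sim` (a [sim_params()] object, tables generated on the fly) must be
#' supplied.
#'
#' @param input_dir directory with the four linked tables, or `NULL`.
#' @param sim a [sim_params()] object, or `NULL`.
#' @param anchor episode anchoring: `"admission_assessment"` (default)
#'   or `"entry"`.
#' @param count_discharge_day count the episode end date as an NH day
#'   (default `TRUE`; see [expand_to_days()]).
#' @param drop_out_of_facility_gaps remove bridged-reentry gap days from
#'   the day grid (default `FALSE`; see [drop_gap_days()]).
#' @param include_discharge_day closed Part A stay intervals (default
#'   `FALSE`; see [flag_part_a_stays()]).
#' @param enrollment_granularity `"month"` (default) or `"daily"`.
#' @param long_stay_cutoff day-index cutoff of the long-stay comparator
#'   (default 101).
#' @param long_stay_attribution `"from_cutoff"` (default) or
#'   `"whole_episode"`.
#' @param n_partitions number of resident-hash partitions (default 1).
#' @param output_dir directory for output tables, or `NULL` to skip
#'   writing.
#' @param format `"csv"` (default) or `"parquet"`.
#' @param write_day_grid write the (large) day-level grid too (default
#'   `FALSE`).
#' @param seed optional integer; when simulating, overrides `sim$seed`.
#' @param study_start,study_end optional window override for
#'   `input_dir` mode.
#' @return a validated list with class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_dir = NULL, sim = NULL,
                            anchor = c("admission_assessment", "entry"),
                            count_discharge_day = TRUE,
                            drop_out_of_facility_gaps = FALSE,
                            include_discharge_day = FALSE,
                            enrollment_granularity = "month",
                            long_stay_cutoff = 101L,
                            long_stay_attribution = "from_cutoff",
                            n_partitions = 1L,
                            output_dir = NULL,
                            format = c("csv", "parquet"),
                            write_day_grid = FALSE,
                            seed = NULL,
                            study_start = NULL, study_end = NULL) {
  anchor <- match.arg(anchor)
  format <- match.arg(format)
  if (is.null(input_dir) == is.null(sim)) {
    stop("supply exactly one of 'input_dir' or 'sim'", call. = FALSE)
  }
  if (!is.null(sim) && !inherits(sim, "sim_params")) {
    stop("'sim' must be a sim_params() object", call. = FALSE)
  }
  n_partitions <- as.integer(n_partitions)
  if (is.na(n_partitions) || n_partitions < 1L) {
    stop("'n_partitions' must be >= 1", call. = FALSE)
  }
  if (!is.null(sim) && !is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(
    input_dir = input_dir, sim = sim, anchor = anchor,
    count_discharge_day = isTRUE(count_discharge_day),
    drop_out_of_facility_gaps = isTRUE(drop_out_of_facility_gaps),
    include_discharge_day = isTRUE(include_discharge_day),
    enrollment_granularity = enrollment_granularity,
    long_stay_cutoff = as.integer(long_stay_cutoff),
    long_stay_attribution = long_stay_attribution,
    n_partitions = n_partitions, output_dir = output_dir, format = format,
    write_day_grid = isTRUE(write_day_grid), seed = seed,
    study_start = study_start, study_end = study_end
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()] arguments; a `sim` map is
#' passed through [sim_params()] (distribution entries as in
#' [read_sim_params()]). Unknown keys are an error.
#'
#' @param path YAML file.
#' @return a `"pipeline_config"` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(unknown)) {
    stop(sprintf("unknown pipeline config key(s) in %s: %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(raw$sim)) {
    dist_fields <- c("los_distribution", "snf_leadin_distribution",
                     "hosp_length_distribution", "reentry_gap_distribution")
    for (f in intersect(names(raw$sim), dist_fields)) {
      raw$sim[[f]] <- do.call(nh_dist, raw$sim[[f]])
    }
    raw$sim <- do.call(sim_params, raw$sim)
  }
  do.call(pipeline_config, raw)
}

subset_tables <- function(tables, ids) {
  nh_tables(tables$mds[resident_id %in% ids],
            tables$enrollment[resident_id %in% ids],
            tables$part_a_stays[resident_id %in% ids],
            tables$dispensings[resident_id %in% ids],
            tables$deaths[resident_id %in% ids],
            tables$study_start, tables$study_end)
}

#' Run the full observable-time pipeline
#'
#' Loads or simulates the linked tables, validates them, then — per
#' resident-hash partition — builds and finalizes episodes for the
#' configured anchoring, expands to the day grid, sets the three flags,
#' and extracts observable days and episodes. Partitions are appended
#' and canonically sorted, so the output is invariant to `n_partitions`.
#' Finally computes the attrition summary and the long-stay
#' classification, optionally writes all output tables, and assembles a
#' run manifest (configuration echo, package version, per-step row and
#' removal counts, per-partition content fingerprints, wall-clock per
#' step).
#'
#' @param config a [pipeline_config()] object (or a YAML path).
#' @return list of class `"nh_pipeline_result"` with elements `tables`,
#'   `violations`, `episodes`, `days`, `observable_days`,
#'   `observable_episodes`, `attrition`, `long_stay`, `manifest`.
#' @export
#' @examples
#' cfg <- pipeline_config(sim = sim_params(n_residents = 10, seed = 3))
#' res <- run_pipeline(cfg)
#' res$attrition
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c(); tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  tables <- if (!is.null(config$sim)) {
    generate_cohort(config$sim)
  } else {
    read_tables(config$input_dir, config$format,
                config$study_start, config$study_end)
  }
  timings["load"] <- tic() - t0

  t0 <- tic()
  violations <- validate_tables(tables)
  if (nrow(violations)) {
    stop(sprintf("run_pipeline: input tables failed validation (%d violation(s)); first: [%s row %s col %s] %s",
                 nrow(violations), violations$table[1],
                 violations$row[1], violations$column[1],
                 violations$problem[1]), call. = FALSE)
  }
  timings["validate"] <- tic() - t0

  ids <- unique(tables$mds$resident_id)
  parts <- if (length(ids)) split(ids, partition_of(ids, config$n_partitions)) else list()

  t0 <- tic()
  ep_l <- list(); day_l <- list(); obs_l <- list(); obse_l <- list()
  fingerprints <- character(0)
  for (p in names(parts)) {
    sub <- subset_tables(tables, parts[[p]])
    eps <- build_episodes(sub, anchor = config$anchor)
    days <- expand_to_days(eps, count_discharge_day = config$count_discharge_day)
    if (config$drop_out_of_facility_gaps) {
      days <- drop_gap_days(days, attr(eps, "bridged_gaps"))
    }
    days <- classify_days(days, sub,
                          include_discharge_day = config$include_discharge_day,
                          enrollment_granularity = config$enrollment_granularity)
    obs <- select_observable_days(days)
    ep_l[[p]] <- eps; day_l[[p]] <- days; obs_l[[p]] <- obs
    obse_l[[p]] <- build_observable_episodes(obs)
    fingerprints[p] <- table_fingerprint(obse_l[[p]])
  }
  episodes <- if (length(ep_l)) data.table::rbindlist(ep_l) else build_episodes(tables, anchor = config$anchor)
  days <- if (length(day_l)) data.table::rbindlist(day_l) else
    classify_days(expand_to_days(episodes), tables)
  observable_days <- if (length(obs_l)) data.table::rbindlist(obs_l) else select_observable_days(days)
  observable_episodes <- if (length(obse_l)) data.table::rbindlist(obse_l) else build_observable_episodes(observable_days)
  data.table::setorder(episodes, resident_id, anchor, start_date)
  data.table::setorder(days, resident_id, episode_id, date)
  data.table::setorder(observable_days, resident_id, episode_id, date)
  data.table::setorder(observable_episodes, resident_id, episode_id, start_date)
  timings["classify"] <- tic() - t0

  t0 <- tic()
  removal <- Reduce(`+`, lapply(obs_l, attr, "removal_counts"),
                    accumulate = FALSE)
  if (is.null(removal)) removal <- c(unenrolled = 0L, snf = 0L, hospital = 0L)
  attrition <- summarize_attrition(days)
  long_stay <- classify_long_stay_method2(days, cutoff = config$long_stay_cutoff,
                                          attribution = config$long_stay_attribution)
  timings["summarize"] <- tic() - t0

  manifest <- list(
    package_version = as.character(utils::packageVersion("nhobs")),
    config = config_echo(config),
    n_partitions = config$n_partitions,
    step_counts = list(
      residents = length(ids),
      mds_records = nrow(tables$mds),
      episodes = nrow(episodes),
      nh_days = nrow(days),
      days_removed_unenrolled = unname(removal["unenrolled"]),
      days_removed_snf = unname(removal["snf"]),
      days_removed_hospital = unname(removal["hospital"]),
      days_removed_unique = nrow(days) - nrow(observable_days),
      observable_days = nrow(observable_days),
      observable_episodes = nrow(observable_episodes)
    ),
    partition_fingerprints = as.list(fingerprints),
    timings_sec = as.list(round(timings, 3))
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_one(episodes, file.path(config$output_dir, "episodes"), config$format)
    write_one(observable_episodes,
              file.path(config$output_dir, "observable_episodes"), config$format)
    write_one(attrition, file.path(config$output_dir, "attrition"), config$format)
    write_one(long_stay, file.path(config$output_dir, "long_stay"), config$format)
    if (config$write_day_grid) {
      write_one(days, file.path(config$output_dir, "day_grid"), config$format)
    }
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(tables = tables, violations = violations, episodes = episodes,
                 days = days, observable_days = observable_days,
                 observable_episodes = observable_episodes,
                 attrition = attrition, long_stay = long_stay,
                 manifest = manifest),
            class = "nh_pipeline_result")
}

config_echo <- function(config) {
  out <- unclass(config)
  if (!is.null(out$sim)) {
    sim <- unclass(out$sim)
    sim$study_start <- as.character(sim$study_start)
    sim$study_end <- as.character(sim$study_end)
    for (f in names(sim)) if (inherits(sim[[f]], "nh_dist")) sim[[f]] <- unclass(sim[[f]])
    out$sim <- sim
  }
  for (f in c("study_start", "study_end")) {
    if (!is.null(out[[f]])) out[[f]] <- as.character(out[[f]])
  }
  out[!vapply(out, is.null, logical(1))]
}

#' @export
print.nh_pipeline_result <- function(x, ...) {
  sc <- x$manifest$step_counts
  cat("<nh_pipeline_result>\n")
  cat(sprintf("  %d residents | %d episodes | %d NH days\n",
              sc$residents, sc$episodes, sc$nh_days))
  cat(sprintf("  removed: %d unenrolled, %d SNF, %d hospital (unique removed %d)\n",
              sc$days_removed_unenrolled, sc$days_removed_snf,
              sc$days_removed_hospital, sc$days_removed_unique))
  cat(sprintf("  observable: %d days in %d observable episodes\n",
              sc$observable_days, sc$observable_episodes))
  invisible(x)
}
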