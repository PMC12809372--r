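#' Duration distribution specification
#'
#' Small constructor for the named duration distributions accepted by
#' [sim_params()]: `"lognormal"` (`meanlog`, `sdlog`), `"fixed"`
#' (`value`), `"uniform_int"` (`min`, `max`), and `"poisson"` (`lambda`).
#' Draws are rounded to whole days.
#'
#' @param name distribution name.
#' @param ... distribution parameters (see above).
#' @return a list with class `"nh_dist"`.
#' @export
#' @examples
#' nh_dist("lognormal", meanlog = log(31), sdlog = 1.75)
#' nh_dist("fixed", value = 20)
nh_dist <- function(name, ...) {
  spec <- c(list(name = name), list(...))
  needed <- switch(name,
    lognormal   = c("meanlog", "sdlog"),
    fixed       = "value",
    uniform_int = c("min", "max"),
    poisson     = "lambda",
    stop(sprintf("unknown distribution name '%s'", name), call. = FALSE))
  missing <- setdiff(needed, names(spec))
  if (length(missing)) {
    stop(sprintf("distribution '%s' requires parameter(s): %s",
                 name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  structure(spec, class = "nh_dist")
}

#' Simulation parameters for a synthetic linked nursing-home cohort
#'
#' Bundles and validates every knob of the synthetic claims generator.
#' Defaults reflect the published margins of the 2013-2020 US nursing-home
#' population where such margins exist (length of stay: median 31 days,
#' mean ~145 days, hence a heavy-tailed lognormal; about 1.5 admission
#' episodes per resident), and documented placeholder choices elsewhere
#' (skilled-nursing lead-in and hospitalization distributions are not
#' published at this granularity; see the methods vignette).
#'
#' @param n_residents number of residents to simulate.
#' @param study_start,study_end study window (ISO dates). All generated
#'   events fall inside this window.
#' @param admission_rate expected NH admission episodes per resident over
#'   the study; realised as `1 + Poisson(admission_rate - 1)` so every
#'   resident has at least one episode (residents enter the source data
#'   only by appearing in the NH).
#' @param los_distribution NH episode length-of-stay distribution, days.
#' @param snf_leadin_prob probability an admission starts with a
#'   skilled-nursing (SNF) lead-in paid under Part A.
#' @param snf_leadin_distribution lead-in length, days; draws are clipped
#'   to \[0, 100\] because Part A covers at most 100 SNF days.
#' @param hosp_rate expected inpatient hospitalizations per person-year of
#'   NH time.
#' @param hosp_length_distribution hospitalization length, days.
#' @param post_hosp_snf_prob probability a mid-episode hospitalization is
#'   followed by a fresh SNF stay (residents can have several discrete
#'   post-acute periods within one NH episode).
#' @param reentry_prob probability an episode contains a
#'   discharge-with-return-anticipated (A0310F = 11) / reentry pair.
#' @param reentry_gap_distribution gap in days between such a discharge
#'   and the return; gaps of 30 days or less continue the same episode,
#'   longer gaps force a new admission.
#' @param enrollment_gap_prob per resident-month probability of lacking
#'   Part A/B/D coverage.
#' @param managed_care_prob per resident-month probability of a managed
#'   care (Medicare Advantage) flag.
#' @param death_prob probability a resident's final episode ends in death.
#' @param missing_discharge_frac fraction of Part A stay records whose
#'   discharge date is blanked (length of stay retained), exercising the
#'   discharge-date imputation path.
#' @param dispensing_prob probability a resident uses the simulated drug
#'   class; users fill repeatedly during NH episodes.
#' @param drug_class label stamped on dispensing records.
#' @param seed integer RNG seed; identical parameters (including the seed)
#'   reproduce byte-identical tables.
#' @return a validated list with class `"sim_params"`.
#' @export
#' @examples
#' p <- sim_params(n_residents = 10, seed = 42)
#' cohort <- generate_cohort(p)
sim_params <- function(n_residents = 100L,
                       study_start = "2013-01-01",
                       study_end = "2020-12-31",
                       admission_rate = 1.5,
                       los_distribution = nh_dist("lognormal",
                                                  meanlog = log(31), sdlog = 1.75),
                       snf_leadin_prob = 0.7,
                       snf_leadin_distribution = nh_dist("lognormal",
                                                         meanlog = log(25), sdlog = 0.6),
                       hosp_rate = 1.0,
                       hosp_length_distribution = nh_dist("lognormal",
                                                          meanlog = log(5), sdlog = 0.5),
                       post_hosp_snf_prob = 0.5,
                       reentry_prob = 0.2,
                       reentry_gap_distribution = nh_dist("uniform_int",
                                                          min = 1, max = 45),
                       enrollment_gap_prob = 0.05,
                       managed_care_prob = 0.25,
                       death_prob = 0.3,
                       missing_discharge_frac = 0.05,
                       dispensing_prob = 0.25,
                       drug_class = "gabapentin",
                       seed = 1L) {
  n_residents <- as.integer(n_residents)
  if (is.na(n_residents) || n_residents < 0L) {
    stop("'n_residents' must be a nonnegative integer", call. = FALSE)
  }
  study_start <- as_nh_date(study_start, "study_start")
  study_end <- as_nh_date(study_end, "study_end")
  if (study_start > study_end) stop("study_start must be <= study_end", call. = FALSE)
  if (admission_rate < 1) stop("'admission_rate' must be >= 1 (every simulated resident has an NH stay)", call. = FALSE)
  for (f in c("snf_leadin_prob", "post_hosp_snf_prob", "reentry_prob",
              "enrollment_gap_prob", "managed_care_prob", "death_prob",
              "missing_discharge_frac", "dispensing_prob")) {
    check_prob(get(f), f)
  }
  if (hosp_rate < 0) stop("'hosp_rate' must be >= 0", call. = FALSE)
  for (f in c("los_distribution", "snf_leadin_distribution",
              "hosp_length_distribution", "reentry_gap_distribution")) {
    spec <- get(f)
    if (!is.list(spec) || is.null(spec$name)) {
      stop(sprintf("'%s' must be an nh_dist() specification", f), call. = FALSE)
    }
    # fail fast on unknown names rather than mid-simulation
    draw_ok <- tryCatch({withr_seed_draw(spec); TRUE},
                        error = function(e) stop(sprintf(
                          "invalid '%s': %s", f, conditionMessage(e)), call. = FALSE))
  }
  structure(list(
    n_residents = n_residents, study_start = study_start, study_end = study_end,
    admission_rate = admission_rate, los_distribution = los_distribution,
    snf_leadin_prob = snf_leadin_prob,
    snf_leadin_distribution = snf_leadin_distribution,
    hosp_rate = hosp_rate, hosp_length_distribution = hosp_length_distribution,
    post_hosp_snf_prob = post_hosp_snf_prob,
    reentry_prob = reentry_prob,
    reentry_gap_distribution = reentry_gap_distribution,
    enrollment_gap_prob = enrollment_gap_prob,
    managed_care_prob = managed_care_prob, death_prob = death_prob,
    missing_discharge_frac = missing_discharge_frac,
    dispensing_prob = dispensing_prob, drug_class = drug_class,
    seed = as.integer(seed)
  ), class = "sim_params")
}

# one throwaway draw under a local RNG state, used only to validate a spec
withr_seed_draw <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(0L)
  draw_duration(spec, 1L, field = spec$name)
  invisible(NULL)
}

#' Read simulation parameters from a YAML scenario file
#'
#' The YAML mirrors [sim_params()] arguments; distribution fields are maps
#' with a `name` key, e.g. `los_distribution: {name: lognormal, meanlog:
#' 3.43, sdlog: 1.75}`.
#'
#' @param path YAML file path.
#' @return a `"sim_params"` object.
#' @export
read_sim_params <- function(path) {
  raw <- yaml::read_yaml(path)
  dist_fields <- c("los_distribution", "snf_leadin_distribution",
                   "hosp_length_distribution", "reentry_gap_distribution")
  for (f in intersect(names(raw), dist_fields)) {
    raw[[f]] <- do.call(nh_dist, raw[[f]])
  }
  unknown <- setdiff(names(raw), names(formals(sim_params)))
  if (length(unknown)) {
    stop(sprintf("unknown sim_params field(s) in %s: %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(sim_params, raw)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("<sim_params> %d residents, %s .. %s, seed %d\n",
              x$n_residents, x$study_start, x$study_end, x$seed))
  cat(sprintf("  admissions/resident %.2f | LOS %s | SNF lead-in p=%.2f %s\n",
              x$admission_rate, x$los_distribution$name,
              x$snf_leadin_prob, x$snf_leadin_distribution$name))
  cat(sprintf("  hosp %.2f/py | reentry p=%.2f | enroll gap p=%.2f | MA p=%.2f | death p=%.2f\n",
              x$hosp_rate, x$reentry_prob, x$enrollment_gap_prob,
              x$managed_care_prob, x$death_prob))
  invisible(x)
}
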