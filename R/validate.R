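# Schema validation for the four linked tables. The report is the
# product: every violation is listed with its table, row and column; an
# empty report means the tables pass.

violation <- function(table, row, column, problem) {
  data.table(table = table, row = as.integer(row), column = column,
             problem = problem)
}

no_violations <- function() violation(character(0), integer(0), character(0),
                                      character(0))[0]

check_columns <- function(dt, table, required) {
  missing <- setdiff(required, names(dt))
  if (length(missing)) {
    violation(table, NA_integer_, missing, "required column missing")
  } else no_violations()
}

check_dates <- function(dt, table, column, study_start, study_end,
                        allow_na = FALSE) {
  v <- list(no_violations())
  x <- dt[[column]]
  parsed <- suppressWarnings(data.table::as.IDate(as.character(x),
                                                  format = "%Y-%m-%d"))
  if (inherits(x, "Date")) parsed <- data.table::as.IDate(x)
  bad_parse <- which(is.na(parsed) & !is.na(x) & nzchar(trimws(as.character(x))))
  if (length(bad_parse)) {
    v <- c(v, list(violation(table, bad_parse, column, "unparsable date")))
  }
  bad_na <- which(is.na(x) | !nzchar(trimws(as.character(x))))
  if (!allow_na && length(bad_na)) {
    v <- c(v, list(violation(table, bad_na, column, "missing date")))
  }
  inside <- !is.na(parsed) & (parsed < study_start | parsed > study_end)
  if (any(inside)) {
    v <- c(v, list(violation(table, which(inside), column,
                             "date outside the study window")))
  }
  data.table::rbindlist(v)
}

#' Validate a linked table bundle against the expected schemas
#'
#' Checks column presence, date parsability and study-window containment,
#' code domains (record kinds, A0310F disposition in \{10, 11, 12\} on
#' discharge records only, stay types, 0/1 indicators, positive days
#' supply), duplicate resident-month and death keys, discharge-before-
#' admission stays, stays missing both discharge date and length of stay,
#' and that every resident referenced by the satellite tables appears in
#' the MDS table.
#'
#' @param tables an [nh_tables()] bundle.
#' @return data.table of violations (`table`, `row`, `column`,
#'   `problem`); zero rows when everything passes.
#' @export
#' @examples
#' validate_tables(make_fixture("figure1_schematic"))
validate_tables <- function(tables) {
  stopifnot(inherits(tables, "nh_tables"))
  s0 <- tables$study_start; s1 <- tables$study_end
  v <- list(no_violations())
  add <- function(x) v[[length(v) + 1L]] <<- x

  mds <- tables$mds
  add(check_columns(mds, "mds", c("resident_id", "record_kind", "event_date",
                                  "disposition_code")))
  if (all(c("record_kind", "event_date", "disposition_code") %in% names(mds)) &&
      nrow(mds)) {
    kinds <- c("entry", "discharge", "admission_assessment", "other_assessment")
    bad_kind <- which(!(mds$record_kind %in% kinds))
    if (length(bad_kind)) add(violation("mds", bad_kind, "record_kind",
                                        sprintf("record_kind not one of: %s",
                                                paste(kinds, collapse = ", "))))
    add(check_dates(mds, "mds", "event_date", s0, s1))
    is_disc <- mds$record_kind == "discharge"
    bad_code <- which(is_disc & !(mds$disposition_code %in% c(10L, 11L, 12L)))
    if (length(bad_code)) {
      add(violation("mds", bad_code, "disposition_code",
                    "A0310F disposition must be 10, 11 or 12 on discharge records"))
    }
    stray <- which(!is_disc & !is.na(mds$disposition_code))
    if (length(stray)) {
      add(violation("mds", stray, "disposition_code",
                    "disposition code present on a non-discharge record"))
    }
  }

  enr <- tables$enrollment
  add(check_columns(enr, "enrollment", c("resident_id", "year_month", "part_a",
                                         "part_b", "part_d", "managed_care")))
  if (all(c("year_month", "part_a") %in% names(enr)) && nrow(enr)) {
    bad_ym <- which(!grepl("^\\d{4}-\\d{2}$", enr$year_month))
    if (length(bad_ym)) add(violation("enrollment", bad_ym, "year_month",
                                      "expected YYYY-MM"))
    for (col in c("part_a", "part_b", "part_d", "managed_care")) {
      bad <- which(!(enr[[col]] %in% c(0L, 1L)))
      if (length(bad)) add(violation("enrollment", bad, col,
                                     "indicator must be 0 or 1"))
    }
    dup <- duplicated(enr, by = c("resident_id", "year_month"))
    if (any(dup)) add(violation("enrollment", which(dup), "resident_id",
                                "duplicate resident-month row"))
  }

  st <- tables$part_a_stays
  add(check_columns(st, "part_a_stays", c("resident_id", "stay_type",
                                          "admit_date", "discharge_date",
                                          "length_of_stay")))
  if (all(c("stay_type", "admit_date") %in% names(st)) && nrow(st)) {
    bad_type <- which(!(st$stay_type %in% c("snf", "inpatient")))
    if (length(bad_type)) add(violation("part_a_stays", bad_type, "stay_type",
                                        "stay_type must be snf or inpatient"))
    add(check_dates(st, "part_a_stays", "admit_date", s0, s1))
    add(check_dates(st, "part_a_stays", "discharge_date", s0, s1, allow_na = TRUE))
    inv <- which(!is.na(st$discharge_date) & st$discharge_date < st$admit_date)
    if (length(inv)) add(violation("part_a_stays", inv, "discharge_date",
                                   "discharge date before admission date"))
    neither <- which(is.na(st$discharge_date) & is.na(st$length_of_stay))
    if (length(neither)) {
      add(violation("part_a_stays", neither, "discharge_date",
                    "missing both discharge date and length of stay"))
    }
    bad_los <- which(!is.na(st$length_of_stay) & st$length_of_stay < 0L)
    if (length(bad_los)) add(violation("part_a_stays", bad_los, "length_of_stay",
                                       "negative length of stay"))
  }

  disp <- tables$dispensings
  add(check_columns(disp, "dispensings", c("resident_id", "drug_class",
                                           "fill_date", "days_supply")))
  if (all(c("fill_date", "days_supply") %in% names(disp)) && nrow(disp)) {
    add(check_dates(disp, "dispensings", "fill_date", s0, s1))
    bad_sup <- which(is.na(disp$days_supply) | disp$days_supply <= 0L)
    if (length(bad_sup)) add(violation("dispensings", bad_sup, "days_supply",
                                       "days supply must be positive"))
  }

  de <- tables$deaths
  add(check_columns(de, "deaths", c("resident_id", "death_date")))
  if (all(c("resident_id", "death_date") %in% names(de)) && nrow(de)) {
    add(check_dates(de, "deaths", "death_date", s0, s1))
    dup <- duplicated(de$resident_id)
    if (any(dup)) add(violation("deaths", which(dup), "resident_id",
                                "duplicate death record"))
  }

  if ("resident_id" %in% names(mds)) {
    known <- unique(mds$resident_id)
    for (tb in c("enrollment", "part_a_stays", "dispensings", "deaths")) {
      t <- tables[[tb]]
      if ("resident_id" %in% names(t) && nrow(t)) {
        orphan <- which(!(t$resident_id %in% known))
        if (length(orphan)) add(violation(tb, orphan, "resident_id",
                                          "resident id absent from the mds table"))
      }
    }
  }

  data.table::rbindlist(v)
}
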