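# Internal helpers shared across modules.

#' Coerce to an integer calendar date
#'
#' Accepts `Date`, `IDate`, or ISO-8601 character input; anything that does
#' not parse is an error (dates drive every downstream day count, so silent
#' NA coercion is never acceptable).
#'
#' @param x date-like vector.
#' @param what label used in error messages.
#' @return a [data.table::IDate] vector.
#' @keywords internal
#' @noRd
as_nh_date <- function(x, what = "date") {
  if (inherits(x, "IDate")) return(x)
  if (inherits(x, "Date")) return(data.table::as.IDate(x))
  out <- suppressWarnings(data.table::as.IDate(as.character(x), format = "%Y-%m-%d"))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(as.character(x))))
  if (length(bad)) {
    stop(sprintf("unparsable %s at position(s) %s: %s", what,
                 paste(head(bad, 5L), collapse = ", "),
                 paste(head(as.character(x)[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' Calendar month key ("YYYY-MM") of a date vector
#' @keywords internal
#' @noRd
month_key <- function(dates) format(as.Date(dates), "%Y-%m")

#' First day of a "YYYY-MM" month key
#' @keywords internal
#' @noRd
month_start <- function(ym) data.table::as.IDate(paste0(ym, "-01"))

#' Last day of a "YYYY-MM" month key
#' @keywords internal
#' @noRd
month_end <- function(ym) {
  first <- as.Date(paste0(ym, "-01"))
  data.table::as.IDate(seq(first, by = "1 month", length.out = 2L)[2L] - 1L)
}

#' Percentage rounded half away from zero
#'
#' Published stepwise percentages use commercial rounding (half away from
#' zero) to one decimal, not the IEC round-half-even rule of base
#' [round()]. Returns `NA` (absent), never zero, on a zero denominator.
#'
#' @param numerator,denominator nonnegative counts.
#' @param digits decimal places (default 1).
#' @return numeric percentage on the 0-100 scale.
#' @export
#' @examples
#' pct_round(1063746842, 1468869489)  # 72.4
#' pct_round(0, 100)                  # 0
#' pct_round(5, 0)                    # NA
pct_round <- function(numerator, denominator, digits = 1L) {
  x <- 100 * numerator / denominator
  x[denominator == 0] <- NA_real_
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Stable string hash for resident-id partitioning (FNV-1a, 32 bit)
#'
#' Deterministic across sessions and platforms, unlike R's internal string
#' hashing; used to assign residents to pipeline partitions. Implemented
#' in double arithmetic (exact below 2^53) since R's bitwXor is 32-bit
#' signed; the xor folds one octet at a time as FNV-1a specifies.
#'
#' @param x character vector.
#' @return nonnegative numeric hash values (< 2^32).
#' @keywords internal
#' @noRd
fnv1a32 <- function(x) {
  prime <- 16777619
  vapply(x, function(s) {
    h <- 2166136261
    for (b in utf8ToInt(s)) {
      # xor on the low 8 bits only (FNV-1a folds one octet at a time)
      low <- h %% 256
      h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
      h <- (h * prime) %% 4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Partition index (1..n) for each resident id
#' @keywords internal
#' @noRd
partition_of <- function(resident_id, n_partitions) {
  if (n_partitions < 1L) stop("n_partitions must be >= 1", call. = FALSE)
  as.integer(fnv1a32(as.character(resident_id)) %% n_partitions) + 1L
}

#' Lightweight content fingerprint of a data.table
#'
#' Order-sensitive digest over the printed representation; used in run
#' manifests to assert determinism, not for cryptographic integrity.
#' @keywords internal
#' @noRd
table_fingerprint <- function(dt) {
  if (!nrow(dt)) return("empty:0")
  lines <- do.call(paste, c(lapply(dt, as.character), sep = "\x1f"))
  h <- 5381
  chunk <- vapply(lines, function(s) sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9,
                  numeric(1), USE.NAMES = FALSE)
  acc <- h
  for (v in chunk) acc <- (acc * 33 + v) %% 1e15
  sprintf("djb:%.0f:n%d", acc, nrow(dt))
}

#' Draw from a named duration distribution
#'
#' Distribution specs are lists `list(name = , ...)` with names
#' `"lognormal"` (`meanlog`, `sdlog`), `"fixed"` (`value`),
#' `"uniform_int"` (`min`, `max`), or `"poisson"` (`lambda`). Draws are
#' rounded to whole days; `min_days` enforces a floor.
#'
#' @keywords internal
#' @noRd
draw_duration <- function(spec, n, min_days = 1L, field = "distribution") {
  if (n == 0L) return(integer(0))
  if (!is.list(spec) || is.null(spec$name)) {
    stop(sprintf("invalid distribution for '%s': expected list(name = ...)", field),
         call. = FALSE)
  }
  d <- switch(spec$name,
    lognormal   = round(rlnorm(n, meanlog = spec$meanlog, sdlog = spec$sdlog)),
    fixed       = rep(round(spec$value), n),
    uniform_int = sample(seq.int(spec$min, spec$max), n, replace = TRUE),
    poisson     = rpois(n, lambda = spec$lambda),
    stop(sprintf("unknown distribution name '%s' in field '%s'", spec$name, field),
         call. = FALSE)
  )
  as.integer(pmax(d, min_days))
}

#' Validate a probability parameter
#' @keywords internal
#' @noRd
check_prob <- function(p, field) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", field), call. = FALSE)
  }
  p
}
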