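#' Parse FAERS-style partial dates
#'
#' FAERS stores dates as digit strings: \code{YYYYMMDD}, \code{YYYYMM} or
#' \code{YYYY}. A date may therefore be known only to month or year
#' precision; the precision travels with the value so downstream steps can
#' require (for example) day precision for time-to-onset arithmetic.
#'
#' @param raw character vector of digit strings; \code{NA} and \code{""}
#'   denote absent dates.
#' @return A \code{data.table} with one row per input: \code{raw},
#'   \code{year}, \code{month}, \code{day} (integer, \code{NA} where not
#'   given), \code{precision} (\code{"day"}, \code{"month"}, \code{"year"}
#'   or \code{NA} for absent/invalid), \code{date} (\code{Date}, set only at
#'   day precision) and \code{key}, a numeric sort key in which missing
#'   components compare as the lowest value (\code{YYYY0000 < YYYY0101}).
#'   Impossible calendar values (month 13, day 32) yield \code{NA}
#'   precision and are counted in \code{attr(, "n_invalid")}.
#' @export
#' @examples
#' parse_date(c("20100401", "201004", "2010", "", "20101340"))
parse_date <- function(raw) {
  raw <- as.character(raw)
  n <- length(raw)
  year <- month <- day <- rep(NA_integer_, n)
  precision <- rep(NA_character_, n)
  clean <- !is.na(raw) & grepl("^[0-9]+$", raw)
  len <- ifelse(clean, nchar(raw), 0L)

  y8 <- clean & len == 8L
  y6 <- clean & len == 6L
  y4 <- clean & len == 4L
  year[y8 | y6 | y4] <- as.integer(substr(raw[y8 | y6 | y4], 1L, 4L))
  month[y8 | y6] <- as.integer(substr(raw[y8 | y6], 5L, 6L))
  day[y8] <- as.integer(substr(raw[y8], 7L, 8L))

  ok_month <- !is.na(month) & month >= 1L & month <= 12L
  # day validity against month lengths (with leap years)
  dim_tab <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  maxd <- rep(NA_integer_, n)
  maxd[ok_month] <- dim_tab[month[ok_month]] +
    (month[ok_month] == 2L & leap[ok_month])
  ok_day <- y8 & ok_month & !is.na(day) & day >= 1L & day <= maxd
  precision[y8 & ok_day] <- "day"
  precision[y6 & ok_month] <- "month"
  precision[y4] <- "year"

  # wipe components of invalid entries (non-digit strings, wrong lengths,
  # impossible calendar values); empty/NA inputs are absent, not invalid
  bad <- !is.na(raw) & nzchar(raw) & is.na(precision)
  year[bad] <- month[bad] <- day[bad] <- NA_integer_
  month[precision %in% "year"] <- NA_integer_
  day[!(precision %in% "day")] <- NA_integer_

  date <- rep(NA_real_, n)
  i <- which(precision %in% "day")
  if (length(i)) date[i] <- days_from_civil(year[i], month[i], day[i])
  date <- structure(date, class = "Date")
  key <- ifelse(is.na(precision), NA_real_,
    year * 10000 +
      ifelse(is.na(month), 0, month) * 100 +
      ifelse(is.na(day), 0, day))

  out <- data.table::data.table(
    raw = raw, year = year, month = month, day = day,
    precision = precision, date = date)
  data.table::set(out, j = "key", value = key)
  data.table::setattr(out, "n_invalid", sum(bad))
  out[]
}

#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimals (0.5 rounds up, -0.5
#' rounds down), as used for the percentage columns of report tables; base
#' \code{round()} rounds half to even instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a denominator
#'
#' \code{100 * numerator / denominator}, rounded half away from zero to the
#' requested number of decimals — the convention used for every derived
#' percent column the pipeline writes.
#'
#' @param numerator,denominator counts; \code{denominator} must be positive.
#' @param decimals decimal places to keep (default 2).
#' @return percent value, or \code{NA_real_} when \code{denominator} is 0.
#' @export
#' @examples
#' proportion(852, 4520, 2) # 18.85
proportion <- function(numerator, denominator, decimals = 2L) {
  out <- rep(NA_real_, length(numerator))
  ok <- !is.na(denominator) & denominator > 0
  out[ok] <- round_half_up(100 * numerator[ok] / denominator[ok], decimals)
  if (length(out) == 1L) out <- as.numeric(out)
  out
}

# days since 1970-01-01 from calendar components, pure vectorised
# arithmetic (civil-calendar algorithm) — avoids strptime on hot paths
days_from_civil <- function(y, m, d) {
  y <- as.numeric(y) - (m <= 2L)
  era <- floor(y / 400)
  yoe <- y - era * 400
  mp <- (m + 9L) %% 12L
  doy <- floor((153 * mp + 2) / 5) + d - 1
  doe <- yoe * 365 + floor(yoe / 4) - floor(yoe / 100) + doy
  era * 146097 + doe - 719468
}

# ---- quarter helpers ---------------------------------------------------

#' Quarter labels and ordering
#'
#' FAERS archives are quarterly; labels look like \code{"2014Q1"}. The
#' index is a total order on quarters (year * 4 + quarter - 1) used for
#' approval cut-offs and the era split.
#'
#' @param quarter_id character vector like \code{"2004Q3"}.
#' @return integer index.
#' @export
quarter_index <- function(quarter_id) {
  stopifnot(all(grepl("^[0-9]{4}Q[1-4]$", quarter_id[!is.na(quarter_id)])))
  yr <- as.integer(substr(quarter_id, 1L, 4L))
  qq <- as.integer(substr(quarter_id, 6L, 6L))
  yr * 4L + (qq - 1L)
}

#' @rdname quarter_index
#' @param year,month integer vectors; months map to quarters, missing months
#'   (year-precision dates) map to Q1 so partial dates take the lowest
#'   consistent quarter.
#' @export
quarter_of <- function(year, month) {
  q <- ifelse(is.na(month), 1L, (as.integer(month) - 1L) %/% 3L + 1L)
  ifelse(is.na(year), NA_character_, sprintf("%04dQ%d", as.integer(year), q))
}

#' @rdname quarter_index
#' @param from,to quarter labels delimiting an inclusive range.
#' @export
quarter_seq <- function(from, to) {
  i <- quarter_index(from):quarter_index(to)
  sprintf("%04dQ%d", i %/% 4L, i %% 4L + 1L)
}

# first / last calendar day of a quarter, as Date
quarter_bounds <- function(quarter_id) {
  yr <- as.integer(substr(quarter_id, 1L, 4L))
  qq <- as.integer(substr(quarter_id, 6L, 6L))
  first <- as.Date(sprintf("%04d-%02d-01", yr, (qq - 1L) * 3L + 1L))
  last <- seq(first, by = "3 months", length.out = 2L)[2L] - 1L
  list(first = first, last = last)
}

# FAERS file suffix for a quarter: "2004Q1" -> "04Q1"
quarter_suffix <- function(quarter_id) substr(quarter_id, 3L, 6L)

# ---- id ordering -------------------------------------------------------

# FAERS ids are digit strings; compare numerically when all are digits,
# lexicographically otherwise (the format does not guarantee numeric ids).
id_rank_value <- function(ids) {
  ids <- as.character(ids)
  if (all(grepl("^[0-9]+$", ids[!is.na(ids)]))) {
    suppressWarnings(as.numeric(ids))
  } else {
    # rank of the lexicographic order keeps comparisons consistent
    as.numeric(xtfrm(ids))
  }
}

# ---- string normalisation ----------------------------------------------

# uppercase, punctuation to spaces, collapse whitespace
normalize_drugname <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("[^A-Z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}
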