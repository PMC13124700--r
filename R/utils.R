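`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half-up
#'
#' Rounds to `digits` decimals with ties going away from zero-half upward
#' (22.95 -> 23.0), the convention used throughout the descriptive tables.
#' Base `round()` uses banker's rounding and would print 22.9 there.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(100 * 42 / 183, 1) # 23.0
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # tiny eps absorbs binary representation error in count ratios (e.g. 22.95)
  floor(x * p + 0.5 + 1e-9) / p
}

# Derive a reproducible child seed from a master seed and a stream tag, so
# that draws for one output table never perturb another table's stream.
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483563)
}

# Parse FAERS-style YYYYMMDD date strings. Returns a list with:
#   date  - Date (NA unless a valid 8-digit date)
#   year  - integer year (populated for 4, 6 or 8 digit strings)
#   partial - logical, TRUE when digits present but fewer than 8 / invalid day
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  digits <- grepl("^[0-9]+$", x)
  n <- nchar(x)
  full <- digits & n == 8L
  date <- rep(as.Date(NA), length(x))
  date[full] <- as.Date(x[full], format = "%Y%m%d")
  # invalid calendar dates (e.g. 20230231) come back NA from as.Date
  bad_full <- full & is.na(date)
  year <- rep(NA_integer_, length(x))
  has_year <- digits & n %in% c(4L, 6L, 8L)
  year[has_year] <- as.integer(substr(x[has_year], 1L, 4L))
  partial <- (digits & n %in% c(4L, 6L)) | bad_full
  list(date = date, year = year, partial = partial)
}

# YYYYMMDD integer encoding of a Date vector (NA-safe).
date_to_faers <- function(d) {
  out <- rep(NA_character_, length(d))
  ok <- !is.na(d)
  out[ok] <- format(d[ok], "%Y%m%d")
  out
}

# uppercase + collapse internal whitespace; canonical key for name matching
norm_name <- function(x) {
  toupper(gsub("\\s+", " ", trimws(as.character(x))))
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}
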