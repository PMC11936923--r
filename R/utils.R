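# shared internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

# round half away from zero (Table-style percentages; base round() is
# banker's rounding, which never yields e.g. 39.6 from 39.55)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  # epsilon guards values like 39.55 whose binary form sits just below .5
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# drug-name normalization: upper case, trimmed, internal whitespace collapsed
norm_name <- function(x) {
  gsub("[[:space:]]+", " ", toupper(trimws(as.character(x))))
}

# PT/SOC label normalization: lower case, trimmed, whitespace collapsed
norm_pt <- function(x) {
  gsub("[[:space:]]+", " ", tolower(trimws(as.character(x))))
}

# Parse FAERS-style dates given as YYYYMMDD / YYYYMM / YYYY digit strings.
# Returns a list with the retained string, a precision tag
# ("day"/"month"/"year", NA when absent or invalid) and a Date that is
# non-NA only at day precision.
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x) | is.na(x)] <- NA_character_
  prec <- rep(NA_character_, length(x))
  prec[!is.na(x) & grepl("^[0-9]{8}$", x)] <- "day"
  prec[!is.na(x) & grepl("^[0-9]{6}$", x)] <- "month"
  prec[!is.na(x) & grepl("^[0-9]{4}$", x)] <- "year"
  d <- rep(as.Date(NA), length(x))
  day <- which(prec == "day")
  if (length(day)) {
    dd <- as.Date(x[day], format = "%Y%m%d")
    # reject impossible calendar dates (e.g. 20230230)
    bad <- is.na(dd)
    prec[day[bad]] <- NA_character_
    d[day[!bad]] <- dd[!bad]
  }
  mon <- which(prec == "month")
  if (length(mon)) {
    mm <- as.integer(substr(x[mon], 5, 6))
    prec[mon[mm < 1 | mm > 12]] <- NA_character_
  }
  value <- x
  value[is.na(prec)] <- NA_character_
  list(value = value, prec = prec, date = d)
}

date_to_int <- function(d) as.integer(format(d, "%Y%m%d"))
int_to_date <- function(x) as.Date(sprintf("%08d", as.integer(x)), format = "%Y%m%d")
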