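#' Convert FAERS age values to years
#'
#' FAERS ages carry a unit code: DEC (decades), YR (years), MON (months),
#' WK (weeks), DY (days), HR (hours). A missing code is treated as years.
#' Negative values are invalid and become `NA` with a warning.
#'
#' @param value numeric age values.
#' @param code unit codes (recycled against `value`).
#' @return Numeric vector of ages in years.
#' @examples
#' normalize_age(720, "MON")  # 60
#' normalize_age(7.2, "DEC")  # 72
#' @export
normalize_age <- function(value, code = NA_character_) {
  value <- as.numeric(value)
  code <- toupper(trimws(as.character(code)))
  code <- rep_len(code, length(value))
  factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.18,
              DY = 1 / 365.25, HR = 1 / 8766)
  f <- factor[code]
  f[is.na(code) | !nzchar(code)] <- 1
  unknown <- !is.na(code) & nzchar(code) & !code %in% names(factor)
  f[unknown] <- NA_real_
  out <- unname(value * f)
  neg <- !is.na(value) & value < 0
  if (any(neg)) {
    warning(sum(neg), " negative age value(s) set to NA")
    out[neg] <- NA_real_
  }
  out
}

#' Build the analysis cohort for a set of reports
#'
#' Joins the deduplicated DEMO rows in `ids` with their reactions and
#' therapy rows. PT labels are case-normalized and deduplicated within
#' each report; reports with no reaction rows are excluded and counted.
#' When `patterns` is supplied, therapy rows are restricted to the drug
#' sequences whose DRUG row matches the patterns (the target drug's
#' therapy starts, used for time-to-onset).
#'
#' @param raw a `faers_quarter` (typically concatenated quarters).
#' @param ids primaryids to include (subset of the deduplicated DEMO ids).
#' @param patterns optional drug-name patterns identifying the target drug
#'   for therapy linkage.
#' @return An object of class `faers_cohort`: list with `cases` (one row
#'   per report: demographics, `age_years`, event date fields, `n_pts`),
#'   `reactions` (primaryid, pt), `therapy` (primaryid, dsg_drug_seq,
#'   start date fields), and `log`.
#' @export
build_cohort <- function(raw, ids, patterns = NULL) {
  stopifnot(inherits(raw, "faers_quarter"))
  demo <- raw$tables$demo[primaryid %in% ids]
  reac <- raw$tables$reac[primaryid %in% ids]
  reac <- unique(data.table::data.table(primaryid = reac$primaryid,
                                        pt = norm_pt(reac$pt)))
  has_reac <- unique(reac$primaryid)
  excluded <- setdiff(demo$primaryid, has_reac)
  demo <- demo[primaryid %in% has_reac]

  age_years <- if (all(c("age", "age_cod") %in% names(demo))) {
    normalize_age(demo$age, demo$age_cod)
  } else rep(NA_real_, nrow(demo))
  cases <- data.table::data.table(
    primaryid = demo$primaryid,
    caseid = demo[["caseid"]],
    age_years = age_years,
    sex = demo[["sex"]] %||% rep(NA_character_, nrow(demo)),
    occp_cod = demo[["occp_cod"]] %||% rep(NA_character_, nrow(demo)),
    occr_country = demo[["occr_country"]] %||% rep(NA_character_, nrow(demo)),
    rept_yr = demo[["rept_yr"]] %||% rep(NA_integer_, nrow(demo)),
    event_dt = demo[["event_dt"]] %||% rep(NA_character_, nrow(demo)),
    event_dt_prec = demo[["event_dt_prec"]] %||% rep(NA_character_, nrow(demo)),
    event_date = demo[["event_date"]] %||% rep(as.Date(NA), nrow(demo)))
  cases <- merge(cases, reac[, .(n_pts = .N), by = primaryid],
                 by = "primaryid", all.x = TRUE)

  ther <- raw$tables$ther
  if (!is.null(ther)) {
    ther <- ther[primaryid %in% cases$primaryid]
    if (!is.null(patterns)) {
      sel <- select_primary_suspect(raw$tables$drug, patterns, role = "PS")
      seqs <- attr(sel, "matches")
      ther <- merge(ther, unique(seqs), by.x = c("primaryid", "dsg_drug_seq"),
                    by.y = c("primaryid", "drug_seq"))
    }
    therapy <- ther[, .(primaryid, dsg_drug_seq, start_dt, start_prec, start_date)]
  } else {
    therapy <- data.table::data.table(
      primaryid = character(0), dsg_drug_seq = integer(0),
      start_dt = character(0), start_prec = character(0),
      start_date = as.Date(character(0)))
  }
  structure(list(cases = cases, reactions = reac, therapy = therapy,
                 log = list(excluded_no_reaction = length(excluded))),
            class = "faers_cohort")
}

#' Demographic descriptives of a cohort
#'
#' Tabulates sex, age bins, top reporting countries, reporter occupation
#' and reporting year, with percentages of the case total rounded
#' half-up to one decimal. Age bins partition at 18, 65 and 85 years
#' (`<18`, `18-65` = \[18, 65), `65-85` = \[65, 85\], `>85`); occupation
#' codes map MD -> Physician, CN -> Consumer, HP and OT -> Health
#' professionals, PH -> Pharmacist; anything absent falls in `Miss`.
#'
#' @param cohort a `faers_cohort`.
#' @param top_countries how many countries to list individually (rest
#'   pooled as `Other`).
#' @return data.table with columns `section`, `level`, `n`, `pct`; the
#'   case total is attached as attribute `total`.
#' @export
summarize_demographics <- function(cohort, top_countries = 5L) {
  stopifnot(inherits(cohort, "faers_cohort"))
  cases <- cohort$cases
  total <- nrow(cases)
  if (!total) stop("empty cohort")

  tab <- function(section, x, levels = NULL) {
    cnt <- table(x)
    dt <- data.table::data.table(section = section,
                                 level = names(cnt),
                                 n = as.integer(cnt))
    if (!is.null(levels)) {
      dt <- dt[match(levels[levels %in% dt$level], level)]
    }
    dt
  }

  sex <- ifelse(is.na(cases$sex), "Miss",
                ifelse(cases$sex == "M", "Male",
                       ifelse(cases$sex == "F", "Female", "Miss")))
  sex_dt <- tab("sex", sex, c("Male", "Female", "Miss"))

  age <- cases$age_years
  bin <- ifelse(is.na(age), "Miss",
         ifelse(age < 18, "<18",
         ifelse(age < 65, "18-65",
         ifelse(age <= 85, "65-85", ">85"))))
  age_dt <- tab("age", bin, c("<18", "18-65", "65-85", ">85", "Miss"))

  ctry <- ifelse(is.na(cases$occr_country), "Miss", cases$occr_country)
  cnt <- sort(table(ctry[ctry != "Miss"]), decreasing = TRUE)
  top <- names(cnt)[seq_len(min(top_countries, length(cnt)))]
  ctry2 <- ifelse(ctry %in% c(top, "Miss"), ctry, "Other")
  ctry_dt <- tab("country", ctry2, c(top, "Other", "Miss"))

  occ_map <- c(MD = "Physician", CN = "Consumer", HP = "Health professionals",
               OT = "Health professionals", PH = "Pharmacist")
  occ <- occ_map[cases$occp_cod]
  occ[is.na(occ)] <- "Miss"
  occ_dt <- tab("reporter", occ, c("Physician", "Consumer",
                                   "Health professionals", "Pharmacist", "Miss"))

  yr <- ifelse(is.na(cases$rept_yr), "Miss", as.character(cases$rept_yr))
  yr_dt <- tab("year", yr)

  out <- data.table::rbindlist(list(sex_dt, age_dt, ctry_dt, occ_dt, yr_dt))
  out[, pct := round_half_up(100 * n / total, 1)]
  data.table::setattr(out, "total", total)
  out[]
}
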