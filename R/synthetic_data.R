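#' Bundled miniature PT/SOC ontology
#'
#' A deterministic catalog of MedDRA-like preferred-term labels grouped
#' under system-organ-class headings (structure resembling, not copying,
#' the licensed dictionary). With the defaults it yields 60 PTs over 6
#' SOCs; `n_per_soc` can be raised, extra labels being suffixed grades.
#'
#' @param n_per_soc preferred terms per organ class (>= 1).
#' @return data.table with columns `pt`, `soc`.
#' @export
mini_meddra <- function(n_per_soc = 10L) {
  socs <- list(
    "eye disorders" = c("ocular", "retinal"),
    "cardiac disorders" = c("myocardial", "pericardial"),
    "nervous system disorders" = c("cranial", "neural"),
    "gastrointestinal disorders" = c("gastric", "intestinal"),
    "skin and subcutaneous tissue disorders" = c("dermal", "subcutaneous"),
    "general disorders and administration site conditions" =
      c("systemic", "injection site"))
  path <- c("inflammation", "haemorrhage", "pain", "oedema", "degeneration")
  out <- data.table::rbindlist(lapply(names(socs), function(s) {
    base <- as.vector(outer(socs[[s]], path, paste))
    pts <- base
    g <- 2L
    while (length(pts) < n_per_soc) {
      pts <- c(pts, paste(base, "grade", g))
      g <- g + 1L
    }
    data.table::data.table(pt = pts[seq_len(n_per_soc)], soc = s)
  }))
  out[]
}

#' Configuration for the synthetic FAERS report generator
#'
#' The defaults emulate the reporting structure of a recent intravitreal
#' anti-VEGF pharmacovigilance cohort: demographic and missingness rates
#' from its published case characteristics, onset times from
#' Weibull(shape 0.80, scale 133.72 days) with 16% of reports carrying
#' complete onset and therapy-start dates, about 2.1 distinct reactions
#' per case (1 + Poisson(1.1), capped at 6), report years weighted
#' 5.2/27.1/67.7 across 2022-2024, and three comparator drugs. Five
#' eye-disorder preferred terms carry an injected relative risk of 12 for
#' the target drug, sized so that an expected signal cell of ~90 records
#' clears all four positivity thresholds with margin (see the methods
#' vignette). Case totals default to 400 target + 3 x 2000 comparator
#' cases - a desk-scale stand-in, not the full database.
#'
#' @param seed integer seed; mandatory, all randomness derives from it.
#' @param n_cases named integer vector of cases per drug; the first name
#'   is the signal target drug.
#' @param pt_map PT/SOC catalog (data.table `pt`, `soc`), >= 50 PTs over
#'   >= 5 SOCs by default.
#' @param signals data.table (`drug`, `pt`, `rr`) of injected relative
#'   risks (`NULL` for the default five; pass an empty data.table for a
#'   global null).
#' @param pts_per_case_lambda Poisson rate of extra PTs per case.
#' @param max_pts_per_case cap on distinct PTs per case.
#' @param duplicate_rate fraction of cases emitted as 2-3 report versions
#'   with distinct FDA receipt dates.
#' @param missingness named rates for absent sex/age/country/occupation.
#' @param tto list with Weibull `shape`, `scale` (days) and
#'   `frac_complete`, the fraction of cases with full event and start
#'   dates.
#' @param concomitant_rate chance of an extra concomitant (role C) drug
#'   row per report.
#' @param year_prob named report-year weights.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_cases = c(faricimab = 400, ranibizumab = 2000,
                                   aflibercept = 2000, bevacizumab = 2000),
                       pt_map = mini_meddra(),
                       signals = NULL,
                       pts_per_case_lambda = 1.1,
                       max_pts_per_case = 6L,
                       duplicate_rate = 0.25,
                       missingness = c(sex = 0.249, age = 0.423,
                                       country = 0.05, occp = 0.002),
                       tto = list(shape = 0.80, scale = 133.72,
                                  frac_complete = 0.16),
                       concomitant_rate = 0.3,
                       year_prob = c("2022" = 0.052, "2023" = 0.271,
                                     "2024" = 0.677)) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(names(n_cases)) || any(!nzchar(names(n_cases)))) {
    stop("n_cases must be a named vector (one entry per drug)")
  }
  if (is.null(signals)) {
    sig_pts <- pt_map[soc == "eye disorders", pt][1:5]
    sig_pts <- sig_pts[!is.na(sig_pts)]
    signals <- data.table::data.table(drug = names(n_cases)[1],
                                      pt = sig_pts, rr = 12)
  }
  stopifnot(all(signals$rr >= 0), all(signals$pt %in% pt_map$pt),
            all(signals$drug %in% names(n_cases)),
            duplicate_rate >= 0, duplicate_rate <= 1,
            all(missingness >= 0 & missingness <= 1),
            tto$shape > 0, tto$scale > 0,
            tto$frac_complete >= 0, tto$frac_complete <= 1)
  structure(list(seed = as.integer(seed), n_cases = n_cases, pt_map = pt_map,
                 signals = signals,
                 pts_per_case_lambda = pts_per_case_lambda,
                 max_pts_per_case = as.integer(max_pts_per_case),
                 duplicate_rate = duplicate_rate, missing = missingness,
                 tto = tto, concomitant_rate = concomitant_rate,
                 year_prob = year_prob),
            class = "sim_config")
}

# per-drug PT sampling weights under the injected relative risks
pt_weights <- function(config, drug) {
  w <- rep(1, nrow(config$pt_map))
  names(w) <- config$pt_map$pt
  sel <- which(as.data.frame(config$signals)$drug == drug)
  if (length(sel)) w[config$signals$pt[sel]] <- config$signals$rr[sel]
  w
}

# expected distinct PTs per case: E[min(1 + Pois(lambda), cap)]
mean_pts_per_case <- function(lambda, cap) {
  k <- 0:(cap - 2L)
  sum((1 + k) * stats::dpois(k, lambda)) +
    cap * (1 - stats::ppois(cap - 2L, lambda))
}

#' Closed-form expected contingency cells for a generator configuration
#'
#' First-order oracle under the conditional generative model: each drug's
#' expected record total is its case count times the truncated-Poisson
#' mean PT count, and each record's PT follows the renormalized weight
#' vector `rr / sum(rr)`. Within-case distinctness of PTs makes the true
#' cell means for strongly elevated PTs up to a couple of percent lower;
#' tests compare Monte-Carlo means against this oracle at moderate
#' relative risks where the approximation is well inside sampling noise.
#'
#' @param config a [sim_config()].
#' @return data.table with per (drug, pt) expected cells `a`, `b`, `c`,
#'   `d` and the expected reporting odds ratio `exp_ror`.
#' @export
expected_tables <- function(config) {
  drugs <- names(config$n_cases)
  mp <- mean_pts_per_case(config$pts_per_case_lambda, config$max_pts_per_case)
  R <- config$n_cases * mp
  p <- vapply(drugs, function(d) {
    w <- pt_weights(config, d)
    w / sum(w)
  }, numeric(nrow(config$pt_map)))
  a <- sweep(p, 2, R, `*`)                  # pts x drugs
  ac <- rowSums(a)
  out <- data.table::rbindlist(lapply(seq_along(drugs), function(j) {
    aa <- a[, j]
    data.table::data.table(drug = drugs[j], pt = config$pt_map$pt,
                           a = aa, b = R[j] - aa, c = ac - aa,
                           d = sum(R) - R[j] - (ac - aa))
  }))
  out[, exp_ror := (a * d) / (b * c)]
  out[]
}

#' Generate synthetic FAERS quarterly files
#'
#' Writes "$"-delimited DEMO/DRUG/REAC/THER files (one set per quarter in
#' the span covered by the drawn receipt dates), a `pt_soc_map.csv`, and a
#' `manifest.json` with the ground truth (case counts, duplicate groups,
#' injected signals with their expected cells, true Weibull parameters).
#' Fully reproducible: the same config yields byte-identical files.
#'
#' Duplicate report versions reuse the caseid with a new, higher
#' primaryid and an FDA receipt date shifted 1-90 days later, mimicking
#' FAERS follow-up reports; deduplication must recover exactly one row
#' per case.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created; must be writable).
#' @return invisibly, a list with `dir`, `quarters`, the ground-truth
#'   `manifest`, and the in-memory `tables` (before version duplication
#'   splitting, for fast oracle checks).
#' @export
simulate_faers <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  set.seed(config$seed)

  drugs <- names(config$n_cases)
  n_total <- sum(config$n_cases)
  case_drug <- rep(drugs, config$n_cases)
  caseid <- sprintf("C%07d", seq_len(n_total))
  base_pid <- (seq_len(n_total) + 1000L) * 10L

  # receipt dates: year weighted, uniform within year (2024 capped at Q2)
  yr <- sample(names(config$year_prob), n_total, TRUE, config$year_prob)
  span <- list("2022" = c("2022-01-01", "2022-12-31"),
               "2023" = c("2023-01-01", "2023-12-31"),
               "2024" = c("2024-01-01", "2024-06-30"))
  fda_date <- as.Date(vapply(yr, function(y) {
    s <- as.Date(span[[y]][1]); e <- as.Date(span[[y]][2])
    as.numeric(s) + floor(stats::runif(1) * (as.numeric(e) - as.numeric(s) + 1))
  }, 0), origin = "1970-01-01")

  # distinct PTs per case, weighted by the injected relative risks
  npts <- pmin(1L + stats::rpois(n_total, config$pts_per_case_lambda),
               config$max_pts_per_case)
  wlist <- lapply(drugs, function(d) pt_weights(config, d))
  names(wlist) <- drugs
  pts_idx <- lapply(seq_len(n_total), function(i) {
    sample.int(nrow(config$pt_map), npts[i], prob = wlist[[case_drug[i]]])
  })

  # demographics
  miss <- config$missing
  sex <- ifelse(stats::runif(n_total) < miss["sex"], NA,
                ifelse(stats::runif(n_total) < 0.528, "F", "M"))
  age_bin <- sample(c("<18", "18-65", "65-85", ">85"), n_total, TRUE,
                    c(0.035, 0.295, 0.556, 0.114))
  lo <- c("<18" = 1, "18-65" = 18, "65-85" = 65, ">85" = 85)[age_bin]
  hi <- c("<18" = 18, "18-65" = 65, "65-85" = 85, ">85" = 100)[age_bin]
  age <- round(lo + stats::runif(n_total) * (hi - lo))
  age[stats::runif(n_total) < miss["age"]] <- NA
  age_cod <- ifelse(is.na(age), NA, "YR")
  country <- sample(c("US", "JP", "CA", "GB", "IN", "DE", "FR", "AU"),
                    n_total, TRUE,
                    c(0.58, 0.08, 0.05, 0.05, 0.05, 0.07, 0.07, 0.05))
  country[stats::runif(n_total) < miss["country"]] <- NA
  occp <- sample(c("MD", "CN", "HP", "OT", "PH"), n_total, TRUE,
                 c(0.614, 0.297, 0.047, 0.024, 0.018))
  occp[stats::runif(n_total) < miss["occp"]] <- NA

  # onset model: therapy start before receipt, event = start + Weibull draw
  tto_true <- stats::rweibull(n_total, config$tto$shape, config$tto$scale)
  complete <- stats::runif(n_total) < config$tto$frac_complete
  start_date <- fda_date - 30L - floor(stats::runif(n_total) * 365)
  event_date <- start_date + round(tto_true)
  fmt <- function(d) format(d, "%Y%m%d")
  event_dt <- ifelse(complete, fmt(event_date),
                     ifelse(stats::runif(n_total) < 0.4, NA,
                            ifelse(stats::runif(n_total) < 0.5,
                                   format(event_date, "%Y%m"),
                                   format(event_date, "%Y"))))
  start_dt <- ifelse(complete, fmt(start_date),
                     ifelse(stats::runif(n_total) < 0.5, NA,
                            format(start_date, "%Y%m")))

  # report versions (duplicates): 2-3 versions, later receipt dates
  n_ver <- ifelse(stats::runif(n_total) < config$duplicate_rate,
                  sample(2:3, n_total, TRUE), 1L)
  ver_case <- rep(seq_len(n_total), n_ver)
  ver_idx <- sequence(n_ver)
  shift <- integer(length(ver_case))
  dup <- ver_idx > 1L
  shift[dup] <- sample(1:90, sum(dup), TRUE) * (ver_idx[dup] - 1L)
  pid <- base_pid[ver_case] + ver_idx - 1L
  v_fda <- fda_date[ver_case] + shift

  demo <- data.table::data.table(
    PRIMARYID = as.character(pid),
    CASEID = caseid[ver_case],
    CASEVERSION = as.character(ver_idx),
    I_F_CODE = ifelse(ver_idx == 1L, "I", "F"),
    FDA_DT = fmt(v_fda),
    EVENT_DT = event_dt[ver_case],
    AGE = ifelse(is.na(age[ver_case]), NA, as.character(age[ver_case])),
    AGE_COD = age_cod[ver_case],
    SEX = sex[ver_case],
    OCCP_COD = occp[ver_case],
    OCCR_COUNTRY = country[ver_case])

  name_style <- function(nm, i) {
    v <- c(toupper(nm), nm, paste0(toupper(substr(nm, 1, 1)),
                                   substr(nm, 2, nchar(nm))))
    v[(i %% 3L) + 1L]
  }
  drugname <- vapply(seq_along(ver_case),
                     function(i) name_style(case_drug[ver_case[i]], i), "")
  drug_ps <- data.table::data.table(
    PRIMARYID = as.character(pid), CASEID = caseid[ver_case],
    DRUG_SEQ = "1", ROLE_COD = "PS", DRUGNAME = drugname,
    PROD_AI = toupper(case_drug[ver_case]))
  conc <- stats::runif(length(ver_case)) < config$concomitant_rate
  other <- vapply(case_drug[ver_case][conc], function(d) {
    pool <- setdiff(drugs, d)
    pool[sample.int(length(pool), 1L)]
  }, "")
  drug_c <- data.table::data.table(
    PRIMARYID = as.character(pid[conc]), CASEID = caseid[ver_case][conc],
    DRUG_SEQ = "2", ROLE_COD = "C", DRUGNAME = toupper(other),
    PROD_AI = toupper(other))
  drug <- rbind(drug_ps, drug_c)
  data.table::setorder(drug, PRIMARYID, DRUG_SEQ)

  pt_labels <- config$pt_map$pt
  reac <- data.table::data.table(
    PRIMARYID = rep(as.character(pid), npts[ver_case]),
    CASEID = rep(caseid[ver_case], npts[ver_case]),
    PT = unlist(pts_idx[ver_case]))
  reac[, PT := pt_labels[as.integer(PT)]]

  has_start <- !is.na(start_dt[ver_case])
  ther <- data.table::data.table(
    PRIMARYID = as.character(pid[has_start]),
    CASEID = caseid[ver_case][has_start],
    DSG_DRUG_SEQ = "1",
    START_DT = start_dt[ver_case][has_start],
    END_DT = NA_character_)

  # write one file set per quarter of the receipt date
  qlab <- paste0(format(v_fda, "%Y"), "Q", (as.POSIXlt(v_fda)$mon %/% 3) + 1L)
  quarters <- sort(unique(qlab))
  qmap <- data.table::data.table(PRIMARYID = as.character(pid), qtr = qlab)
  write_tbl <- function(tb, name) {
    x <- merge(tb, qmap, by = "PRIMARYID", sort = FALSE)
    for (qq in quarters) {
      f <- file.path(outdir, paste0(name, substr(qq, 3, 4), "Q",
                                    substr(qq, 6, 6), ".txt"))
      part <- x[x$qtr == qq, !"qtr"]
      data.table::setorder(part, PRIMARYID)
      data.table::fwrite(part, f, sep = "$", quote = FALSE, na = "")
    }
  }
  write_tbl(demo, "DEMO")
  write_tbl(drug, "DRUG")
  write_tbl(reac, "REAC")
  write_tbl(ther, "THER")
  data.table::fwrite(config$pt_map, file.path(outdir, "pt_soc_map.csv"))

  exp_tab <- expected_tables(config)
  sig <- merge(config$signals, exp_tab, by = c("drug", "pt"), sort = FALSE)
  manifest <- list(
    seed = config$seed,
    n_cases = as.list(config$n_cases),
    n_report_versions = length(pid),
    n_duplicate_groups = sum(n_ver > 1L),
    quarters = quarters,
    weibull = list(shape = config$tto$shape, scale = config$tto$scale,
                   frac_complete = config$tto$frac_complete),
    signals = sig)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = outdir, quarters = quarters, manifest = manifest,
                 tables = list(demo = demo, drug = drug, reac = reac,
                               ther = ther)))
}
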