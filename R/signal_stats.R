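# Vectorized core for the four disproportionality statistics.
#
# Zero-cell handling: when a >= 1 and any of b, c, d is zero, the
# Haldane-Anscombe correction (+0.5 on all four cells) is applied before
# computing statistics and confidence limits, and the `corrected` flag is
# set. a = 0 yields NA statistics (not computable).
#
# IC025 modes:
#   fixed_offset (default): ic025 = ic - delta with delta = 1.67, the
#     count-independent gap observed between IC and its lower limit in
#     published four-algorithm FAERS analyses of this design.
#   delta: ic025 = ic - 2*sqrt(V) with the delta-method variance
#     V = (1/ln 2)^2 (1/a - 1/(a+b) + 1/(a+c) - 1/N).
disprop_stats <- function(a, b, c, d,
                          ic_mode = c("fixed_offset", "delta"),
                          ic_delta = 1.67) {
  ic_mode <- match.arg(ic_mode)
  corrected <- a >= 1 & (b == 0 | c == 0 | d == 0)
  k <- 0.5 * corrected
  aa <- a + k; bb <- b + k; cc <- c + k; dd <- d + k
  N <- aa + bb + cc + dd
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  ror <- (aa * dd) / (bb * cc)
  prr <- aa * (cc + dd) / (cc * (aa + bb))
  chi2 <- (aa * dd - bb * cc)^2 * N /
    ((aa + bb) * (cc + dd) * (aa + cc) * (bb + dd))
  ebgm <- aa * N / ((aa + cc) * (aa + bb))
  ic <- log2(ebgm)
  vic <- (1 / log(2))^2 * (1 / aa - 1 / (aa + bb) + 1 / (aa + cc) - 1 / N)
  ic025 <- if (ic_mode == "fixed_offset") ic - ic_delta else ic - 2 * sqrt(vic)
  out <- data.table::data.table(
    a = a, b = b, c = c, d = d,
    ror = ror, ror_lo = ror * exp(-1.96 * se), ror_hi = ror * exp(1.96 * se),
    prr = prr, chi2 = chi2, ic = ic, ic025 = ic025,
    ebgm = ebgm, ebgm05 = ebgm * exp(-1.96 * se),
    corrected = corrected)
  bad <- a < 1
  if (any(bad)) {
    for (col in c("ror", "ror_lo", "ror_hi", "prr", "chi2", "ic", "ic025",
                  "ebgm", "ebgm05")) {
      data.table::set(out, which(bad), col, NA_real_)
    }
  }
  out
}

#' Reporting odds ratio with lognormal 95% confidence interval
#'
#' `ROR = ad / (bc)`; `CI = exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param t a [contingency_table()].
#' @param ... passed to the shared statistic core (e.g. `ic_delta`).
#' @return list with `ror`, `ci95` (low, high) and `corrected`.
#' @examples
#' compute_ror(contingency_table(10, 20, 30, 240))$ror  # 4
#' @export
compute_ror <- function(t, ...) {
  s <- disprop_stats(t$a, t$b, t$c, t$d, ...)
  list(ror = s$ror, ci95 = c(s$ror_lo, s$ror_hi), corrected = s$corrected)
}

#' Proportional reporting ratio and chi-squared statistic
#'
#' `PRR = a(c+d) / (c(a+b))`; the chi-squared statistic is the usual
#' Pearson form `(ad - bc)^2 N / ((a+b)(c+d)(a+c)(b+d))` without
#' continuity correction.
#'
#' @inheritParams compute_ror
#' @return list with `prr`, `chi2` and `corrected`.
#' @export
compute_prr <- function(t, ...) {
  s <- disprop_stats(t$a, t$b, t$c, t$d, ...)
  list(prr = s$prr, chi2 = s$chi2, corrected = s$corrected)
}

#' Information component (BCPNN) with lower 95% limit
#'
#' `IC = log2( a N / ((a+c)(a+b)) )`, the base-2 log of the
#' observed-to-expected reporting ratio. The lower limit uses either a
#' fixed offset of 1.67 below IC (default) or the delta-method variance;
#' see the methods vignette for the rationale.
#'
#' @inheritParams compute_ror
#' @param mode `"fixed_offset"` or `"delta"`.
#' @return list with `ic`, `ic025`, `mode` and `corrected`.
#' @export
compute_ic <- function(t, mode = c("fixed_offset", "delta"), ...) {
  mode <- match.arg(mode)
  s <- disprop_stats(t$a, t$b, t$c, t$d, ic_mode = mode, ...)
  list(ic = s$ic, ic025 = s$ic025, mode = mode, corrected = s$corrected)
}

#' Relative reporting ratio (EBGM as printed) with lower 95% limit
#'
#' `EBGM = a N / ((a+c)(a+b))` - the raw observed-to-expected relative
#' reporting ratio with a lognormal confidence limit, exactly as used in
#' the four-algorithm FAERS literature this package targets. Note this is
#' not the shrinkage estimator of the full MGPS gamma-Poisson model; the
#' name is kept for comparability with published tables.
#'
#' @inheritParams compute_ror
#' @return list with `ebgm`, `ebgm05` and `corrected`.
#' @export
compute_ebgm <- function(t, ...) {
  s <- disprop_stats(t$a, t$b, t$c, t$d, ...)
  list(ebgm = s$ebgm, ebgm05 = s$ebgm05, corrected = s$corrected)
}

#' Positivity thresholds for the four algorithms
#'
#' Defaults: ROR positive when the lower 95% limit exceeds 1 and `n >= 3`;
#' PRR positive when `PRR >= 2`, `chi2 >= 4` and `n >= 3`; BCPNN positive
#' when `IC025 > 0`; MGPS positive when `EBGM05 > 2`.
#'
#' @param ror_ci_low,ror_min_n,prr_min,chi2_min,prr_min_n,ic025_min,ebgm05_min
#'   individual threshold overrides.
#' @return list of thresholds.
#' @export
signal_thresholds <- function(ror_ci_low = 1, ror_min_n = 3, prr_min = 2,
                              chi2_min = 4, prr_min_n = 3, ic025_min = 0,
                              ebgm05_min = 2) {
  list(ror_ci_low = ror_ci_low, ror_min_n = ror_min_n, prr_min = prr_min,
       chi2_min = chi2_min, prr_min_n = prr_min_n, ic025_min = ic025_min,
       ebgm05_min = ebgm05_min)
}

apply_thresholds <- function(out, th) {
  out[, flag_ror := !is.na(ror_lo) & ror_lo > th$ror_ci_low & n >= th$ror_min_n]
  out[, flag_prr := !is.na(prr) & prr >= th$prr_min & chi2 >= th$chi2_min &
        n >= th$prr_min_n]
  out[, flag_bcpnn := !is.na(ic025) & ic025 > th$ic025_min]
  out[, flag_mgps := !is.na(ebgm05) & ebgm05 > th$ebgm05_min]
  out[, combined := flag_ror & flag_prr & flag_bcpnn & flag_mgps]
  out
}

#' Evaluate one contingency table against the positivity thresholds
#'
#' @param t a [contingency_table()].
#' @param thresholds see [signal_thresholds()].
#' @param ic_mode IC lower-limit mode, `"fixed_offset"` or `"delta"`.
#' @return one-row data.table with the term, n (= a), all four statistics
#'   and their limits, per-algorithm flags and the combined (four-way)
#'   flag.
#' @export
evaluate_signal <- function(t, thresholds = signal_thresholds(),
                            ic_mode = c("fixed_offset", "delta")) {
  ic_mode <- match.arg(ic_mode)
  s <- disprop_stats(t$a, t$b, t$c, t$d, ic_mode = ic_mode)
  out <- cbind(data.table::data.table(term = t$term, level = t$level, n = t$a), s)
  apply_thresholds(out, thresholds)[]
}

#' Full signal table for one drug at PT or SOC level
#'
#' Builds every term's contingency table from the record list and
#' evaluates the four algorithms. This is the vectorized equivalent of
#' calling [build_pt_table()] + [evaluate_signal()] per term.
#'
#' @param records `faers_records` from [enumerate_records()].
#' @param drug drug label in `records$drug`.
#' @param level `"pt"` or `"soc"`.
#' @param map PT to SOC map, required at SOC level.
#' @param min_n report only terms with at least this many target-drug
#'   records (default 1).
#' @param thresholds see [signal_thresholds()].
#' @param ic_mode IC lower-limit mode.
#' @return data.table sorted by n descending, one row per term, with the
#'   columns of [evaluate_signal()].
#' @export
signal_table <- function(records, drug, level = c("pt", "soc"), map = NULL,
                         min_n = 1L, thresholds = signal_thresholds(),
                         ic_mode = c("fixed_offset", "delta")) {
  level <- match.arg(level)
  ic_mode <- match.arg(ic_mode)
  isdrug <- drug_mask(records, drug)
  if (!any(isdrug)) stop("no records for drug '", drug, "'")
  term_vec <- if (level == "pt") {
    records$pt
  } else {
    if (is.null(map)) stop("a PT->SOC map is required at SOC level")
    map_soc(records$pt, map)
  }
  x <- data.table::data.table(term = term_vec, isd = isdrug)
  cnt <- x[, .(ac = .N, a = sum(isd)), by = term]
  drug_total <- sum(x$isd)
  N <- nrow(x)
  s <- disprop_stats(cnt$a, drug_total - cnt$a, cnt$ac - cnt$a,
                     N - drug_total - (cnt$ac - cnt$a), ic_mode = ic_mode)
  out <- cbind(data.table::data.table(term = cnt$term, level = level,
                                      n = cnt$a), s)
  out <- apply_thresholds(out, thresholds)
  out <- out[n >= min_n]
  data.table::setorder(out, -n, term)
  out[]
}

#' Positive term sets per algorithm and their intersections
#'
#' @param results a signal table from [signal_table()] (one level).
#' @return list with `sets` (positive terms per algorithm), `intersection`
#'   (terms positive on all four), and `region_counts`, the count of terms
#'   per positivity signature (letters R, P, B, M for ROR, PRR, BCPNN,
#'   MGPS; e.g. `"RPBM"` is the four-way region of the Venn diagram).
#' @export
intersect_positive <- function(results) {
  sets <- list(ror = results$term[results$flag_ror],
               prr = results$term[results$flag_prr],
               bcpnn = results$term[results$flag_bcpnn],
               mgps = results$term[results$flag_mgps])
  sig <- paste0(ifelse(results$flag_ror, "R", ""),
                ifelse(results$flag_prr, "P", ""),
                ifelse(results$flag_bcpnn, "B", ""),
                ifelse(results$flag_mgps, "M", ""))
  sig[sig == ""] <- "none"
  list(sets = sets,
       intersection = Reduce(intersect, sets),
       region_counts = table(sig))
}

#' Compare the reporting odds ratio of several drugs for listed terms
#'
#' Each drug is contrasted independently against all other drugs in the
#' record list. Terms with no record for a drug are marked not reported
#' (`nr = TRUE`, NA statistics), matching the "NR" convention of
#' published comparison tables.
#'
#' @param records `faers_records` covering all drugs.
#' @param drugs character vector of at least two drug labels.
#' @param terms PT labels to compare.
#' @return data.table with columns `drug`, `term`, `n`, `ror`, `ror_lo`,
#'   `ror_hi`, `nr`.
#' @export
compare_drugs <- function(records, drugs, terms) {
  if (length(drugs) < 2L) stop("need at least two drugs to compare")
  terms <- norm_pt(terms)
  out <- data.table::rbindlist(lapply(drugs, function(dg) {
    isd <- drug_mask(records, dg)
    drug_total <- sum(isd)
    N <- nrow(records)
    a <- vapply(terms, function(t) sum(isd & records$pt == t), 0L)
    ac <- vapply(terms, function(t) sum(records$pt == t), 0L)
    s <- disprop_stats(a, drug_total - a, ac - a, N - drug_total - (ac - a))
    data.table::data.table(drug = dg, term = terms, n = a,
                           ror = s$ror, ror_lo = s$ror_lo, ror_hi = s$ror_hi,
                           nr = a == 0L)
  }))
  out[nr == TRUE, c("ror", "ror_lo", "ror_hi") := NA_real_]
  out[]
}

#' Reconstruct contingency cells from published summary statistics
#'
#' Validation utility: given a published cell `a`, the drug's record total
#' `a + b`, and the printed ROR and EBGM of a row, solves the two
#' remaining cells. `c/d` follows from `ROR = (a/b)/(c/d)` and the
#' absolute scale from `EBGM = a N / ((a+c)(a+b))`. The returned cells are
#' real-valued; a consistency report with all four statistics recomputed
#' from them is attached as attribute `consistency`.
#'
#' @param a target-drug/target-event record count.
#' @param drug_total the drug's total record count (`a + b`).
#' @param ror published reporting odds ratio (> 0).
#' @param ebgm published relative reporting ratio (> 0, != 1).
#' @return A `contingency_table` with real-valued `c` and `d`.
#' @examples
#' tab <- reconstruct_counts(2109, 5691, ror = 29.56, ebgm = 18.81)
#' attr(tab, "consistency")$prr  # ~ 18.97
#' @export
reconstruct_counts <- function(a, drug_total, ror, ebgm) {
  stopifnot(ror > 0, ebgm > 0, drug_total > a, a > 0)
  b <- drug_total - a
  r <- a / (ror * b)                       # c/d ratio
  den <- a * (1 + r) - ebgm * r * drug_total
  num <- a * drug_total * (ebgm - 1)
  if (abs(ebgm - 1) < 1e-12) {
    # RR = 1: the scale is indeterminate (any balanced table with
    # c/d = a/b works); require marginal consistency and return the
    # representative with other-drug margin equal to the drug margin.
    if (abs(den) > 1e-8 * drug_total) {
      stop("inconsistent published statistics: ror and ebgm disagree at RR = 1")
    }
    d <- drug_total / (1 + r)
    cc <- r * d
  } else {
    d <- num / den
    if (!is.finite(d) || d <= 0) stop("inconsistent published statistics")
    cc <- r * d
  }
  tab <- contingency_table(a, b, cc, d)
  attr(tab, "consistency") <- disprop_stats(a, b, cc, d)
  tab
}
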