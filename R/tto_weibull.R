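#' Extract time-to-onset records from a cohort
#'
#' Time to onset (TTO) is the number of days from the first day-precision
#' therapy start of the target drug to the adverse-event onset date of the
#' report. Reports are excluded - with a reason code - when either date is
#' absent or only partially known (month or year precision), or when the
#' event precedes the start. A same-day onset (0 days) is remapped to 0.5
#' days so the values stay inside the strictly positive Weibull support.
#'
#' @param cohort a `faers_cohort` built with the target drug's `patterns`
#'   (so that `therapy` holds only the target drug's rows).
#' @return data.table of class `tto_records` with `primaryid` and
#'   `tto_days`; attributes `exclusions` (data.table of reason counts) and
#'   `n_zero_remapped`.
#' @export
extract_tto <- function(cohort) {
  stopifnot(inherits(cohort, "faers_cohort"))
  cases <- cohort$cases
  th <- cohort$therapy[start_prec == "day" & !is.na(start_date)]
  minstart <- th[, .(start = min(start_date)), by = primaryid]
  has_any_ther <- unique(cohort$therapy$primaryid)

  x <- merge(cases[, .(primaryid, event_dt_prec, event_date)],
             minstart, by = "primaryid", all.x = TRUE)
  reason <- rep(NA_character_, nrow(x))
  reason[is.na(x$event_dt_prec)] <- "missing event date"
  ev_partial <- is.na(reason) & x$event_dt_prec != "day"
  reason[ev_partial] <- "partial event date"
  no_start <- is.na(reason) & is.na(x$start)
  reason[no_start & !x$primaryid %in% has_any_ther] <- "missing start date"
  reason[no_start & x$primaryid %in% has_any_ther] <- "partial start date"
  tto <- as.numeric(x$event_date - x$start)
  reason[is.na(reason) & tto < 0] <- "negative"

  keep <- is.na(reason)
  n_zero <- sum(keep & tto == 0)
  tto[keep & tto == 0] <- 0.5
  out <- data.table::data.table(primaryid = x$primaryid[keep],
                                tto_days = tto[keep])
  excl <- data.table::as.data.table(table(reason = reason[!keep]))
  data.table::setattr(out, "exclusions", excl)
  data.table::setattr(out, "n_zero_remapped", n_zero)
  data.table::setattr(out, "class", c("tto_records", class(out)))
  out[]
}

tto_vector <- function(ttos) {
  t <- if (is.data.frame(ttos)) ttos$tto_days else as.numeric(ttos)
  if (anyNA(t)) stop("tto values must be non-missing")
  t
}

#' Summarize time-to-onset values
#'
#' Median and quartiles use the inclusive linear-interpolation definition
#' (R's default quantile type 7); the histogram bins days into 30-day
#' months.
#'
#' @param ttos `tto_records` or numeric vector of positive days.
#' @param bin_days histogram bin width in days (default 30).
#' @return list with `n`, `median`, `q1`, `q3`, `iqr`, and `hist`
#'   (data.table of `bin_start`, `bin_end`, `count`).
#' @export
summarize_tto <- function(ttos, bin_days = 30) {
  t <- tto_vector(ttos)
  if (!length(t)) stop("no time-to-onset values")
  q <- stats::quantile(t, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  brk <- seq(0, bin_days * ceiling(max(t) / bin_days), by = bin_days)
  cnt <- table(cut(t, breaks = brk, include.lowest = TRUE, right = TRUE))
  list(n = length(t), median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
       hist = data.table::data.table(bin_start = brk[-length(brk)],
                                     bin_end = brk[-1],
                                     count = as.integer(cnt)))
}

#' Fit a two-parameter Weibull model to time-to-onset data
#'
#' Maximum likelihood via the profile score equation in the shape: for a
#' given shape `beta` the scale has the closed form
#' `alpha = (mean(t^beta))^(1/beta)`, and the profile score
#' `1/beta + mean(log t) - sum(t^beta log t)/sum(t^beta)` is monotone, so
#' its root (found to a score norm below 1e-8) is the global MLE.
#' Confidence intervals use the observed information on the log-parameter
#' scale, exponentiated back, which keeps the bounds positive.
#'
#' @param ttos `tto_records` or positive numeric vector, n >= 10.
#' @return Object of class `weibull_fit`: `n`, `shape` + `shape_ci`,
#'   `scale` (days) + `scale_ci`, `loglik`, `failure_class` (see
#'   [classify_failure()]) and the log-scale covariance `vcov_log`.
#' @examples
#' set.seed(1)
#' fit <- fit_weibull(rweibull(500, shape = 0.8, scale = 134))
#' fit$shape
#' @export
fit_weibull <- function(ttos) {
  t <- tto_vector(ttos)
  if (length(t) < 10L) stop("need at least 10 time-to-onset values")
  if (any(t <= 0)) stop("time-to-onset values must be positive")
  if (max(t) == min(t)) stop("degenerate sample: all values identical")
  lt <- log(t)
  score <- function(beta) {
    tb <- (t / max(t))^beta          # scaled to avoid overflow
    1 / beta + mean(lt) - sum(tb * lt) / sum(tb)
  }
  lo <- 1e-3; hi <- 1
  while (score(hi) > 0 && hi < 1e3) hi <- hi * 2
  if (score(lo) < 0 || score(hi) > 0) {
    stop("Weibull shape score has no root in [", lo, ", ", hi, "]")
  }
  root <- stats::uniroot(score, c(lo, hi), tol = 1e-12)
  beta <- root$root
  if (abs(score(beta)) > 1e-8) {
    stop("Weibull fit did not converge: |score| = ", abs(score(beta)),
         " after ", root$iter, " iterations")
  }
  alpha <- exp(log(mean(exp(beta * (lt - max(lt))))) / beta + max(lt))
  nll <- function(p) -sum(stats::dweibull(t, shape = exp(p[2]),
                                          scale = exp(p[1]), log = TRUE))
  H <- stats::optimHess(c(log(alpha), log(beta)), nll)
  V <- solve(H)
  se <- sqrt(diag(V))
  scale_ci <- alpha * exp(c(-1, 1) * 1.96 * se[1])
  shape_ci <- beta * exp(c(-1, 1) * 1.96 * se[2])
  fit <- structure(list(n = length(t), shape = beta, shape_ci = shape_ci,
                        scale = alpha, scale_ci = scale_ci,
                        loglik = -nll(c(log(alpha), log(beta))),
                        vcov_log = V),
                   class = "weibull_fit")
  fit$failure_class <- classify_failure(fit)
  fit
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull fit (n = %d)\n", x$n))
  cat(sprintf("  scale alpha = %.2f d (95%% CI %.2f-%.2f)\n",
              x$scale, x$scale_ci[1], x$scale_ci[2]))
  cat(sprintf("  shape beta  = %.3f   (95%% CI %.3f-%.3f)\n",
              x$shape, x$shape_ci[1], x$shape_ci[2]))
  cat(sprintf("  log-likelihood %.2f; failure mode: %s\n",
              x$loglik, x$failure_class))
  invisible(x)
}

#' Classify the hazard-over-time failure mode from the shape CI
#'
#' Early failure when the shape's 95% CI lies entirely below 1 (hazard
#' decreasing over time), wear-out when entirely above 1, random
#' otherwise. Exactly one class is always assigned.
#'
#' @param fit a `weibull_fit`.
#' @return `"early"`, `"random"` or `"wear-out"`.
#' @export
classify_failure <- function(fit) {
  ci <- fit$shape_ci
  if (ci[2] < 1) "early" else if (ci[1] > 1) "wear-out" else "random"
}

#' Empirical and fitted cumulative onset curves
#'
#' @param ttos `tto_records` or positive numeric vector.
#' @param fit a `weibull_fit`.
#' @param days evaluation grid in days; defaults to the sorted distinct
#'   observed values.
#' @return data.table with `day`, `empirical` (step CDF k/n) and `fitted`
#'   (`1 - exp(-(t/alpha)^beta)`).
#' @export
cumulative_curve <- function(ttos, fit, days = NULL) {
  t <- tto_vector(ttos)
  if (!length(t)) stop("no time-to-onset values")
  if (is.null(days)) days <- sort(unique(t))
  data.table::data.table(
    day = days,
    empirical = stats::ecdf(t)(days),
    fitted = stats::pweibull(days, shape = fit$shape, scale = fit$scale))
}
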