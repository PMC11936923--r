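#!/usr/bin/env Rscript
# Optional integration run against a real FAERS download (not part of the
# test suite; the full quarterly files are several GB and not bundled).
#
# Expects a directory of extracted FAERS ASCII quarters (DEMO22Q1.txt ...)
# and a user-supplied PT->SOC mapping CSV, and reproduces the full
# faricimab analysis: cohort descriptives, PT/SOC signal tables, four-way
# intersection, time-to-onset Weibull fit and the three-drug comparison.
#
# Usage:
#   Rscript scripts/integration_faers.R --faers-dir DIR --map meddra.csv \
#       [--out results/faers_full]

suppressMessages(library(faerspv))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
faers_dir <- get_arg("--faers-dir")
map_path <- get_arg("--map")
out_dir <- get_arg("--out", "results/faers_full")
if (is.null(faers_dir)) stop("--faers-dir is required (extracted FAERS quarters)")

patterns <- c("VABYSMO", "FARICIMAB",
              "VASCULAR ENDOTHELIAL GROWTH FACTOR INHIBITORS FARICIMAB",
              "BLINDED FARICIMAB")

man <- run_pipeline(faers_dir, out_dir, drug = "faricimab",
                    patterns = patterns, map_path = map_path,
                    compare = c("RANIBIZUMAB", "AFLIBERCEPT"))

cat("cases (primary suspect):", man$counts$ps_cases, "\n")
cat("drug-event records:     ", man$counts$drug_records, "\n")
cat("four-way positive PTs:  ", man$counts$pt_four_way_positive, "\n")
fit_path <- file.path(out_dir, "weibull_fit.json")
if (file.exists(fit_path)) {
  fit <- jsonlite::read_json(fit_path)
  cat(sprintf("onset: n = %d, median %.0f d (IQR %.0f-%.0f), alpha = %.2f, beta = %.2f (%s)\n",
              fit$n, fit$median, fit$q1, fit$q3, fit$scale, fit$shape,
              fit$failure_class))
}
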