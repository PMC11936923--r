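#' Run the full signal-detection pipeline on a quarter directory
#'
#' Ties the stages together: read every quarter found in `input_dir`,
#' deduplicate, select the reports with the target drug as primary
#' suspect, build the cohort and its demographic summary, enumerate
#' drug-event records, compute PT- and SOC-level signal tables and their
#' four-way intersection, extract time-to-onset and fit the Weibull
#' model, optionally compare drugs, and write every artifact plus a run
#' manifest with the stage counts. Any stage error aborts with the stage
#' name after writing the manifest collected so far. The pipeline itself
#' is deterministic: all randomness lives in the generator.
#'
#' @param input_dir directory of FAERS-style quarterly files.
#' @param out_dir output directory (created if needed).
#' @param drug label for the target drug in outputs.
#' @param patterns drug-name patterns selecting the target drug.
#' @param map_path PT to SOC map CSV; defaults to `pt_soc_map.csv` inside
#'   `input_dir` when present, else SOC-level outputs are skipped.
#' @param compare optional character vector of other drug labels for the
#'   ROR comparison table.
#' @param min_n minimum target-drug record count for reported terms.
#' @param thresholds see [signal_thresholds()].
#' @param ic_mode IC lower-limit mode.
#' @return invisibly, the run manifest (list).
#' @export
run_pipeline <- function(input_dir, out_dir, drug, patterns,
                         map_path = NULL, compare = NULL, min_n = 1L,
                         thresholds = signal_thresholds(),
                         ic_mode = c("fixed_offset", "delta")) {
  ic_mode <- match.arg(ic_mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(input = input_dir, drug = drug, patterns = patterns,
                   ic_mode = ic_mode, thresholds = thresholds,
                   version = as.character(utils::packageVersion("faerspv")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   counts = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  raw <- stage("ingest", faers_read_dir(input_dir))
  manifest$counts$reports_in <- nrow(raw$tables$demo)

  demo <- stage("deduplicate", faers_dedup(raw$tables$demo))
  manifest$counts$after_dedup <- nrow(demo)
  raw$tables$demo <- demo

  ids <- stage("primary_suspect", {
    sel <- select_primary_suspect(raw$tables$drug, patterns)
    sel <- sel[sel %in% demo$primaryid]
    if (!length(sel)) {
      stop("no primary-suspect reports match pattern(s): ",
           paste(patterns, collapse = ", "))
    }
    sel
  })
  manifest$counts$ps_cases <- length(ids)

  cohort <- stage("cohort", build_cohort(raw, ids, patterns = patterns))
  manifest$counts$cohort_cases <- nrow(cohort$cases)
  demog <- stage("demographics", summarize_demographics(cohort))
  data.table::fwrite(demog, file.path(out_dir, "demographics.csv"))

  records <- stage("records", enumerate_records(
    raw, drug_groups = stats::setNames(list(patterns), drug), dedup = FALSE))
  manifest$counts$records_total <- nrow(records)
  manifest$counts$drug_records <- sum(records$drug == drug)

  pt_tab <- stage("signals_pt", signal_table(
    records, drug, level = "pt", min_n = min_n, thresholds = thresholds,
    ic_mode = ic_mode))
  data.table::fwrite(pt_tab, file.path(out_dir, "signals_pt.csv"))
  venn <- intersect_positive(pt_tab)
  jsonlite::write_json(
    list(sets = venn$sets, intersection = venn$intersection,
         region_counts = as.list(venn$region_counts)),
    file.path(out_dir, "intersection_pt.json"), auto_unbox = TRUE)
  manifest$counts$pt_four_way_positive <- length(venn$intersection)

  if (is.null(map_path)) {
    cand <- file.path(input_dir, "pt_soc_map.csv")
    if (file.exists(cand)) map_path <- cand
  }
  if (!is.null(map_path)) {
    map <- stage("meddra_map", read_meddra_map(map_path))
    soc_tab <- stage("signals_soc", signal_table(
      records, drug, level = "soc", map = map, min_n = min_n,
      thresholds = thresholds, ic_mode = ic_mode))
    data.table::fwrite(soc_tab, file.path(out_dir, "signals_soc.csv"))
  }

  tto <- stage("tto", extract_tto(cohort))
  manifest$counts$tto_n <- nrow(tto)
  data.table::fwrite(tto, file.path(out_dir, "tto_records.csv"))
  if (nrow(tto) >= 10L) {
    fit <- stage("weibull", fit_weibull(tto))
    smry <- summarize_tto(tto)
    jsonlite::write_json(
      list(n = fit$n, median = smry$median, q1 = smry$q1, q3 = smry$q3,
           scale = fit$scale, scale_ci = fit$scale_ci,
           shape = fit$shape, shape_ci = fit$shape_ci,
           loglik = fit$loglik, failure_class = fit$failure_class),
      file.path(out_dir, "weibull_fit.json"), auto_unbox = TRUE, digits = NA)
    curve <- cumulative_curve(tto, fit)
    data.table::fwrite(curve, file.path(out_dir, "cumulative_curve.csv"))
  }

  if (!is.null(compare)) {
    terms <- unique(records$pt[records$drug == drug])
    cmp <- stage("compare", compare_drugs(records, c(drug, compare), terms))
    data.table::fwrite(cmp, file.path(out_dir, "drug_comparison.csv"))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
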