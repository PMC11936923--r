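#' Read a PT to SOC mapping table
#'
#' MedDRA itself is licensed, so the hierarchy is supplied by the user as
#' a two-column CSV `pt,soc` (one primary SOC per PT). Labels are
#' case-normalized; duplicate PT rows are an error.
#'
#' @param path CSV file path.
#' @return data.table with columns `pt`, `soc`.
#' @export
read_meddra_map <- function(path) {
  map <- data.table::fread(path, colClasses = "character")
  if (!all(c("pt", "soc") %in% names(map))) {
    stop("mapping file must have columns 'pt' and 'soc'")
  }
  map <- map[, .(pt = norm_pt(pt), soc = norm_pt(soc))]
  if (anyDuplicated(map$pt)) stop("each PT must map to exactly one SOC")
  map[]
}

# map normalized PT labels to SOC, unmapped -> "unmapped" pseudo-SOC
map_soc <- function(pts, map) {
  soc <- map$soc[match(pts, map$pt)]
  n_un <- sum(is.na(soc))
  if (n_un) {
    message(n_un, " record(s) with PTs outside the map assigned to 'unmapped'")
    soc[is.na(soc)] <- "unmapped"
  }
  soc
}

#' Enumerate drug-event records from deduplicated reports
#'
#' The analysis unit of every contingency count is the (report, distinct
#' PT) record: one deduplicated report with k distinct reactions
#' contributes k records, all attributed to the report's primary-suspect
#' drug. A drug's record total therefore exceeds its case total.
#'
#' @param raw a `faers_quarter` (concatenated quarters).
#' @param drug_groups optional named list of pattern vectors; reports
#'   whose PS drug name matches any pattern of a group are labelled with
#'   the group's name (e.g. `list(faricimab = c("VABYSMO", "FARICIMAB"))`).
#'   Unmatched drugs keep their normalized PS drug name.
#' @param role role code defining the attributed drug (default `"PS"`).
#' @param dedup deduplicate DEMO first (default `TRUE`).
#' @return data.table of class `faers_records` with columns `primaryid`,
#'   `drug`, `pt`; attributes `n_no_ps` and `n_no_reaction` count the
#'   reports dropped for lacking a PS drug row or any reaction.
#' @export
enumerate_records <- function(raw, drug_groups = NULL, role = "PS",
                              dedup = TRUE) {
  stopifnot(inherits(raw, "faers_quarter"))
  demo <- if (dedup) faers_dedup(raw$tables$demo) else raw$tables$demo
  ids <- unique(demo$primaryid)
  drg <- raw$tables$drug[primaryid %in% ids & role_cod == toupper(role)]
  if (!nrow(drg)) stop("no DRUG rows with role ", role)
  drg <- drg[order(primaryid, drug_seq)]
  ps <- drg[, .(drug = norm_name(drugname[1L])), by = primaryid]
  if (!is.null(drug_groups)) {
    for (g in names(drug_groups)) {
      pats <- norm_name(drug_groups[[g]])
      ps[drug %in% pats, drug := g]
    }
  }
  n_no_ps <- length(ids) - nrow(ps)
  reac <- raw$tables$reac[primaryid %in% ps$primaryid]
  rec <- unique(data.table::data.table(primaryid = reac$primaryid,
                                       pt = norm_pt(reac$pt)))
  rec <- merge(rec, ps, by = "primaryid")
  n_no_reac <- nrow(ps) - data.table::uniqueN(rec$primaryid)
  out <- rec[, .(primaryid, drug, pt)]
  data.table::setattr(out, "n_no_ps", n_no_ps)
  data.table::setattr(out, "n_no_reaction", n_no_reac)
  data.table::setattr(out, "class", c("faers_records", class(out)))
  out[]
}

#' Two-by-two contingency table for one drug-event pair
#'
#' Cell layout: `a` = records with both the target drug and the target
#' event; `b` = the drug's records with other events; `c` = other drugs'
#' records with the event; `d` = the remainder. `N = a+b+c+d` is the
#' record total of the dataset and is identical for every table built
#' from it. Cells may be non-integer for reconstructed tables
#' (see [reconstruct_counts()]).
#'
#' @param a,b,c,d non-negative cell counts.
#' @param term,level optional labels carried into results.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, term = NA_character_,
                              level = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0)) stop("cells must be non-negative")
  structure(list(a = a, b = b, c = c, d = d, n = a, N = a + b + c + d,
                 term = term, level = level),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table%s: a=%g b=%g c=%g d=%g (N=%g)\n",
              if (is.na(x$term)) "" else paste0(" [", x$term, "]"),
              x$a, x$b, x$c, x$d, x$N))
  invisible(x)
}

#' Build the contingency table for a drug and a preferred term
#'
#' @param records `faers_records` from [enumerate_records()].
#' @param drug drug label as it appears in `records$drug` (normalized
#'   internally).
#' @param pt preferred-term label (case-insensitive).
#' @return A `contingency_table`; when the PT is absent from the whole
#'   dataset the table is returned with `a = c = 0` and attribute
#'   `absent = TRUE`.
#' @export
build_pt_table <- function(records, drug, pt) {
  build_term_table(records, drug, norm_pt(pt), records$pt, level = "pt")
}

#' Build the contingency table for a drug and a system organ class
#'
#' Counts records whose PT maps to the SOC. Several same-SOC PTs on one
#' report each keep their own record (no per-report collapse), keeping
#' the denominators consistent with the record-level counting unit.
#'
#' @param records `faers_records`.
#' @param drug drug label.
#' @param soc SOC label.
#' @param map PT to SOC map (see [read_meddra_map()]).
#' @return A `contingency_table` at SOC level.
#' @export
build_soc_table <- function(records, drug, soc, map) {
  if (is.null(map) || !nrow(map)) stop("empty PT->SOC map")
  build_term_table(records, drug, norm_pt(soc), map_soc(records$pt, map),
                   level = "soc")
}

# match a drug label against the record labels: group names are used
# verbatim, raw PS names after normalization
drug_mask <- function(records, drug) {
  m <- records$drug == drug
  if (!any(m)) m <- records$drug == norm_name(drug)
  m
}

build_term_table <- function(records, drug, term, term_vec, level) {
  isd <- drug_mask(records, drug)
  ist <- term_vec == term
  a <- sum(isd & ist)
  tab <- contingency_table(a, sum(isd & !ist), sum(!isd & ist),
                           sum(!isd & !ist), term = term, level = level)
  if (a == 0L && sum(ist) == 0L) attr(tab, "absent") <- TRUE
  tab
}
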