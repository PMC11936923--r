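#' Read one quarter of FAERS-style ASCII tables
#'
#' Parses the "$"-delimited quarterly text files (DEMO, DRUG, REAC and,
#' when present, THER, INDI, OUTC, RPSR) from a directory into typed
#' [data.table::data.table] tables. Field names are lowercased; rows whose
#' field count disagrees with the header are counted and dropped (FAERS
#' uses no quoting dialect, so such rows cannot be repaired); unparseable
#' dates become `NA` with the row retained.
#'
#' Typed columns added on top of the raw fields:
#' * DEMO: `fda_date` (Date), `event_dt_prec` + `event_date`
#'   (precision tag and day-precision Date), `rept_yr` (from FDA_DT),
#'   numeric `age`, normalized `age_cod`, `sex`, `occp_cod`.
#' * DRUG: integer `drug_seq`, normalized `role_cod`.
#' * THER: integer `dsg_drug_seq`, `start_prec` + `start_date`.
#'
#' @param path directory containing the quarterly files, e.g. `DEMO22Q1.txt`.
#' @param quarter quarter label such as `"2022Q1"`; recorded in a `quarter`
#'   column of every table. Guessed from the DEMO file name when `NULL`.
#' @return An object of class `faers_quarter`: a list with `tables` (named
#'   list of data.tables), `quarter`, and `log` (malformed-row and orphan
#'   counts per table).
#' @examples
#' cfg <- sim_config(seed = 1, n_cases = c(drug_a = 20, drug_b = 20))
#' out <- simulate_faers(cfg, tempfile("faers"))
#' q <- faers_read_quarter(out$dir, out$quarters[1])
#' nrow(q$tables$demo)
#' @export
faers_read_quarter <- function(path, quarter = NULL) {
  if (!dir.exists(path)) stop("directory not found: ", path)
  tables <- c("DEMO", "DRUG", "REAC", "THER", "INDI", "OUTC", "RPSR")
  required <- c("DEMO", "DRUG", "REAC")
  files <- list.files(path)
  found <- lapply(tables, function(tb) {
    hit <- files[grepl(paste0("^", tb, ".*\\.txt$"), files, ignore.case = TRUE)]
    if (length(hit)) {
      if (!is.null(quarter)) {
        qtag <- paste0(substr(quarter, 3, 4), "Q", substr(quarter, 6, 6))
        hit2 <- hit[grepl(qtag, hit, ignore.case = TRUE)]
        if (length(hit2)) hit <- hit2
      }
      hit[1]
    } else NA_character_
  })
  names(found) <- tables
  for (tb in required) {
    if (is.na(found[[tb]])) {
      stop("required FAERS table file missing from ", path, ": ", tb)
    }
  }
  if (is.null(quarter)) {
    m <- regmatches(found$DEMO, regexpr("[0-9]{2}Q[1-4]", found$DEMO))
    quarter <- if (length(m)) paste0("20", sub("Q", "Q", m)) else "unknown"
  }
  out <- list()
  log <- list(malformed = integer(0), orphans = integer(0))
  for (tb in tables) {
    if (is.na(found[[tb]])) next
    dt <- read_dollar_table(file.path(path, found[[tb]]))
    log$malformed[tolower(tb)] <- attr(dt, "n_malformed")
    dt[, quarter := quarter]
    out[[tolower(tb)]] <- dt
  }
  out$demo <- type_demo(out$demo)
  out$drug <- type_drug(out$drug)
  out$reac <- type_reac(out$reac)
  if (!is.null(out$ther)) out$ther <- type_ther(out$ther)
  # referential check: child primaryids should exist in DEMO (logged only)
  ids <- unique(out$demo$primaryid)
  for (tb in setdiff(names(out), "demo")) {
    if (is.data.frame(out[[tb]]) && "primaryid" %in% names(out[[tb]])) {
      log$orphans[tb] <- sum(!out[[tb]]$primaryid %in% ids)
    }
  }
  structure(list(tables = out, quarter = quarter, log = log),
            class = "faers_quarter")
}

# Parse one "$"-delimited file with a header line. A sentinel is appended
# before splitting so trailing empty fields survive strsplit().
read_dollar_table <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (!length(lines)) stop("empty file: ", file)
  parts <- strsplit(paste0(lines, "$\x01"), "$", fixed = TRUE)
  header <- tolower(trimws(parts[[1]][-length(parts[[1]])]))
  body <- parts[-1]
  nf <- lengths(body) - 1L
  good <- nf == length(header)
  rows <- body[good]
  dt <- if (length(rows)) {
    m <- matrix(unlist(lapply(rows, `[`, seq_along(header))),
                ncol = length(header), byrow = TRUE)
    data.table::as.data.table(m)
  } else {
    data.table::as.data.table(
      matrix(character(), nrow = 0, ncol = length(header)))
  }
  data.table::setalloccol(dt)
  data.table::setnames(dt, header)
  for (j in names(dt)) {
    blank <- which(!nzchar(dt[[j]]))
    if (length(blank)) data.table::set(dt, blank, j, NA_character_)
  }
  n_bad <- sum(!good)
  if (n_bad) {
    message(sprintf("%s: dropped %d row(s) with wrong field count",
                    basename(file), n_bad))
  }
  data.table::setattr(dt, "n_malformed", n_bad)
  dt
}

type_demo <- function(demo) {
  if (!"primaryid" %in% names(demo)) stop("DEMO lacks a primaryid column")
  fd <- parse_faers_date(demo[["fda_dt"]])
  demo[, fda_date := fd$date]
  demo[, rept_yr := as.integer(substr(fd$value, 1, 4))]
  ev <- parse_faers_date(demo[["event_dt"]])
  demo[, `:=`(event_dt = ev$value, event_dt_prec = ev$prec, event_date = ev$date)]
  if ("age" %in% names(demo)) {
    demo[, age := suppressWarnings(as.numeric(age))]
  }
  if ("age_cod" %in% names(demo)) demo[, age_cod := toupper(trimws(age_cod))]
  if ("sex" %in% names(demo)) demo[, sex := toupper(trimws(sex))]
  if ("occp_cod" %in% names(demo)) demo[, occp_cod := toupper(trimws(occp_cod))]
  demo
}

type_drug <- function(drug) {
  if ("drug_seq" %in% names(drug)) {
    drug[, drug_seq := suppressWarnings(as.integer(drug_seq))]
  }
  if ("role_cod" %in% names(drug)) {
    drug[, role_cod := toupper(trimws(role_cod))]
  }
  drug
}

type_reac <- function(reac) {
  if (!"pt" %in% names(reac)) stop("REAC lacks a pt column")
  reac[!is.na(pt) & nzchar(trimws(pt))]
}

type_ther <- function(ther) {
  if ("dsg_drug_seq" %in% names(ther)) {
    ther[, dsg_drug_seq := suppressWarnings(as.integer(dsg_drug_seq))]
  }
  st <- parse_faers_date(ther[["start_dt"]])
  ther[, `:=`(start_dt = st$value, start_prec = st$prec, start_date = st$date)]
  ther
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat("FAERS quarter", x$quarter, "\n")
  for (tb in names(x$tables)) {
    cat(sprintf("  %-5s %7d rows\n", tb, nrow(x$tables[[tb]])))
  }
  invisible(x)
}

#' Concatenate quarters into one multi-quarter table set
#'
#' Row-wise union of the per-quarter tables; every record keeps its
#' `quarter` label and no deduplication is performed (see [faers_dedup()]).
#'
#' @param quarters list of `faers_quarter` objects (length >= 1).
#' @return A `faers_quarter` whose tables are the concatenation.
#' @export
faers_concat <- function(quarters) {
  if (!length(quarters)) stop("need at least one quarter")
  if (length(quarters) == 1L) return(quarters[[1]])
  tabs <- unique(unlist(lapply(quarters, function(q) names(q$tables))))
  out <- list()
  for (tb in tabs) {
    pieces <- lapply(quarters, function(q) q$tables[[tb]])
    pieces <- pieces[!vapply(pieces, is.null, logical(1))]
    cols <- lapply(pieces, names)
    if (length(unique(vapply(cols, paste, "", collapse = "|"))) > 1L) {
      stop("inconsistent column sets for table ", tb, ": ",
           paste(unique(unlist(cols)), collapse = ", "))
    }
    out[[tb]] <- data.table::rbindlist(pieces)
  }
  logs <- lapply(quarters, `[[`, "log")
  structure(list(tables = out,
                 quarter = paste(vapply(quarters, `[[`, "", "quarter"),
                                 collapse = "+"),
                 log = list(per_quarter = logs)),
            class = "faers_quarter")
}

#' Read and concatenate every quarter found in a directory
#'
#' Quarter labels are detected from `DEMO*.txt` file names
#' (`DEMO22Q1.txt` -> `2022Q1`).
#'
#' @param path directory with one or more quarters of files.
#' @return A concatenated `faers_quarter`.
#' @export
faers_read_dir <- function(path) {
  demo_files <- list.files(path, pattern = "^DEMO.*\\.txt$", ignore.case = TRUE)
  if (!length(demo_files)) stop("no DEMO*.txt files found in ", path)
  tags <- regmatches(demo_files, regexpr("[0-9]{2}Q[1-4]", demo_files))
  quarters <- sort(unique(paste0("20", tags)))
  faers_concat(lapply(quarters, function(q) faers_read_quarter(path, q)))
}

#' Deduplicate FAERS reports by the FDA-recommended rule
#'
#' Keeps, for each CASEID, the report version with the latest FDA receipt
#' date; when several versions share that date, the one with the highest
#' PRIMARYID wins (numeric comparison when all ids in the case group are
#' digit strings, lexicographic otherwise). Output is sorted by caseid, so
#' the operation is deterministic and idempotent.
#'
#' @param demo DEMO table (data.table with `primaryid`, `caseid`, `fda_dt`).
#' @return The deduplicated DEMO table: exactly one row per caseid.
#' @examples
#' demo <- data.table::data.table(
#'   primaryid = c("10", "11"), caseid = c("C1", "C1"),
#'   fda_dt = c("20230101", "20230301"))
#' faers_dedup(demo)$primaryid  # "11"
#' @export
faers_dedup <- function(demo) {
  need <- c("primaryid", "caseid", "fda_dt")
  if (!all(need %in% names(demo))) {
    stop("DEMO must contain columns: ", paste(need, collapse = ", "))
  }
  d <- data.table::as.data.table(demo)
  fd <- as.integer(d$fda_dt)
  if (anyNA(fd)) stop("fda_dt must be a full YYYYMMDD date on every row")
  keep <- d[, {
    i <- which(fd[.I] == max(fd[.I]))
    if (length(i) > 1L) {
      p <- primaryid[i]
      i <- if (all(grepl("^[0-9]+$", p))) {
        i[which.max(as.numeric(p))]
      } else {
        i[order(p, decreasing = TRUE)[1L]]
      }
    }
    .I[i]
  }, by = caseid]$V1
  out <- d[sort(keep)]
  data.table::setorder(out, caseid)
  out[]
}

#' Select reports where a drug matches name patterns under a role code
#'
#' Returns the primaryids having at least one DRUG row whose `drugname` or
#' `prod_ai` matches any of the patterns (case-insensitive, trimmed,
#' internal whitespace collapsed; exact match after normalization by
#' default, substring optionally) and whose role code equals `role`
#' (`"PS"` = primary suspect).
#'
#' @param drug DRUG table.
#' @param patterns character vector of name patterns (non-empty).
#' @param role role code, one of `"PS"`, `"SS"`, `"C"`, `"I"`.
#' @param match `"exact"` (default) or `"substring"`.
#' @return Sorted character vector of primaryids, with a `matches`
#'   attribute holding the matched (primaryid, drug_seq) pairs.
#' @export
select_primary_suspect <- function(drug, patterns, role = "PS",
                                   match = c("exact", "substring")) {
  match <- match.arg(match)
  if (!length(patterns) || all(!nzchar(trimws(patterns)))) {
    stop("patterns must be a non-empty character vector")
  }
  role <- toupper(role)
  if (!role %in% c("PS", "SS", "C", "I")) stop("unknown role code: ", role)
  if (!nrow(drug)) {
    return(structure(character(0),
                     matches = data.table::data.table(primaryid = character(0),
                                                      drug_seq = integer(0))))
  }
  pn <- norm_name(patterns)
  dn <- norm_name(drug$drugname %||% rep(NA_character_, nrow(drug)))
  ai <- norm_name(drug$prod_ai %||% rep(NA_character_, nrow(drug)))
  hit <- if (match == "exact") {
    (!is.na(dn) & dn %in% pn) | (!is.na(ai) & ai %in% pn)
  } else {
    Reduce(`|`, lapply(pn, function(p) {
      (!is.na(dn) & grepl(p, dn, fixed = TRUE)) |
        (!is.na(ai) & grepl(p, ai, fixed = TRUE))
    }))
  }
  hit <- hit & !is.na(drug$role_cod) & drug$role_cod == role
  ids <- sort(unique(drug$primaryid[hit]))
  matches <- data.table::data.table(
    primaryid = drug$primaryid[hit],
    drug_seq = if ("drug_seq" %in% names(drug)) drug$drug_seq[hit]
               else rep(NA_integer_, sum(hit)))
  structure(ids, matches = matches)
}
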