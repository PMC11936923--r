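# Fixtures are built in code at test time; nothing is stored on disk.

# Write a quarter directory from in-memory tables (uppercase FAERS headers).
quarter_from_tables <- function(dir, demo, drug = NULL, reac = NULL,
                                ther = NULL, tag = "23Q1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tb, name) {
    if (!is.null(tb)) {
      data.table::fwrite(tb, file.path(dir, paste0(name, tag, ".txt")),
                         sep = "$", quote = FALSE, na = "")
    }
  }
  w(demo, "DEMO"); w(drug, "DRUG"); w(reac, "REAC"); w(ther, "THER")
  dir
}

# Minimal handcrafted quarter: two well-formed reports.
mini_quarter <- function(dir = tempfile("q")) {
  demo <- data.table::data.table(
    PRIMARYID = c("1001", "1002"), CASEID = c("C1001", "C1002"),
    FDA_DT = c("20230105", "20230210"), EVENT_DT = c("20221220", "202211"),
    AGE = c("64", "720"), AGE_COD = c("YR", "MON"), SEX = c("F", "M"),
    OCCP_COD = c("MD", "CN"), OCCR_COUNTRY = c("US", "JP"))
  drug <- data.table::data.table(
    PRIMARYID = c("1001", "1001", "1002"), CASEID = c("C1001", "C1001", "C1002"),
    DRUG_SEQ = c("1", "2", "1"), ROLE_COD = c("PS", "C", "PS"),
    DRUGNAME = c("Vabysmo", "OTHERDRUG", "FARICIMAB "),
    PROD_AI = c("FARICIMAB", NA, "FARICIMAB"))
  reac <- data.table::data.table(
    PRIMARYID = c("1001", "1001", "1002"), CASEID = c("C1001", "C1001", "C1002"),
    PT = c("Uveitis", "UVEITIS", "Eye pain"))
  ther <- data.table::data.table(
    PRIMARYID = c("1001", "1002"), CASEID = c("C1001", "C1002"),
    DSG_DRUG_SEQ = c("1", "1"), START_DT = c("20221201", "202210"),
    END_DT = c(NA, NA))
  quarter_from_tables(dir, demo, drug, reac, ther)
}

# Record list with known contingency cells for ("target", "headache"):
# a = 10, b = 20, c = 30, d = 240.
toy_records <- function() {
  rec <- data.table::rbindlist(list(
    data.table::data.table(drug = "TARGET", pt = "headache", k = 10),
    data.table::data.table(drug = "TARGET", pt = "nausea", k = 20),
    data.table::data.table(drug = "OTHER", pt = "headache", k = 30),
    data.table::data.table(drug = "OTHER", pt = "rash", k = 240)))
  rec <- rec[rep(seq_len(.N), k)][, k := NULL]
  rec[, primaryid := as.character(.I)]
  data.table::setcolorder(rec, c("primaryid", "drug", "pt"))
  rec
}

# Brute-force 2x2 cells by an explicit double classification loop.
brute_cells <- function(records, drug, pt) {
  a <- b <- cc <- d <- 0L
  for (i in seq_len(nrow(records))) {
    isd <- records$drug[i] == drug
    isp <- records$pt[i] == pt
    if (isd && isp) a <- a + 1L
    else if (isd) b <- b + 1L
    else if (isp) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# Random DEMO fixture with duplicate case versions, for dedup properties.
random_demo <- function(n_cases, seed) {
  set.seed(seed)
  n_ver <- sample(1:3, n_cases, TRUE)
  idx <- rep(seq_len(n_cases), n_ver)
  ver <- sequence(n_ver)
  data.table::data.table(
    primaryid = as.character(idx * 10L + ver),
    caseid = sprintf("C%04d", idx),
    fda_dt = format(as.Date("2023-01-01") +
                      sample(0:365, length(idx), TRUE), "%Y%m%d"))
}
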