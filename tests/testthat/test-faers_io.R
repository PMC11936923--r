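test_that("quarter files parse into typed lowercase tables", {
  q <- faers_read_quarter(mini_quarter(), "2023Q1")
  demo <- q$tables$demo
  expect_equal(nrow(demo), 2L)
  expect_true(all(c("primaryid", "caseid", "fda_dt", "sex") %in% names(demo)))
  # hand-parse of the first fixture line against the declared column order
  r <- demo[primaryid == "1001"]
  expect_equal(r$sex, "F")
  expect_equal(r$fda_date, as.Date("2023-01-05"))
  expect_equal(r$event_dt_prec, "day")
  expect_equal(r$rept_yr, 2023L)
  # partial event date keeps its precision tag but no Date
  r2 <- demo[primaryid == "1002"]
  expect_equal(r2$event_dt_prec, "month")
  expect_true(is.na(r2$event_date))
  expect_equal(q$tables$ther[primaryid == "1002"]$start_prec, "month")
})

test_that("missing required table is fatal and names the file", {
  dir <- mini_quarter()
  file.remove(list.files(dir, pattern = "^REAC", full.names = TRUE))
  expect_error(faers_read_quarter(dir, "2023Q1"), "REAC")
})

test_that("rows with the wrong field count are counted and dropped", {
  dir <- mini_quarter()
  f <- list.files(dir, pattern = "^DEMO", full.names = TRUE)
  cat("9999$C9999$20230101\n", file = f, append = TRUE)   # too few fields
  expect_message(q <- faers_read_quarter(dir, "2023Q1"), "wrong field count")
  expect_equal(nrow(q$tables$demo), 2L)
  expect_equal(unname(q$log$malformed["demo"]), 1L)
})

test_that("unparseable dates become absent fields, row retained", {
  dir <- mini_quarter()
  demo <- data.table::data.table(
    PRIMARYID = "1", CASEID = "C1", FDA_DT = "20230101",
    EVENT_DT = "20230230", AGE = "60", AGE_COD = "YR", SEX = "F",
    OCCP_COD = "MD", OCCR_COUNTRY = "US")
  drug <- data.table::data.table(PRIMARYID = "1", CASEID = "C1",
                                 DRUG_SEQ = "1", ROLE_COD = "PS",
                                 DRUGNAME = "X", PROD_AI = "X")
  reac <- data.table::data.table(PRIMARYID = "1", CASEID = "C1", PT = "rash")
  d2 <- quarter_from_tables(tempfile("q"), demo, drug, reac)
  q <- faers_read_quarter(d2, "2023Q1")
  expect_equal(nrow(q$tables$demo), 1L)
  expect_true(is.na(q$tables$demo$event_dt_prec))
})

test_that("concatenation is a row union with no implicit dedup", {
  q1 <- faers_read_quarter(mini_quarter(), "2023Q1")
  q2 <- faers_read_quarter(mini_quarter(), "2023Q2")
  both <- faers_concat(list(q1, q2))
  expect_equal(nrow(both$tables$demo), 4L)          # 2 + 2
  expect_equal(sort(unique(both$tables$demo$quarter)), c("2023Q1", "2023Q2"))
  # same primaryids appear twice: dedup is a separate, explicit step
  expect_equal(sum(both$tables$demo$primaryid == "1001"), 2L)
  # single quarter is the identity
  expect_identical(faers_concat(list(q1))$tables$demo, q1$tables$demo)
})

test_that("concatenation rejects inconsistent column sets", {
  q1 <- faers_read_quarter(mini_quarter(), "2023Q1")
  q2 <- faers_read_quarter(mini_quarter(), "2023Q2")
  q2$tables$demo[, extra_col := "x"]
  expect_error(faers_concat(list(q1, q2)), "inconsistent column sets")
})

test_that("deduplication keeps latest receipt date, then highest primaryid", {
  demo <- data.table::data.table(
    primaryid = c("10", "11"), caseid = c("C1", "C1"),
    fda_dt = c("20230101", "20230301"))
  expect_equal(faers_dedup(demo)$primaryid, "11")
  # receipt-date tie: numeric comparison of primaryid, not lexicographic
  demo2 <- data.table::data.table(
    primaryid = c("100", "200", "99"), caseid = "C1",
    fda_dt = "20230101")
  expect_equal(faers_dedup(demo2)$primaryid, "200")
  # non-numeric ids fall back to lexicographic
  demo3 <- data.table::data.table(
    primaryid = c("A10", "A9"), caseid = "C1", fda_dt = "20230101")
  expect_equal(faers_dedup(demo3)$primaryid, "A9")
  # already-unique input is unchanged
  demo4 <- data.table::data.table(
    primaryid = c("1", "2"), caseid = c("C1", "C2"),
    fda_dt = c("20230101", "20230102"))
  expect_equal(faers_dedup(demo4)$primaryid, c("1", "2"))
})

test_that("deduplication is idempotent and yields one row per case", {
  for (seed in c(7, 19, 31)) {
    demo <- random_demo(200, seed)
    once <- faers_dedup(demo)
    expect_equal(nrow(once), data.table::uniqueN(demo$caseid))
    expect_identical(faers_dedup(once), once)
    expect_false(anyDuplicated(once$caseid) > 0)
  }
})

test_that("primary-suspect selection matches patterns under the role code", {
  q <- faers_read_quarter(mini_quarter(), "2023Q1")
  drug <- q$tables$drug
  # brand name, free-text case and trailing blanks are all normalized away
  expect_equal(as.character(select_primary_suspect(drug, "VABYSMO")), "1001")
  expect_setequal(as.character(select_primary_suspect(drug, "FARICIMAB")),
                  c("1001", "1002"))  # via prod_ai for 1001, drugname for 1002
  # a concomitant row does not qualify under role PS
  expect_length(select_primary_suspect(drug, "OTHERDRUG"), 0L)
  expect_equal(as.character(select_primary_suspect(drug, "OTHERDRUG",
                                                   role = "C")), "1001")
  expect_equal(as.character(select_primary_suspect(drug, "VABY",
                                                   match = "substring")), "1001")
  expect_error(select_primary_suspect(drug, character(0)), "non-empty")
  empty <- drug[0]
  expect_length(select_primary_suspect(empty, "VABYSMO"), 0L)
})

test_that("synthetic quarters round-trip through the reader", {
  cfg <- sim_config(seed = 5, n_cases = c(drug_a = 60, drug_b = 60),
                    duplicate_rate = 0)
  out <- simulate_faers(cfg, tempfile("rt"))
  raw <- suppressMessages(faers_read_dir(out$dir))
  demo <- raw$tables$demo
  expect_equal(nrow(demo), nrow(out$tables$demo))
  expect_setequal(demo$caseid, out$tables$demo$CASEID)
  # field values preserved for a specific report
  i <- out$tables$demo[5]
  j <- demo[primaryid == i$PRIMARYID]
  expect_equal(j$fda_dt, i$FDA_DT)
  expect_equal(j$sex, i$SEX)
  reac <- raw$tables$reac
  expect_equal(nrow(reac), nrow(out$tables$reac))
})
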