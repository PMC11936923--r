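test_that("balanced cells give the null value of every statistic", {
  t0 <- contingency_table(10, 10, 10, 10)
  r <- compute_ror(t0)
  expect_equal(r$ror, 1)
  # CI symmetric about 1 on the log scale
  expect_equal(log(r$ci95[1]), -log(r$ci95[2]))
  p <- compute_prr(t0)
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)
  expect_equal(compute_ic(t0)$ic, 0)
  expect_equal(compute_ebgm(t0)$ebgm, 1)
})

test_that("statistics match hand-computed values on the worked 2x2 table", {
  t1 <- contingency_table(10, 20, 30, 240)
  r <- compute_ror(t1)
  expect_equal(r$ror, 4)
  # frozen: 4 * exp(-/+ 1.96 * sqrt(1/10 + 1/20 + 1/30 + 1/240))
  expect_equal(r$ci95, c(1.7118753, 9.3464749), tolerance = 1e-6)
  p <- compute_prr(t1)
  expect_equal(p$prr, 3)
  expect_equal(p$chi2, 11.5384615, tolerance = 1e-6)
  # independent oracle for the chi-squared statistic
  cs <- suppressWarnings(
    stats::chisq.test(matrix(c(10, 20, 30, 240), 2, byrow = TRUE),
                      correct = FALSE))
  expect_equal(p$chi2, unname(cs$statistic))
  expect_equal(compute_ic(t1)$ic, log2(2.5))
  expect_equal(compute_ebgm(t1)$ebgm, 2.5)
})

test_that("IC lower limit follows the selected variance mode", {
  t1 <- contingency_table(10, 20, 30, 240)
  fixed <- compute_ic(t1, mode = "fixed_offset")
  expect_equal(fixed$ic - fixed$ic025, 1.67)
  del <- compute_ic(t1, mode = "delta")
  v <- (1 / log(2))^2 * (1 / 10 - 1 / 30 + 1 / 40 - 1 / 300)
  expect_equal(del$ic025, del$ic - 2 * sqrt(v))
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  t1 <- contingency_table(5, 10, 0, 100)
  r <- compute_ror(t1)
  expect_true(r$corrected)
  expect_equal(r$ror, (5.5 * 100.5) / (10.5 * 0.5))
  # a = 0 is not computable but still returns a result with flags off
  t0 <- contingency_table(0, 10, 5, 100)
  ev <- evaluate_signal(t0)
  expect_true(is.na(ev$ror))
  expect_false(any(ev$flag_ror, ev$flag_prr, ev$flag_bcpnn, ev$flag_mgps,
                   ev$combined))
})

test_that("positivity flags follow the published thresholds", {
  # clears every threshold
  strong <- evaluate_signal(contingency_table(20, 80, 100, 9800))
  expect_true(strong$combined)
  # n below 3 blocks ROR and PRR positivity regardless of magnitude
  tiny <- evaluate_signal(contingency_table(2, 8, 10, 9980))
  expect_false(tiny$flag_ror)
  expect_false(tiny$flag_prr)
  # ROR-only pattern: lower CI > 1 but PRR < 2
  weak <- evaluate_signal(contingency_table(200, 800, 1500, 8500))
  expect_true(weak$flag_ror)
  expect_false(weak$flag_prr)
  expect_false(weak$combined)
  # loosening a threshold never removes a positive term
  th_loose <- signal_thresholds(prr_min = 1.5, ebgm05_min = 1)
  weak2 <- evaluate_signal(contingency_table(200, 800, 1500, 8500), th_loose)
  expect_true(all(weak2[, .(flag_ror, flag_prr, flag_bcpnn, flag_mgps)] >=
                  weak[, .(flag_ror, flag_prr, flag_bcpnn, flag_mgps)]))
})

test_that("IC equals log2 of the relative reporting ratio on random tables", {
  set.seed(21)
  n <- 1e4
  a <- sample(1:500, n, TRUE); b <- sample(1:2000, n, TRUE)
  cc <- sample(1:2000, n, TRUE); d <- sample(1:20000, n, TRUE)
  s <- faerspv:::disprop_stats(a, b, cc, d)
  expect_identical(s$ic, log2(s$ebgm))
  # ror and prr sit on the same side of 1: ror/prr = (1 + a/b)/(1 + c/d)
  gt <- s$ror > 1 & abs(s$ror - 1) > 1e-12
  lt <- s$ror < 1 & abs(s$ror - 1) > 1e-12
  expect_true(all(s$ror[gt] > s$prr[gt]))
  expect_true(all(s$ror[lt] < s$prr[lt]))
})

test_that("exported scalar and vectorized paths agree", {
  set.seed(22)
  for (i in 1:50) {
    cells <- sample(1:300, 4, TRUE)
    t1 <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    s <- faerspv:::disprop_stats(cells[1], cells[2], cells[3], cells[4])
    expect_equal(compute_ror(t1)$ror, s$ror)
    expect_equal(compute_ebgm(t1)$ebgm05, s$ebgm05)
  }
})

test_that("cells reconstructed from ROR and EBGM round-trip to 1e-6", {
  truth <- contingency_table(10, 20, 30, 240)
  tab <- reconstruct_counts(10, 30, ror = compute_ror(truth)$ror,
                            ebgm = compute_ebgm(truth)$ebgm)
  expect_equal(tab$c, 30, tolerance = 1e-6)
  expect_equal(tab$d, 240, tolerance = 1e-6)
  # random positive-cell tables round-trip as well
  set.seed(23)
  for (i in 1:20) {
    cells <- sample(5:500, 4, TRUE)
    t1 <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    rt <- reconstruct_counts(cells[1], cells[1] + cells[2],
                             compute_ror(t1)$ror, compute_ebgm(t1)$ebgm)
    expect_equal(rt$c / cells[3], 1, tolerance = 1e-6)
    expect_equal(rt$d / cells[4], 1, tolerance = 1e-6)
  }
  # impossible statistic pairs are rejected
  expect_error(reconstruct_counts(10, 30, ror = 2, ebgm = 50),
               "inconsistent")
})

test_that("null statistics yield the balanced reconstruction family", {
  tab <- reconstruct_counts(10, 30, ror = 1, ebgm = 1)
  expect_equal(tab$c / tab$d, 10 / 20, tolerance = 1e-9)
  expect_equal(attr(tab, "consistency")$ror, 1, tolerance = 1e-9)
})

test_that("drug comparison marks unreported terms and matches the 2x2 path", {
  rec <- data.table::rbindlist(list(
    data.table::data.table(drug = "A", pt = rep(c("x", "y"), c(10, 20))),
    data.table::data.table(drug = "B", pt = rep(c("x", "z"), c(5, 40))),
    data.table::data.table(drug = "C", pt = rep("z", 60))))
  rec[, primaryid := as.character(.I)]
  cmp <- compare_drugs(rec, c("A", "B", "C"), c("x", "y"))
  # term y occurs only for drug A: others are NR
  expect_true(cmp[drug == "B" & term == "y"]$nr)
  expect_true(is.na(cmp[drug == "C" & term == "y"]$ror))
  expect_false(cmp[drug == "A" & term == "x"]$nr)
  # ROR agrees with the direct contingency computation
  direct <- compute_ror(build_pt_table(rec, "A", "x"))
  expect_equal(cmp[drug == "A" & term == "x"]$ror, direct$ror)
  expect_error(compare_drugs(rec, "A", "x"), "two drugs")
})

test_that("identical record profiles give identical RORs", {
  rec <- data.table::rbindlist(list(
    data.table::data.table(drug = "A", pt = rep(c("x", "y"), c(10, 30))),
    data.table::data.table(drug = "B", pt = rep(c("x", "y"), c(10, 30))),
    data.table::data.table(drug = "BG", pt = rep(c("x", "y"), c(50, 200)))))
  rec[, primaryid := as.character(.I)]
  cmp <- compare_drugs(rec, c("A", "B"), "x")
  expect_equal(cmp[drug == "A"]$ror, cmp[drug == "B"]$ror)
})

test_that("positive sets intersect into the four-way region", {
  res <- data.table::data.table(
    term = c("p1", "p2", "p3", "p4"),
    flag_ror = c(TRUE, TRUE, TRUE, FALSE),
    flag_prr = c(TRUE, TRUE, FALSE, FALSE),
    flag_bcpnn = c(TRUE, TRUE, FALSE, FALSE),
    flag_mgps = c(TRUE, FALSE, FALSE, FALSE))
  v <- intersect_positive(res)
  expect_equal(v$intersection, "p1")
  expect_equal(unname(v$region_counts[c("RPBM", "RPB", "R", "none")]),
               rep(1L, 4), ignore_attr = TRUE)
  # all-positive and disjoint corner cases
  allpos <- data.table::data.table(term = c("a", "b"), flag_ror = TRUE,
                                   flag_prr = TRUE, flag_bcpnn = TRUE,
                                   flag_mgps = TRUE)
  expect_setequal(intersect_positive(allpos)$intersection, c("a", "b"))
  disj <- data.table::data.table(term = c("a", "b"),
                                 flag_ror = c(TRUE, FALSE),
                                 flag_prr = c(FALSE, TRUE),
                                 flag_bcpnn = FALSE, flag_mgps = FALSE)
  expect_length(intersect_positive(disj)$intersection, 0L)
})

test_that("four-way positivity is at least as strict as any single algorithm", {
  # all relative risks at 1: the combined positive share cannot exceed the
  # ROR-only share
  cfg <- sim_config(seed = 33, n_cases = c(drug_a = 1200, drug_b = 1200),
                    pt_map = mini_meddra(40),
                    signals = data.table::data.table(
                      drug = character(0), pt = character(0),
                      rr = numeric(0)),
                    duplicate_rate = 0)
  out <- simulate_faers(cfg, tempfile("null"))
  raw <- suppressMessages(faers_read_dir(out$dir))
  rec <- enumerate_records(raw)
  st <- signal_table(rec, "DRUG_A")
  expect_lte(mean(st$combined), mean(st$flag_ror))
})
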