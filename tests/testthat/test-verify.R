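test_that("the packaged summary table reads with eight consistent rows and round-trips", {
  tab <- read_summary_table()
  expect_equal(nrow(tab), 8)
  expect_setequal(unique(tab$valve), c("non-calcified", "calcified"))
  expect_setequal(unique(tab$dobutamine), c("d0", "d5", "d10", "d20"))
  tmp <- tempfile(fileext = ".tsv")
  utils::write.table(tab, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  tab2 <- read_summary_table(tmp)
  expect_equal(tab2, tab)
})

test_that("symmetric percent error is symmetric, zero at equality, and matches arithmetic", {
  expect_equal(symmetric_percent_error(149, 143), 100 * 6 / 146, tolerance = 1e-12)
  expect_equal(round(symmetric_percent_error(149, 143), 2), 4.11)
  expect_equal(symmetric_percent_error(149, 143),
               symmetric_percent_error(143, 149))
  expect_equal(symmetric_percent_error(7, 7), 0)
  expect_equal(symmetric_percent_error(110, 100, denominator = "exp"), 10)
  expect_equal(symmetric_percent_error(110, 100, denominator = "sim"),
               1000 / 110, tolerance = 1e-12)
})

test_that("error summaries need all four conditions and vanish for identical rows", {
  tab <- read_summary_table()
  expect_error(error_summary(tab[tab$dobutamine != "d10", ], "non-calcified"),
               "4 dobutamine")
  same <- tab[tab$valve == "non-calcified", ]
  same$q_sim <- same$q_exp
  same$valve <- "x"
  expect_equal(error_summary(same, "x", "q_mean")$mean_percent, 0)
})

test_that("within-uncertainty flags follow the 10% flow-probe band", {
  expect_true(within_uncertainty(149, 143))    # 6 <= 14.3
  expect_false(within_uncertainty(154, 137))   # 17 > 13.7
  expect_true(within_uncertainty(100, 100))
  expect_false(within_uncertainty(111, 100))
  expect_true(within_uncertainty(111, 100, frac = 0.12))
})

test_that("the verification table carries flags and errors for all eight rows", {
  tab <- build_table(read_summary_table())
  expect_equal(nrow(tab), 8)
  expect_true(all(c("q_within", "q_error_pct", "ava_within", "ava_error_pct")
                  %in% names(tab)))
  # the one condition whose simulated flow exceeded the uncertainty band
  d0c <- tab[tab$valve == "calcified" & tab$dobutamine == "d0", ]
  expect_false(d0c$q_within)
  expect_true(all(tab$q_within[tab$valve == "non-calcified"]))
})

test_that("pipeline comparison of identical inputs gives zero error everywhere", {
  spec <- mock_loop_spec("d0", noise_sd = 0, n_cycles = 3)
  pp <- generate_pressure_traces(spec)
  dp <- pressure_difference(pp$p_lv, pp$p_ao)
  q <- generate_flow_trace(dp, 1.2, 0.8)
  side <- list(d0 = list(q = q, p_lv = pp$p_lv, p_ao = pp$p_ao, cycle_time = 0.8))
  tab <- pipeline_verify(side, side)
  expect_equal(tab$q_error_pct, 0, tolerance = 1e-10)
  expect_true(all(tab$q_within))
  expect_true(is.na(tab$ava_error_pct))  # AVA absent on both sides: flagged NA
})

test_that("an injected five percent flow bias is recovered by the comparison", {
  spec <- mock_loop_spec("d0", noise_sd = 0, n_cycles = 3)
  pp <- generate_pressure_traces(spec)
  dp <- pressure_difference(pp$p_lv, pp$p_ao)
  q <- generate_flow_trace(dp, 1.2, 0.8)
  mk <- function(scale) {
    out <- list()
    for (cd in c("d0", "d5", "d10", "d20"))
      out[[cd]] <- list(q = time_trace(q$time, q$value * scale, q$units),
                        p_lv = pp$p_lv, p_ao = pp$p_ao, cycle_time = 0.8)
    out
  }
  tab <- pipeline_verify(mk(1.05), mk(1))
  expect_equal(nrow(tab), 4)
  expect_equal(attr(tab, "summaries")$q_mean_error_pct, 5, tolerance = 1)
  expect_true(all(tab$q_within))  # 5% bias stays inside the 10% band
})
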