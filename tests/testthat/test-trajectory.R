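test_that("accumulation patterns are classified by the relative-step rules", {
  expect_equal(classify_pattern(c(10, 20, 10)), "accumulate_then_mobilize")
  expect_equal(classify_pattern(c(34.4, 24, 15.2)), "decline")
  expect_equal(classify_pattern(c(5.0, 5.1, 5.0)), "stable")
  expect_equal(classify_pattern(c(5.1, 5.9, 7.2)), "continuous_increase")
  expect_equal(classify_pattern(c(5, 5, 7)), "continuous_increase")
  expect_equal(classify_pattern(c(0, 0, 0)), "stable")
  expect_error(classify_pattern(c(-1, 2, 3)), "non-negative")
  expect_error(classify_pattern(c(1, 2)), "exactly 3")
})

test_that("pattern classification is scale-invariant", {
  set.seed(21)
  for (i in 1:50) {
    triple <- runif(3, 0, 60)
    k <- runif(1, 0.01, 100)
    expect_equal(classify_pattern(triple * k), classify_pattern(triple))
  }
})

test_that("oleaginy calls use a strict threshold and are monotone", {
  expect_true(call_oleaginous(67.1))
  expect_true(call_oleaginous(29.4))
  expect_false(call_oleaginous(20))   # boundary: strict inequality
  expect_true(call_oleaginous(20.01))
  expect_error(call_oleaginous(50, threshold = 0), "between 0 and 100")
  expect_error(call_oleaginous(50, threshold = 100), "between 0 and 100")
  expect_error(call_oleaginous(120), "\\[0, 100\\]")
  vals <- seq(0, 100, by = 0.5)
  expect_true(all(diff(call_oleaginous(vals)) >= 0))  # monotone in content
})

test_that("the major compound is the argmax with 1% relative ties", {
  expect_setequal(major_compound(c("C18:1(n-9)" = 40, "C16:0" = 39.8)),
                  c("C18:1(n-9)", "C16:0"))
  expect_equal(major_compound(c("C18:2(n-6)" = 30, "C18:1(n-9)" = 20)),
               "C18:2(n-6)")
  zero <- major_compound(c(a = 0, b = 0))
  expect_true(is.na(zero))
  expect_true(attr(zero, "undefined"))
  expect_error(major_compound(numeric()), "empty")
  set.seed(8)
  for (i in 1:50) {
    comp <- setNames(runif(6, 0, 50), paste0("fa", 1:6))
    expect_setequal(major_compound(comp), oracle_major(comp))
  }
})

test_that("trajectories assemble quantifications and classifications", {
  lib <- default_rt_library()
  quant_at <- function(pct, comp = c("C18:1(n-9)" = 0.8, "C16:0" = 0.2)) {
    g <- growth_sim_config(mu_true = 0.3, od_max_true = 20, noise_sd = 0)
    sc <- scenario_config(g, pct_cdw = rep(max(pct, 0.1), 3),
                          composition = comp, chrom_noise_sd = 0)
    b <- simulate_scenario(sc)
    analyze_chromatogram(b$samples[[1]]$chromatogram, lib)
  }
  tr <- build_trajectory(list(quant_at(20), quant_at(52.2), quant_at(35)),
                         strain_label = "YALI", medium_label = "oleic")
  expect_equal(tr$pattern, "accumulate_then_mobilize")
  expect_equal(tr$max_pct_cdw, 52.2, tolerance = 0.01 * 52.2)
  expect_true(tr$oleaginous)
  expect_equal(tr$major_compound_at_max, "C18:1(n-9)")
  expect_output(print(tr), "accumulate_then_mobilize")

  # missing time point -> partial trajectory, classifications unset
  tr2 <- build_trajectory(list(quant_at(10), NULL, quant_at(30)))
  expect_true(is.na(tr2$pattern))
  expect_true(is.na(tr2$points$pct_cdw[2]))
  expect_equal(tr2$max_pct_cdw, 30, tolerance = 0.5)
  expect_error(build_trajectory(list(quant_at(10), quant_at(10))),
               "three time points")

  rep <- trajectory_report(list(tr))
  expect_equal(rep$pattern, "accumulate_then_mobilize")
  comp <- composition_report(list(tr))
  expect_true(all(c("strain", "timepoint", "fa_name",
                    "mg_per_g_cdw") %in% names(comp)))
})

test_that("three empty-lipid time points give a stable, non-oleaginous record", {
  lib <- default_rt_library()
  ch <- simulate_chromatogram(quiet_chrom(numeric()), aliquot_cdw_mg = 5)
  q <- analyze_chromatogram(ch, lib)
  tr <- build_trajectory(list(q, q, q))
  expect_equal(tr$pattern, "stable")
  expect_false(tr$oleaginous)
  expect_equal(tr$max_pct_cdw, 0)
})
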