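test_that("compliant-analyte counting applies the window inclusively", {
  all_good <- data.frame(analyte = sprintf("a%02d", 1:43),
                         spike_level = 50, measured = 50)
  expect_equal(compliant_count(all_good), 43L)

  edge <- data.frame(analyte = c("w", "x", "y", "z"), spike_level = 100,
                     measured = c(79.9, 80.0, 110.0, 110.1))
  expect_equal(compliant_count(edge), 2L)

  none <- data.frame(analyte = c("a", "b"), spike_level = 50,
                     measured = c(10, 120))
  expect_equal(compliant_count(none), 0L)

  # replicates are averaged before the window is applied
  reps <- data.frame(analyte = "a", spike_level = 100,
                     measured = c(70, 95))  # mean recovery 82.5
  expect_equal(compliant_count(reps), 1L)

  expect_error(compliant_count(edge[0, ]), "empty")
})

test_that("widening the compliance window never lowers the count", {
  set.seed(8)
  for (i in 1:10) {
    rec <- data.frame(analyte = sprintf("a%02d", 1:30), spike_level = 50,
                      measured = 50 * runif(30, 0.5, 1.4))
    counts <- sapply(seq(0, 30, by = 5), function(w) {
      compliant_count(rec, compliance_rule(80 - w, 110 + w))
    })
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("decision limit and detection capability follow the 1.64-SD rule", {
  expect_equal(cc_limits(50, 0), c(cc_alpha = 10, cc_beta = 10))

  # inverting the decision limit for the replicate SD, then re-applying
  sd_inv <- (10.9 - 10) / 1.64
  cc <- cc_limits(50, sd_inv)
  expect_equal(unname(cc["cc_alpha"]), 10.9)
  expect_equal(unname(cc["cc_beta"]), 11.8)

  # a large-SD row: printed 52.5 vs recomputed 52.6 (intermediate rounding)
  cc2 <- cc_limits(50, (31.3 - 10) / 1.64)
  expect_equal(unname(cc2["cc_beta"]), 52.6, tolerance = 1e-10)
  expect_lt(abs(unname(cc2["cc_beta"]) - 52.5), 0.1 + 1e-9)

  # algebraic spacing identity, any SD and VL
  set.seed(3)
  for (i in 1:50) {
    vl <- runif(1, 10, 200)
    s <- runif(1, 0, 15)
    cc <- cc_limits(vl, s)
    expect_equal(unname(cc["cc_beta"]), unname(2 * cc["cc_alpha"] - 0.2 * vl),
                 tolerance = 1e-12)
    expect_gte(cc["cc_alpha"], 0.2 * vl)
    expect_gte(cc["cc_beta"], cc["cc_alpha"])
  }
  expect_error(cc_limits(50, -1), "non-negative")
  expect_error(cc_limits(0, 1), "positive")
})

test_that("matrix effect classifies slope ratios with inclusive boundaries", {
  expect_equal(matrix_effect(0.8, 0.8), list(me = 0, class = "mild_or_medium"))
  expect_equal(matrix_effect(0.4, 0.8),
               list(me = -50, class = "mild_or_medium"))
  expect_equal(matrix_effect(1.2, 0.8)$class, "mild_or_medium")
  expect_equal(matrix_effect(0.3, 0.8)$class, "strong")
  expect_equal(matrix_effect(1.3, 0.8)$class, "strong")
  expect_error(matrix_effect(0.5, 0), "zero")

  # scale invariance: rescaling both curves leaves ME unchanged
  lv <- c(1, 5, 10, 50)
  m <- fit_calibration(lv, 0.7 * lv + rnorm(4, 0, 1e-3), "matrix")
  s <- fit_calibration(lv, 1.1 * lv + rnorm(4, 0, 1e-3), "solvent")
  me1 <- matrix_effect(m, s)$me
  m2 <- fit_calibration(lv, 100 * m$responses, "matrix")
  s2 <- fit_calibration(lv, 100 * s$responses, "solvent")
  expect_equal(matrix_effect(m2, s2)$me, me1, tolerance = 1e-9)
})

test_that("LOQ scales linearly from the reference signal-to-noise", {
  expect_equal(loq_estimate(1, 10), 1)
  expect_equal(loq_estimate(1, 20), 0.5)
  expect_equal(loq_estimate(0.2, 4), 0.5)
  expect_error(loq_estimate(1, 0), "positive")
  expect_error(loq_estimate(-1, 10), "positive")
})

test_that("precision pooling matches a brute-force per-day oracle", {
  toy <- data.frame(analyte = "a", matrix = "bacon", spike_level = 10,
                    day = c(1, 1, 2, 2), replicate = c(1, 2, 1, 2),
                    measured = c(9.5, 10.5, 9.0, 11.0))
  vs <- validation_summary(toy, vl = 50)
  lv <- vs$levels
  # oracle: per-day RSDs combined by root mean square
  rsd1 <- 100 * sd(c(9.5, 10.5)) / mean(c(9.5, 10.5))
  rsd2 <- 100 * sd(c(9.0, 11.0)) / mean(c(9.0, 11.0))
  expect_equal(lv$intra_day_rsd, sqrt(mean(c(rsd1^2, rsd2^2))),
               tolerance = 1e-12)
  # inter-day: all replicates pooled
  expect_equal(lv$inter_day_rsd, 100 * sd(toy$measured) / mean(toy$measured),
               tolerance = 1e-12)
  expect_equal(lv$mean_recovery, 100)

  const <- toy
  const$measured <- 10
  vs0 <- validation_summary(const, vl = 50)
  expect_equal(vs0$levels$intra_day_rsd, 0)
  expect_equal(vs0$levels$inter_day_rsd, 0)
})

test_that("validation summary assembles per-analyte metrics and flags gaps", {
  set.seed(14)
  truth <- synthetic_truth(n_analytes = 4, seed = 14)
  qa <- simulate_quant_assets(truth, vl = 50)
  vs <- validation_summary(qa$replicates_02vl, qa$curves, vl = 50)
  expect_equal(nrow(vs$analytes), 4L)
  expect_true(all(c("cc_alpha", "cc_beta", "me", "me_class", "linearity_r2")
                  %in% names(vs$analytes)))
  # CC limits derive from the 0.2 VL spike SD pooled across days
  a1 <- qa$replicates_02vl[qa$replicates_02vl$analyte == "analyte_01", ]
  expect_equal(vs$analytes$cc_alpha[1],
               unname(cc_limits(50, sd(a1$measured))["cc_alpha"]),
               tolerance = 1e-12)
  expect_true(all(vs$analytes$cc_beta >= vs$analytes$cc_alpha))
  expect_true(all(vs$analytes$linearity_r2 > 0.99))
  expect_true(all(vs$analytes$me_class %in% c("mild_or_medium", "strong")))

  # without a 0.2 VL level the limits are reported missing, not defaulted
  shifted <- qa$replicates_02vl
  shifted$spike_level <- 50
  vs2 <- validation_summary(shifted, qa$curves, vl = 50)
  expect_true(all(is.na(vs2$analytes$cc_alpha)))
  expect_true(all(is.na(vs2$analytes$cc_beta)))
})
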