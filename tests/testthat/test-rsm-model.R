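test_that("refitting a reconstructed response returns the source coefficients", {
  des <- ref_design()
  surf <- ref_surface()
  for (seed in c(1, 7, 101)) {
    y <- construct_consistent_response(surf, ref_aggregates$residual_ss,
                                       ref_aggregates$pure_error_ss, des,
                                       seed = seed)
    fit <- rsm_fit(des, y)
    expect_equal(unname(coef(fit)), unname(coef(surf)), tolerance = 1e-12)
    expect_equal(sum(residuals(fit)^2), ref_aggregates$residual_ss,
                 tolerance = 1e-9)
  }
})

test_that("a noise-free response is interpolated exactly", {
  des <- ref_design()
  surf <- ref_surface()
  y <- predict(surf, des)
  fit <- rsm_fit(des, y)
  expect_equal(sum(residuals(fit)^2), 0, tolerance = 1e-20)
  # every center run's fitted value is the intercept
  expect_equal(unname(fitted(fit)[des$point_type == "center"]),
               rep(41.80, 5))
})

test_that("surface prediction matches direct polynomial evaluation", {
  surf <- ref_surface()
  expect_equal(predict(surf, c(0, 0, 0)), 41.80)
  expect_equal(predict(surf, c(0, -1, -1)), 34.75)
  expect_equal(predict(surf, c(1, 1, 0)), 23.0)
  set.seed(9)
  for (i in 1:20) {
    x <- runif(3, -1.2, 1.2)
    expect_equal(predict(surf, x), eval_surface_oracle(coef(surf), x),
                 tolerance = 1e-12)
  }
})

test_that("Type-III decomposition reproduces the reference ANOVA from aggregates", {
  a <- rsm_anova(ref_surface(), design = ref_design(),
                 residual_ss = 11.3, pure_error_ss = 2.8)
  ss <- setNames(a$ss, a$term)
  expect_equal(unname(ss[c("A", "B", "C")]), c(2, 18, 60.5), tolerance = 1e-12)
  expect_equal(unname(ss[c("A:B", "A:C", "B:C")]), c(1, 4, 0), tolerance = 1e-12)
  expect_equal(unname(ss[c("A^2", "B^2", "C^2")]), c(262.78, 297.09, 35.41),
               tolerance = 2e-5)
  expect_equal(unname(ss["Model"]), 737.76, tolerance = 1e-5)
  expect_equal(unname(ss["Cor total"]), 749.06, tolerance = 1e-4)

  f <- setNames(a$f, a$term)
  expect_equal(unname(f["Model"]), 50.78, tolerance = 1e-4)
  expect_equal(unname(f["C"]), 37.48, tolerance = 1e-4)
  expect_equal(unname(f["B"]), 11.15, tolerance = 1e-3)
  expect_equal(unname(f["Lack of fit"]), 4.05, tolerance = 1e-3)
  p <- setNames(a$p, a$term)
  # printed p-values carry four decimals: compare at that precision
  expect_equal(round(unname(p["Lack of fit"]), 4), 0.1051)
  expect_equal(round(unname(p["C"]), 4), 0.0005)
  expect_lt(unname(p["Model"]), 1e-4)

  # the zero interaction: SS 0, F 0, p 1
  bc <- a[a$term == "B:C", ]
  expect_equal(bc$ss, 0, tolerance = 1e-12)
  expect_equal(bc$f, 0, tolerance = 1e-12)
  expect_equal(bc$p, 1, tolerance = 1e-12)

  # significance flags follow the p-value thresholds, including the
  # quadratic term at p = 0.0023 which is below 0.01
  flags <- setNames(a$signif, a$term)
  expect_equal(unname(flags[c("Model", "A", "B", "C", "B:C", "C^2")]),
               c("**", "", "*", "**", "", "**"))
})

test_that("raw-response and aggregate ANOVA routes agree exactly", {
  des <- ref_design()
  surf <- ref_surface()
  y <- construct_consistent_response(surf, 11.3, 2.8, des, seed = 3)
  a_raw <- rsm_anova(rsm_fit(des, y))
  a_agg <- rsm_anova(surf, design = des, residual_ss = 11.3,
                     pure_error_ss = 2.8)
  expect_equal(a_raw$ss, a_agg$ss, tolerance = 1e-9)
  expect_equal(a_raw$df, a_agg$df)
  expect_equal(a_raw$f, a_agg$f, tolerance = 1e-9)
})

test_that("ANOVA bookkeeping identities hold on noisy synthetic fits", {
  des <- ref_design()
  set.seed(21)
  for (i in 1:5) {
    y <- predict(ref_surface(), des) + rnorm(17, sd = 1.5)
    y <- pmax(y, 0)
    a <- rsm_anova(rsm_fit(des, y))
    ss <- setNames(a$ss, a$term)
    expect_equal(unname(ss["Model"] + ss["Residual"]), unname(ss["Cor total"]),
                 tolerance = 1e-9)
    expect_equal(unname(ss["Lack of fit"] + ss["Pure error"]),
                 unname(ss["Residual"]), tolerance = 1e-9)
    expect_true(all(a$ss >= 0))
    df <- setNames(a$df, a$term)
    expect_equal(unname(df["Lack of fit"] + df["Pure error"]),
                 unname(df["Residual"]))
  }
})

test_that("quadratic-term precision constant matches the closed-form inverse", {
  X <- rsm_model_matrix(ref_design())
  d <- diag(solve(crossprod(X)))
  expect_equal(unname(d[8:10]), rep(0.2375, 3), tolerance = 1e-12)
  expect_equal(unname(d[2:4]), rep(1 / 8, 3), tolerance = 1e-12)
  expect_equal(unname(d[5:7]), rep(1 / 4, 3), tolerance = 1e-12)
  # independent check: the symmetric intercept/quadratic block of X'X
  blk <- matrix(c(17, 8, 8, 8,
                  8, 8, 4, 4,
                  8, 4, 8, 4,
                  8, 4, 4, 8), 4, 4)
  expect_equal(unname(diag(solve(blk))[2:4]), rep(0.2375, 3),
               tolerance = 1e-12)
})

test_that("adequacy statistics reproduce the reference diagnostics", {
  adq <- adequacy_stats(ref_surface(), design = ref_design(),
                        residual_ss = 11.3, total_ss = 749.06)
  expect_equal(adq$r2, 0.9849, tolerance = 1e-4)
  expect_equal(adq$adj_r2, 0.9655, tolerance = 1e-4)
  expect_equal(adq$adeq_precision, 19.293, tolerance = 5e-4)
  expect_true(is.na(adq$pred_r2))

  # perfect fit degenerates cleanly
  des <- ref_design()
  fit <- rsm_fit(des, predict(ref_surface(), des))
  adq2 <- adequacy_stats(fit)
  expect_equal(adq2$r2, 1)
  expect_equal(adq2$adj_r2, 1)
  expect_equal(adq2$press, 0, tolerance = 1e-18)
  expect_equal(adq2$pred_r2, 1)
})

test_that("model-space-orthogonal noise can only lower R-squared", {
  des <- ref_design()
  surf <- ref_surface()
  base <- construct_consistent_response(surf, 5, 2, des, seed = 2)
  r2_of <- function(y) adequacy_stats(rsm_fit(des, y))$r2
  r2_base <- r2_of(base)
  for (seed in 1:10) {
    extra <- construct_consistent_response(surf, 5 + seed, 2, des,
                                           seed = seed) -
      predict(surf, des)
    noisier <- predict(surf, des) + extra
    expect_lt(r2_of(noisier), r2_base + 1e-12)
  }
})

test_that("degenerate fitting inputs raise informative errors", {
  des <- ref_design()
  expect_error(rsm_fit(des, rep(1, 5)), "length")
  expect_error(rsm_fit(des, c(rep(1, 16), NA)), "finite")
  expect_error(rsm_fit(des, c(rep(1, 16), -2)), "non-negative")
  # collapsing a factor to zero makes the matrix rank-deficient
  degen <- des
  degen$C <- 0
  expect_error(rsm_fit(degen, rep(1, 17)), "singular|rank")
  expect_error(
    rsm_anova(ref_surface(), design = des, residual_ss = 1,
              pure_error_ss = 2),
    "pure_error_ss exceeds"
  )
})
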