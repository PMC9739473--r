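test_that("stationary point of the reference surface is an interior maximum", {
  surf <- ref_surface()
  st <- stationary_point(surf)
  # independent 3x3 elimination oracle for the gradient system
  H <- matrix(c(-15.8, -0.5, 1, -0.5, -16.8, 0, 1, 0, -5.8), 3, 3)
  x_oracle <- solve(H, -c(-0.50, -1.50, -2.75))
  expect_equal(unname(st$point), x_oracle, tolerance = 1e-10)
  expect_equal(unname(st$point), c(-0.0595, -0.0875, -0.4844),
               tolerance = 1e-3)
  expect_true(all(st$eigenvalues < 0))
  expect_equal(st$nature, "maximum")
  expect_equal(st$value, 42.5466, tolerance = 1e-4)
  # gradient vanishes at the stationary point (finite differences)
  eps <- 1e-6
  for (i in 1:3) {
    e <- replace(numeric(3), i, eps)
    grad_i <- (predict(surf, st$point + e) - predict(surf, st$point - e)) /
      (2 * eps)
    expect_lt(abs(grad_i), 1e-6)
  }
})

test_that("canonical bowls and saddles are classified correctly", {
  bowl <- quad_surface(0, c(0, 0, 0), c(0, 0, 0), c(-1, -1, -1))
  st <- stationary_point(bowl)
  expect_equal(unname(st$point), c(0, 0, 0))
  expect_equal(st$nature, "maximum")
  expect_equal(st$value, 0)

  saddle <- quad_surface(0, c(0, 0, 0), c(0, 0, 0), c(1, -1, -1))
  expect_equal(stationary_point(saddle)$nature, "saddle")

  minimum <- quad_surface(0, c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))
  expect_equal(stationary_point(minimum)$nature, "minimum")

  flat <- quad_surface(0, c(1, 0, 0), c(0, 0, 0), c(-1, -1, 0))
  err <- tryCatch(stationary_point(flat), error = function(e) e)
  expect_s3_class(err, "degenerate_surface_error")
  # the null direction is the flat C axis
  expect_equal(abs(err$null_direction), c(0, 0, 1), tolerance = 1e-10)

  expect_error(stationary_point(quad_surface(1, c(1, 1, 1), c(0, 0, 0),
                                             c(0, 0, 0))),
               "identically zero")
})

test_that("cube optimization equals the stationary point when interior", {
  opt <- optimize_surface(ref_surface())
  st <- stationary_point(ref_surface())
  expect_equal(unname(opt$coded), unname(st$point), tolerance = 1e-12)
  expect_false(opt$on_boundary)
  expect_equal(opt$predicted, predict(ref_surface(), opt$coded))
  expect_equal(opt$predicted_count, 42)  # truncation of 42.55
  expect_equal(optimize_surface(ref_surface(), rounding = "nearest")$predicted_count, 43)
  expect_equal(optimize_surface(ref_surface(), rounding = "none")$predicted_count,
               opt$predicted)
  expect_true(opt$units_flagged)
})

test_that("boundary optima are found exactly", {
  ramp <- quad_surface(0, c(1, 0, 0), c(0, 0, 0), c(0, 0, -1))
  opt <- optimize_surface(ramp)
  expect_equal(unname(opt$coded[1]), 1)
  expect_true(opt$on_boundary)
  expect_equal(opt$predicted, 1)

  clipped <- quad_surface(0, c(4, 0, 0), c(0, 0, 0), c(-1, -1, -1))
  # stationary point at A = 2, outside the cube: max on the A = +1 face
  opt2 <- optimize_surface(clipped)
  expect_equal(unname(opt2$coded), c(1, 0, 0))
  expect_true(opt2$on_boundary)
  expect_equal(opt2$predicted, 3)
})

test_that("analytic optimum agrees with a dense grid oracle", {
  set.seed(5)
  surfaces <- c(list(ref_surface()), lapply(1:4, function(i) {
    quad_surface(runif(1, 20, 50), rnorm(3, 0, 2), rnorm(3, 0, 1),
                 rnorm(3, -4, 3))
  }))
  for (surf in surfaces) {
    opt <- optimize_surface(surf)
    oracle <- grid_max_oracle(surf, step = 0.02)
    expect_gte(opt$predicted, oracle$value - 1e-9)
    expect_lt(opt$predicted - oracle$value, 2e-3)
    # local-optimality audit: no strictly better neighbour on a fine grid
    for (i in 1:3) {
      for (d in c(-0.01, 0.01)) {
        nb <- pmin(pmax(opt$coded + replace(numeric(3), i, d), -1), 1)
        expect_lte(predict(surf, nb), opt$predicted + 1e-12)
      }
    }
  }
})

test_that("optimum is reported in actual units when factor levels are known", {
  specs <- list(bbd_factor("C18", 100, 300), bbd_factor("PSA", 100, 300),
                bbd_factor("Z-Sep+", 20, 80))
  opt <- optimize_surface(ref_surface(), factors = specs)
  expect_false(opt$units_flagged)
  expect_equal(unname(opt$actual),
               unname(coded_to_actual(opt$coded, specs)))
})

test_that("confirmation runs are summarized against the prediction", {
  cc <- confirmation_check(42.55, c(42, 43, 43, 43, 43))
  expect_equal(cc$mean, 42.8)
  expect_equal(cc$rsd_pct, 100 * sqrt(0.2) / 42.8, tolerance = 1e-12)
  expect_equal(cc$rsd_pct, 1.04, tolerance = 1e-2)
  expect_equal(cc$abs_deviation, 0.25, tolerance = 1e-12)

  same <- confirmation_check(10, rep(7, 4))
  expect_equal(same$rsd_pct, 0)
  expect_equal(same$abs_deviation, 3)

  expect_error(confirmation_check(10, 5), "at least 2")
  expect_error(confirmation_check(10, c(-1, 1)), "zero")
})
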