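# shared fixtures: the bundled reference equation and its ANOVA aggregates
ref_surface <- function() {
  quad_surface(41.80,
               linear = c(-0.50, -1.50, -2.75),
               interaction = c(-0.50, 1.00, 0.00),
               quadratic = c(-7.90, -8.40, -2.90))
}

ref_design <- function() bbd_design(c("A", "B", "C"), n_center = 5L)

ref_aggregates <- list(residual_ss = 11.3, residual_df = 7,
                       pure_error_ss = 2.8, pure_error_df = 4,
                       total_ss = 749.06, total_df = 16, vl = 50)

# brute-force surface evaluation independent of predict.quad_surface
eval_surface_oracle <- function(cf, x) {
  cf <- unname(cf)
  cf[1] + cf[2] * x[1] + cf[3] * x[2] + cf[4] * x[3] +
    cf[5] * x[1] * x[2] + cf[6] * x[1] * x[3] + cf[7] * x[2] * x[3] +
    cf[8] * x[1]^2 + cf[9] * x[2]^2 + cf[10] * x[3]^2
}

# dense grid maximization oracle, vectorized over the third axis
grid_max_oracle <- function(surface, step = 0.01) {
  cf <- unname(coef(surface))
  g <- seq(-1, 1, by = step)
  best <- -Inf
  best_pt <- NULL
  for (a in g) {
    for (b in g) {
      v <- cf[1] + cf[2] * a + cf[3] * b + cf[4] * g +
        cf[5] * a * b + cf[6] * a * g + cf[7] * b * g +
        cf[8] * a^2 + cf[9] * b^2 + cf[10] * g^2
      i <- which.max(v)
      if (v[i] > best) {
        best <- v[i]
        best_pt <- c(a, b, g[i])
      }
    }
  }
  list(value = best, point = best_pt)
}
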