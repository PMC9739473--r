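#' Stationary point of a quadratic response surface
#'
#' Solves the 3x3 linear system `gradient = 0` for the fitted second-order
#' polynomial and classifies the stationary point by the eigenvalues of the
#' Hessian (diagonal `2 b_jj`, off-diagonal the interaction coefficients).
#' Eigenvalues within `1e-8 * max(|eigenvalue|)` of zero are treated as
#' degenerate.
#'
#' @param object A `quad_surface` or `rsm_fit`.
#' @return An object of class `"stationary_point"`: list with `point`
#'   (coded 3-vector), `eigenvalues`, `nature` (`"maximum"`, `"minimum"` or
#'   `"saddle"`), and `value` (predicted response at the point).
#' @examples
#' bowl <- quad_surface(0, c(0, 0, 0), c(0, 0, 0), c(-1, -1, -1))
#' stationary_point(bowl)   # origin, maximum
#' @export
stationary_point <- function(object) {
  p <- surface_parts(object)
  if (all(p$quad == 0) && all(p$int == 0)) {
    stop("the quadratic part is identically zero: no stationary point",
         call. = FALSE)
  }
  H <- surface_hessian(object)
  ev <- eigen(H, symmetric = TRUE)
  tol <- 1e-8 * max(abs(ev$values))
  if (any(abs(ev$values) <= tol)) {
    null_dir <- ev$vectors[, which.min(abs(ev$values))]
    cond <- structure(
      class = c("degenerate_surface_error", "error", "condition"),
      list(message = "degenerate surface: singular Hessian",
           call = sys.call(-1), null_direction = null_dir)
    )
    stop(cond)
  }
  x <- drop(solve(H, -p$lin))
  names(x) <- object$factor_names
  nature <- if (all(ev$values < 0)) "maximum"
            else if (all(ev$values > 0)) "minimum"
            else "saddle"
  structure(
    list(point = x, eigenvalues = ev$values, nature = nature,
         value = predict(object, x)),
    class = "stationary_point"
  )
}

#' @export
print.stationary_point <- function(x, ...) {
  cat(sprintf("Stationary point (%s) at coded (%s); predicted %.4g\n",
              x$nature, paste(sprintf("%.4f", x$point), collapse = ", "),
              x$value))
  cat("  Hessian eigenvalues:", sprintf("%.4g", x$eigenvalues), "\n")
  invisible(x)
}

surface_gradient <- function(object, x) {
  p <- surface_parts(object)
  drop(p$lin + surface_hessian(object) %*% x)
}

# exact maximization of a 3D quadratic over a coded box by recursive
# restriction: the maximum is either an interior stationary point or lies
# on a face; fixing one coordinate at a bound induces a lower-dimensional
# quadratic which is maximized the same way.
maximize_quad_box <- function(b0, g, H, lower, upper) {
  d <- length(g)
  candidates <- list()
  if (d == 0L) {
    return(list(x = numeric(0), value = b0))
  }
  # interior stationary point (harmless to include whatever its nature:
  # when it is not the max a boundary candidate dominates it)
  detH <- if (d == 1L) H[1, 1] else det(H)
  if (abs(detH) > 1e-12 * max(1, max(abs(H)))^d) {
    xs <- drop(solve(H, -g))
    if (all(xs >= lower - 1e-12) && all(xs <= upper + 1e-12)) {
      xs <- pmin(pmax(xs, lower), upper)
      val <- b0 + sum(g * xs) + 0.5 * drop(t(xs) %*% H %*% xs)
      candidates[[length(candidates) + 1L]] <- list(x = xs, value = val)
    }
  }
  for (i in seq_len(d)) {
    for (bound in c(lower[i], upper[i])) {
      # restrict coordinate i to `bound`
      keep <- setdiff(seq_len(d), i)
      b0r <- b0 + g[i] * bound + 0.5 * H[i, i] * bound^2
      gr <- g[keep] + H[keep, i] * bound
      Hr <- H[keep, keep, drop = FALSE]
      sub <- maximize_quad_box(b0r, gr, Hr, lower[keep], upper[keep])
      x <- numeric(d)
      x[i] <- bound
      x[keep] <- sub$x
      candidates[[length(candidates) + 1L]] <- list(x = x, value = sub$value)
    }
  }
  vals <- vapply(candidates, `[[`, 0, "value")
  best <- max(vals)
  # tie-break: lexicographically smallest coordinates among near-equal values
  tied <- which(vals >= best - 1e-10 * max(1, abs(best)))
  pts <- do.call(rbind, lapply(candidates[tied], `[[`, "x"))
  ord <- do.call(order, as.data.frame(pts))
  list(x = pts[ord[1L], ], value = vals[tied[ord[1L]]])
}

#' Maximize a fitted surface over the coded experimental region
#'
#' Finds the global maximum of the second-order polynomial over the coded
#' cube (default [-1, 1] per factor) exactly, by recursive restriction: the
#' interior stationary point is a candidate when it falls inside the box,
#' and each face, edge and vertex contributes the maximum of the induced
#' lower-dimensional quadratic. No iterative numerical optimization is
#' involved. When factor specifications carry actual units the optimum is
#' also reported in those units, and the predicted analyte count is derived
#' from the continuous response by the chosen rounding policy.
#'
#' @param object A `quad_surface` or `rsm_fit`.
#' @param lower,upper Box bounds in coded units (scalar or length 3).
#' @param factors Optional list of [bbd_factor()] specifications for
#'   reporting the optimum in actual units (taken from the fit's design
#'   when available).
#' @param rounding How to turn the continuous predicted response into a
#'   count: `"truncate"` (default, toward zero), `"nearest"`, or `"none"`.
#' @return An object of class `"rsm_optimum"`: list with `coded` (3-vector),
#'   `actual` (or `NULL` with `units_flagged = TRUE` when no specs are
#'   available), `predicted` (continuous), `predicted_count`,
#'   `on_boundary`, and the `stationary` point object when one exists.
#' @examples
#' surf <- quad_surface(41.80, c(-0.50, -1.50, -2.75),
#'                      c(-0.50, 1.00, 0.00), c(-7.90, -8.40, -2.90))
#' optimize_surface(surf)
#' @export
optimize_surface <- function(object, lower = -1, upper = 1, factors = NULL,
                             rounding = c("truncate", "nearest", "none")) {
  rounding <- match.arg(rounding)
  lower <- rep_len(lower, 3L)
  upper <- rep_len(upper, 3L)
  stopifnot(all(lower < upper))
  p <- surface_parts(object)
  H <- surface_hessian(object)
  res <- maximize_quad_box(p$b0, p$lin, H, lower, upper)
  x <- res$x
  names(x) <- object$factor_names
  on_boundary <- any(abs(x - lower) < 1e-9 | abs(x - upper) < 1e-9)
  st <- tryCatch(stationary_point(object), error = function(e) NULL)
  if (is.null(factors) && inherits(object, "rsm_fit")) {
    factors <- design_factor_specs(object$design)
  }
  actual <- if (!is.null(factors)) coded_to_actual(x, factors) else NULL
  pred <- predict(object, x)
  count <- switch(rounding,
                  truncate = trunc(pred),
                  nearest = round(pred),
                  none = pred)
  structure(
    list(coded = x, actual = actual, units_flagged = is.null(actual),
         predicted = pred, predicted_count = count,
         on_boundary = on_boundary, rounding = rounding, stationary = st),
    class = "rsm_optimum"
  )
}

#' @export
print.rsm_optimum <- function(x, ...) {
  cat(sprintf("Optimum over the coded region%s:\n",
              if (x$on_boundary) " (on boundary)" else ""))
  cat("  coded   :", sprintf("%.4f", x$coded), "\n")
  if (!is.null(x$actual)) {
    cat("  actual  :", sprintf("%.1f", x$actual), "\n")
  } else {
    cat("  actual  : unavailable (no factor levels supplied)\n")
  }
  cat(sprintf("  predicted response %.4f; count %s (rounding: %s)\n",
              x$predicted, format(x$predicted_count), x$rounding))
  invisible(x)
}

#' Compare confirmation runs against the model prediction
#'
#' Summarizes the replicate runs performed at the optimized conditions:
#' their mean, the relative standard deviation (sample SD over mean, in
#' percent), and the absolute deviation of the mean from the model's
#' predicted response.
#'
#' @param predicted Predicted response at the confirmed conditions.
#' @param observations Numeric vector of at least two replicate outcomes.
#' @return List with `mean`, `rsd_pct`, `abs_deviation`, `n`.
#' @examples
#' confirmation_check(42.5, c(42, 43, 43, 43, 43))
#' @export
confirmation_check <- function(predicted, observations) {
  obs <- as.numeric(observations)
  if (length(obs) < 2L) {
    stop("at least 2 confirmation observations are required", call. = FALSE)
  }
  if (!all(is.finite(obs)) || !is.finite(predicted)) {
    stop("observations and prediction must be finite", call. = FALSE)
  }
  m <- mean(obs)
  if (m == 0) stop("mean of observations is zero: RSD undefined", call. = FALSE)
  list(mean = m,
       rsd_pct = 100 * stats::sd(obs) / m,
       abs_deviation = abs(m - predicted),
       n = length(obs))
}
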