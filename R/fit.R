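#' Construct a second-order response surface from known coefficients
#'
#' Builds a quadratic surface object from its 10 coefficients in coded
#' units, for example a regression equation reported in a publication. The
#' surface supports [predict()], [stationary_point()], [optimize_surface()]
#' and — given a design and residual information — [rsm_anova()] and
#' [adequacy_stats()], without access to the raw response data.
#'
#' @param intercept Intercept b0 (response at the coded center).
#' @param linear Length-3 numeric: coefficients of A, B, C.
#' @param interaction Length-3 numeric: coefficients of AB, AC, BC.
#' @param quadratic Length-3 numeric: coefficients of A^2, B^2, C^2.
#' @param factor_names Optional factor labels (default `c("A","B","C")`).
#' @return An object of class `"quad_surface"` with a named
#'   `$coefficients` vector of length 10.
#' @examples
#' # a reported sorbent-optimization equation, coded units
#' surf <- quad_surface(41.80, linear = c(-0.50, -1.50, -2.75),
#'                      interaction = c(-0.50, 1.00, 0.00),
#'                      quadratic = c(-7.90, -8.40, -2.90))
#' predict(surf, c(0, 0, 0))
#' @export
quad_surface <- function(intercept, linear, interaction, quadratic,
                         factor_names = c("A", "B", "C")) {
  stopifnot(length(intercept) == 1L, length(linear) == 3L,
            length(interaction) == 3L, length(quadratic) == 3L,
            length(factor_names) == 3L)
  cf <- c(intercept, linear, interaction, quadratic)
  if (!all(is.finite(cf))) stop("coefficients must be finite", call. = FALSE)
  names(cf) <- c("(Intercept)", factor_names,
                 paste0(factor_names[1], ":", factor_names[2]),
                 paste0(factor_names[1], ":", factor_names[3]),
                 paste0(factor_names[2], ":", factor_names[3]),
                 paste0(factor_names, "^2"))
  structure(list(coefficients = cf, factor_names = factor_names),
            class = "quad_surface")
}

#' Fit a second-order response surface to design data
#'
#' Ordinary least squares of a response on the 10-column second-order model
#' matrix of a coded three-factor design, solved by QR decomposition. This is
#' the response-surface-methodology workhorse: the response is typically the
#' number of analytes meeting a recovery-compliance window at each design
#' run (see [compliant_count()]), and the fitted surface is subsequently
#' examined by [rsm_anova()], [adequacy_stats()] and [optimize_surface()].
#'
#' @param design A [bbd_design()] (or coded level matrix with 3 columns).
#' @param response Numeric response vector, one finite non-negative value
#'   per run; at least 10 runs with a full-rank model matrix are required.
#' @return An object of class `c("rsm_fit", "quad_surface")` with elements
#'   `coefficients`, `fitted.values`, `residuals`, `leverage` (hat-matrix
#'   diagonal), `design`, `response`, `df.residual` and `qr`.
#' @seealso [rsm_anova()], [adequacy_stats()], [optimize_surface()]
#' @examples
#' des <- bbd_design(c("A", "B", "C"))
#' surf <- quad_surface(40, c(-1, 1, 0), c(0, 0, 0), c(-5, -5, -5))
#' y <- predict(surf, des)
#' fit <- rsm_fit(des, y)           # noise-free: exact interpolation
#' all.equal(coef(fit), coef(surf), check.attributes = FALSE)
#' @export
rsm_fit <- function(design, response) {
  X <- rsm_model_matrix(design)
  y <- as.numeric(response)
  if (length(y) != nrow(X)) {
    stop("response length does not match the number of design runs", call. = FALSE)
  }
  if (!all(is.finite(y))) stop("response must be finite", call. = FALSE)
  if (any(y < 0)) stop("response must be non-negative", call. = FALSE)
  if (nrow(X) < ncol(X)) {
    stop("design must have at least 10 runs to fit the quadratic model",
         call. = FALSE)
  }
  qrx <- qr(X, tol = 1e-10)
  if (qrx$rank < ncol(X)) {
    stop("singular design: the second-order model matrix is rank-deficient",
         call. = FALSE)
  }
  cf <- qr.coef(qrx, y)
  fitted <- drop(X %*% cf)
  res <- y - fitted
  Q <- qr.Q(qrx)
  lev <- rowSums(Q^2)
  fn <- colnames(X)[2:4]
  structure(
    list(coefficients = cf, factor_names = fn,
         fitted.values = fitted, residuals = res, leverage = lev,
         design = design, response = y,
         df.residual = nrow(X) - ncol(X), qr = qrx),
    class = c("rsm_fit", "quad_surface")
  )
}

surface_parts <- function(object) {
  cf <- unname(object$coefficients)
  list(b0 = cf[1], lin = cf[2:4], int = cf[5:7], quad = cf[8:10])
}

#' Hessian of a quadratic surface
#'
#' The symmetric 3x3 Hessian in coded units: diagonal `2 * b_jj`,
#' off-diagonal the interaction coefficients.
#' @param object A `quad_surface` or `rsm_fit`.
#' @return A 3x3 symmetric numeric matrix.
#' @keywords internal
#' @export
surface_hessian <- function(object) {
  p <- surface_parts(object)
  H <- diag(2 * p$quad)
  H[1, 2] <- H[2, 1] <- p$int[1]
  H[1, 3] <- H[3, 1] <- p$int[2]
  H[2, 3] <- H[3, 2] <- p$int[3]
  dimnames(H) <- list(object$factor_names, object$factor_names)
  H
}

#' Evaluate a fitted response surface at coded points
#'
#' @param object A `quad_surface` or `rsm_fit`.
#' @param newdata Coded levels: a length-3 vector, a matrix/data.frame with
#'   one column per factor, or a [bbd_design()]. For an `rsm_fit` with
#'   `newdata` omitted the fitted values are returned.
#' @param ... Unused.
#' @return Predicted response value(s).
#' @export
predict.quad_surface <- function(object, newdata, ...) {
  if (missing(newdata)) {
    if (!is.null(object$fitted.values)) return(object$fitted.values)
    stop("`newdata` is required for a coefficient-only surface", call. = FALSE)
  }
  x <- if (inherits(newdata, "bbd_design")) coded_matrix(newdata) else {
    if (is.null(dim(newdata))) matrix(as.numeric(newdata), nrow = 1L)
    else as.matrix(newdata)
  }
  if (ncol(x) != 3L) stop("expected 3 coded factor levels", call. = FALSE)
  if (!all(is.finite(x))) stop("prediction points must be finite", call. = FALSE)
  X <- rsm_model_matrix(x)
  out <- drop(X %*% unname(object$coefficients))
  if (is.null(dim(newdata)) && !inherits(newdata, "bbd_design")) out[[1]] else out
}

#' @export
coef.quad_surface <- function(object, ...) object$coefficients

#' @export
residuals.rsm_fit <- function(object, ...) object$residuals

#' @export
fitted.rsm_fit <- function(object, ...) object$fitted.values

#' @export
print.quad_surface <- function(x, digits = 4, ...) {
  p <- surface_parts(x)
  fn <- x$factor_names
  term <- function(v, lab) sprintf("%+.*f %s", digits, v, lab)
  eq <- c(sprintf("%.*f", digits, p$b0),
          mapply(term, p$lin, fn),
          mapply(term, p$int, c(paste0(fn[1], fn[2]), paste0(fn[1], fn[3]),
                                paste0(fn[2], fn[3]))),
          mapply(term, p$quad, paste0(fn, "^2")))
  cat("Second-order response surface (coded units):\n")
  cat("  Y =", paste(eq, collapse = " "), "\n")
  invisible(x)
}

#' @export
print.rsm_fit <- function(x, digits = 4, ...) {
  print.quad_surface(x, digits = digits, ...)
  cat(sprintf("  %d runs, residual SS %.4g on %d df\n",
              length(x$response), sum(x$residuals^2), x$df.residual))
  invisible(x)
}

#' @export
summary.rsm_fit <- function(object, ...) {
  structure(
    list(surface = object,
         anova = rsm_anova(object),
         adequacy = adequacy_stats(object)),
    class = "summary.rsm_fit"
  )
}

#' @export
print.summary.rsm_fit <- function(x, ...) {
  print(x$surface)
  cat("\n")
  print(x$anova)
  cat("\n")
  print(x$adequacy)
  invisible(x)
}

#' Simulate response vectors consistent with a fitted surface
#'
#' Draws new response vectors `fitted + e` where `e` is Gaussian noise with
#' the fit's residual standard deviation, one column per simulation.
#'
#' @param object An `rsm_fit`.
#' @param nsim Number of response vectors.
#' @param seed Optional seed passed to [set.seed()].
#' @param ... Unused.
#' @return A data.frame with `nsim` columns.
#' @export
simulate.rsm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$response)
  sigma <- sqrt(sum(object$residuals^2) / object$df.residual)
  out <- as.data.frame(
    matrix(object$fitted.values + rnorm(n * nsim, sd = sigma), ncol = nsim,
           dimnames = list(NULL, paste0("sim_", seq_len(nsim))))
  )
  out
}

#' Contour view of a fitted surface over two factors
#'
#' Draws a filled contour of the predicted response over a pair of coded
#' factors with the remaining factor held fixed — the usual way interaction
#' structure and the location of the optimum are inspected in
#' response-surface work.
#'
#' @param x A `quad_surface` or `rsm_fit`.
#' @param which Indices of the two factors to vary (default 1, 2).
#' @param fix Coded level of the held-out factor (default 0).
#' @param n Grid resolution per axis.
#' @param ... Passed to [graphics::filled.contour()].
#' @return Invisibly, the prediction grid.
#' @export
plot.quad_surface <- function(x, which = c(1, 2), fix = 0, n = 60, ...) {
  stopifnot(length(which) == 2L, all(which %in% 1:3))
  g <- seq(-1, 1, length.out = n)
  pts <- as.matrix(expand.grid(u = g, v = g))
  full <- matrix(fix, nrow(pts), 3L)
  full[, which] <- pts
  z <- matrix(predict(x, full), n, n)
  fn <- x$factor_names
  graphics::filled.contour(
    g, g, z, xlab = paste(fn[which[1]], "(coded)"),
    ylab = paste(fn[which[2]], "(coded)"),
    main = "Predicted response", ...
  )
  invisible(list(x = g, y = g, z = z))
}
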