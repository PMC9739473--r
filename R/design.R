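#' Define a design factor with symmetric coded levels
#'
#' A factor in a response-surface experiment is run at three actual levels
#' (low, center, high) that map onto coded units -1, 0, +1. Coding must be
#' symmetric: the center is the midpoint of low and high, so that the
#' coded-to-actual map is a pure affine rescaling. For dispersive-SPE
#' optimization the actual levels are sorbent masses in mg.
#'
#' @param name Factor label, e.g. `"C18"`, `"PSA"`, `"Z-Sep+"`.
#' @param low,high Actual levels (e.g. mg of sorbent) assigned to coded -1
#'   and +1. Must be strictly positive with `low < high`.
#' @param center Actual level at coded 0; defaults to the midpoint and must
#'   equal it (asymmetric codings are rejected rather than silently
#'   mid-coded).
#' @return An object of class `"bbd_factor"`: a list with elements `name`,
#'   `low`, `center`, `high`, and `half_range`.
#' @examples
#' bbd_factor("C18", low = 100, high = 300)
#' @export
bbd_factor <- function(name, low, high, center = (low + high) / 2) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  vals <- c(low = low, center = center, high = high)
  if (!all(is.finite(vals))) {
    stop("factor levels must be finite numbers", call. = FALSE)
  }
  if (any(vals <= 0)) {
    stop("factor levels must be strictly positive", call. = FALSE)
  }
  if (!(low < center && center < high)) {
    stop("factor levels must satisfy low < center < high", call. = FALSE)
  }
  if (abs(center - (low + high) / 2) > 1e-8 * (high - low)) {
    stop("asymmetric coding: center must equal (low + high)/2", call. = FALSE)
  }
  structure(
    list(name = name, low = low, center = center, high = high,
         half_range = (high - low) / 2),
    class = "bbd_factor"
  )
}

#' @export
print.bbd_factor <- function(x, ...) {
  cat(sprintf("Factor %s: %g / %g / %g (coded -1 / 0 / +1)\n",
              x$name, x$low, x$center, x$high))
  invisible(x)
}

canonical_bbd3_edges <- function() {
  # edge runs by factor pair (1,2), (1,3), (2,3), each pair in
  # (-,-), (-,+), (+,-), (+,+) order; off-pair factor at 0
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  signs <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  out <- matrix(0, nrow = 12L, ncol = 3L)
  k <- 0L
  for (p in pairs) {
    for (s in seq_len(4L)) {
      k <- k + 1L
      out[k, p] <- signs[s, ]
    }
  }
  out
}

#' Generate a three-factor Box-Behnken design
#'
#' Produces the 12 edge-midpoint runs of the Box-Behnken geometry for three
#' factors, i.e. all (+/-1, +/-1) combinations over each factor pair with the
#' remaining factor at its center, plus `n_center` replicated center runs.
#' Runs are emitted in a fixed canonical order (pairs (A,B), (A,C), (B,C);
#' within a pair (-,-), (-,+), (+,-), (+,+); centers last) so that the design
#' is reproducible; run order randomization is a lab concern, not a
#' statistical one for the quantities computed here.
#'
#' @param factors A list of exactly three [bbd_factor()] objects, or a
#'   character vector of three factor names (coded-only design).
#' @param n_center Number of center-point replicates (>= 1); the default 5
#'   gives the classic 17-run design with 4 pure-error degrees of freedom.
#' @return A `data.frame` of class `"bbd_design"` with columns `run_id`,
#'   `point_type` (`"edge"` or `"center"`) and one coded-unit column per
#'   factor. Factor specifications (when supplied) are kept in
#'   `attr(, "factors")`.
#' @examples
#' des <- bbd_design(c("A", "B", "C"))
#' nrow(des)                 # 17
#' colSums(des[, c("A", "B", "C")])    # all zero
#' @export
bbd_design <- function(factors, n_center = 5L) {
  if (is.character(factors)) {
    names_ <- factors
    specs <- NULL
  } else if (is.list(factors) && all(vapply(factors, inherits, TRUE, "bbd_factor"))) {
    names_ <- vapply(factors, `[[`, "", "name")
    specs <- factors
  } else {
    stop("`factors` must be three bbd_factor objects or three names", call. = FALSE)
  }
  if (length(names_) != 3L) {
    stop("unsupported design: exactly 3 factors are required", call. = FALSE)
  }
  if (anyDuplicated(names_)) {
    stop("factor names must be distinct", call. = FALSE)
  }
  n_center <- as.integer(n_center)
  if (length(n_center) != 1L || is.na(n_center) || n_center < 1L) {
    stop("`n_center` must be a single integer >= 1", call. = FALSE)
  }
  coded <- rbind(canonical_bbd3_edges(), matrix(0, n_center, 3L))
  colnames(coded) <- names_
  des <- data.frame(
    run_id = seq_len(nrow(coded)),
    point_type = rep(c("edge", "center"), c(12L, n_center)),
    coded,
    check.names = FALSE
  )
  structure(des, factors = specs, class = c("bbd_design", "data.frame"))
}

#' @export
print.bbd_design <- function(x, ...) {
  nm <- design_factor_names(x)
  cat(sprintf("Box-Behnken design: 3 factors (%s), %d runs (%d edge + %d center)\n",
              paste(nm, collapse = ", "), nrow(x),
              sum(x$point_type == "edge"), sum(x$point_type == "center")))
  print.data.frame(x, ...)
  invisible(x)
}

design_factor_names <- function(design) {
  setdiff(names(design), c("run_id", "point_type"))
}

design_factor_specs <- function(design) {
  attr(design, "factors")
}

coded_matrix <- function(design) {
  as.matrix(design[, design_factor_names(design), drop = FALSE])
}

check_levels_span <- function(coded) {
  if (!all(is.finite(coded))) {
    stop("factor levels must be finite", call. = FALSE)
  }
  if (any(abs(coded) > 1.2)) {
    warning("coded levels beyond |1.2|: extrapolating outside the design region",
            call. = FALSE)
  }
  invisible(coded)
}

as_level_matrix <- function(values, specs) {
  nm <- vapply(specs, `[[`, "", "name")
  if (is.data.frame(values)) values <- as.matrix(values[, nm, drop = FALSE])
  if (is.null(dim(values))) {
    if (length(values) != length(specs)) {
      stop("expected one level per factor", call. = FALSE)
    }
    values <- matrix(values, nrow = 1L, dimnames = list(NULL, nm))
  }
  if (ncol(values) != length(specs)) {
    stop("expected one column per factor", call. = FALSE)
  }
  colnames(values) <- nm
  values
}

#' Map factor levels between coded and actual units
#'
#' The coding is affine: `coded = (actual - center) / half_range`, so a
#' coded-to-actual round trip is exact to machine precision. Levels beyond
#' |coded| > 1.2 are flagged with a warning (the quadratic surface is not
#' trusted that far outside the design region).
#'
#' @param values A numeric vector of one level per factor, or a matrix /
#'   data.frame with one column per factor.
#' @param factors A list of [bbd_factor()] objects, one per column of
#'   `values`.
#' @return Levels in the other unit system, same shape as `values`.
#' @examples
#' f <- list(bbd_factor("A", 100, 300), bbd_factor("B", 50, 150),
#'           bbd_factor("C", 20, 80))
#' coded_to_actual(c(0, 0, 0), f)   # centers: 200 100 50
#' actual_to_coded(c(300, 50, 50), f)  # +1 -1 0
#' @export
coded_to_actual <- function(values, factors) {
  m <- as_level_matrix(values, factors)
  check_levels_span(m)
  for (j in seq_along(factors)) {
    m[, j] <- factors[[j]]$center + m[, j] * factors[[j]]$half_range
  }
  if (is.null(dim(values))) drop(m) else m
}

#' @rdname coded_to_actual
#' @export
actual_to_coded <- function(values, factors) {
  m <- as_level_matrix(values, factors)
  if (!all(is.finite(m))) stop("factor levels must be finite", call. = FALSE)
  for (j in seq_along(factors)) {
    m[, j] <- (m[, j] - factors[[j]]$center) / factors[[j]]$half_range
  }
  check_levels_span(m)
  if (is.null(dim(values))) drop(m) else m
}

#' Second-order model matrix for a coded design
#'
#' Builds the 10-column model matrix (intercept, 3 linear, 3 pairwise
#' interaction, 3 pure quadratic terms) from the coded factor levels.
#'
#' @param design A [bbd_design()] or any matrix/data.frame of coded levels
#'   with three columns.
#' @return A numeric matrix with `nrow(design)` rows and 10 named columns.
#' @keywords internal
#' @export
rsm_model_matrix <- function(design) {
  x <- if (inherits(design, "bbd_design")) coded_matrix(design) else {
    m <- as.matrix(design)
    if (ncol(m) != 3L) stop("expected 3 coded factor columns", call. = FALSE)
    m
  }
  nm <- colnames(x)
  if (is.null(nm)) nm <- c("A", "B", "C")
  X <- cbind(
    1, x,
    x[, 1] * x[, 2], x[, 1] * x[, 3], x[, 2] * x[, 3],
    x[, 1]^2, x[, 2]^2, x[, 3]^2
  )
  colnames(X) <- c("(Intercept)", nm,
                   paste0(nm[1], ":", nm[2]), paste0(nm[1], ":", nm[3]),
                   paste0(nm[2], ":", nm[3]),
                   paste0(nm, "^2"))
  X
}
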