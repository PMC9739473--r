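xtx_inverse <- function(X) {
  chol2inv(chol(crossprod(X)))
}

pure_error_split <- function(design, response) {
  # replicate groups are identified by identical coded rows (the centers,
  # for a Box-Behnken design)
  key <- apply(coded_matrix(design), 1L, paste, collapse = "/")
  ss <- 0
  df <- 0L
  for (g in split(response, key)) {
    if (length(g) > 1L) {
      ss <- ss + sum((g - mean(g))^2)
      df <- df + length(g) - 1L
    }
  }
  list(ss = ss, df = df)
}

signif_flag <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Type-III ANOVA of a second-order response surface
#'
#' Decomposes the variation of a response-surface experiment into per-term
#' partial (Type-III) sums of squares, a residual, and the lack-of-fit
#' versus pure-error split, in the layout conventional for design-of-
#' experiments software. Each term's partial SS is
#' `beta_j^2 / [(X'X)^-1]_jj`; for the three-factor Box-Behnken design with
#' center replicates this is `8 b^2` for a linear term, `4 b^2` for an
#' interaction, and `b^2 / 0.2375` for a quadratic term (17 runs). Pure
#' error is computed from replicated design points only; on a design with
#' no replicates the residual is all lack of fit and a warning is issued.
#'
#' The decomposition can be computed in two ways: from a fitted model
#' carrying its raw response, or from a coefficient-only [quad_surface()]
#' plus externally supplied aggregate `residual_ss` and `pure_error_ss` —
#' the situation when reconstructing a published ANOVA from the printed
#' regression equation and residual rows.
#'
#' @param object An [rsm_fit()] (raw-data route) or [quad_surface()]
#'   (aggregate route).
#' @param design The design; taken from the fit when available.
#' @param response Optional raw response for a coefficient-only surface.
#' @param residual_ss,pure_error_ss Aggregate residual and pure-error sums
#'   of squares (used when no raw response is available).
#' @return A `data.frame` of class `"rsm_anova"` with columns `term`, `ss`,
#'   `df`, `ms`, `f`, `p` and `signif` (`**` for p < 0.01, `*` for
#'   p < 0.05), rows: Model, each of the 9 surface terms, Residual,
#'   Lack of fit, Pure error, Cor total.
#' @examples
#' surf <- quad_surface(41.80, c(-0.50, -1.50, -2.75),
#'                      c(-0.50, 1.00, 0.00), c(-7.90, -8.40, -2.90))
#' des <- bbd_design(c("A", "B", "C"))
#' rsm_anova(surf, design = des, residual_ss = 11.3, pure_error_ss = 2.8)
#' @export
rsm_anova <- function(object, design = NULL, response = NULL,
                      residual_ss = NULL, pure_error_ss = NULL) {
  if (inherits(object, "rsm_fit")) {
    if (is.null(design)) design <- object$design
    if (is.null(response)) response <- object$response
  }
  if (is.null(design)) {
    stop("a design is required (supply `design` for a coefficient-only surface)",
         call. = FALSE)
  }
  X <- rsm_model_matrix(design)
  cf <- unname(object$coefficients)
  n <- nrow(X)
  p <- ncol(X)
  df_res <- n - p
  if (df_res <= 0L) {
    stop("zero residual degrees of freedom: F statistics are undefined",
         call. = FALSE)
  }
  fitted <- drop(X %*% cf)

  if (!is.null(response)) {
    y <- as.numeric(response)
    if (length(y) != n) {
      stop("response length does not match the design", call. = FALSE)
    }
    residual_ss <- sum((y - fitted)^2)
    pe <- pure_error_split(design, y)
    pure_error_ss <- pe$ss
    df_pe <- pe$df
  } else {
    if (is.null(residual_ss) || is.null(pure_error_ss)) {
      stop("supply either a raw response or both `residual_ss` and `pure_error_ss`",
           call. = FALSE)
    }
    n_center <- sum(duplicated(coded_matrix(design)) |
                      duplicated(coded_matrix(design), fromLast = TRUE))
    # for a BBD all replicates are centers; df = replicates - groups
    key <- apply(coded_matrix(design), 1L, paste, collapse = "/")
    tab <- table(key)
    df_pe <- sum(pmax(tab - 1L, 0L))
  }
  if (pure_error_ss > residual_ss + 1e-9 * max(1, residual_ss)) {
    stop("inconsistent input: pure_error_ss exceeds residual_ss", call. = FALSE)
  }
  if (df_pe == 0L) {
    warning("no replicated design points: residual is all lack of fit",
            call. = FALSE)
  }
  lof_ss <- max(residual_ss - pure_error_ss, 0)
  df_lof <- df_res - df_pe

  XtXinv <- xtx_inverse(X)
  term_ss <- cf[-1]^2 / diag(XtXinv)[-1]
  model_ss <- sum((fitted - mean(fitted))^2)
  total_ss <- model_ss + residual_ss

  ms_res <- residual_ss / df_res
  rows <- data.frame(
    term = c("Model", colnames(X)[-1], "Residual", "Lack of fit",
             "Pure error", "Cor total"),
    ss = c(model_ss, term_ss, residual_ss, lof_ss, pure_error_ss, total_ss),
    df = c(p - 1L, rep(1L, p - 1L), df_res, df_lof, df_pe, n - 1L),
    stringsAsFactors = FALSE
  )
  rows$ms <- rows$ss / rows$df
  rows$ms[rows$df == 0L] <- NA_real_
  rows$f <- NA_real_
  rows$p <- NA_real_
  idx_terms <- seq_len(p)             # Model + the 9 surface terms
  rows$f[idx_terms] <- rows$ms[idx_terms] / ms_res
  rows$p[idx_terms] <- stats::pf(rows$f[idx_terms], rows$df[idx_terms],
                                 df_res, lower.tail = FALSE)
  i_lof <- p + 2L
  if (df_pe > 0L && df_lof > 0L && pure_error_ss > 0) {
    rows$f[i_lof] <- rows$ms[i_lof] / (pure_error_ss / df_pe)
    rows$p[i_lof] <- stats::pf(rows$f[i_lof], df_lof, df_pe, lower.tail = FALSE)
  }
  rows$signif <- signif_flag(rows$p)
  rows$signif[c(p + 1L, p + 3L, p + 4L)] <- ""
  structure(rows, class = c("rsm_anova", "data.frame"),
            ms_residual = ms_res, df_residual = df_res)
}

#' @export
anova.rsm_fit <- function(object, ...) rsm_anova(object, ...)

format_p <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p)))
}

#' @export
print.rsm_anova <- function(x, ...) {
  out <- data.frame(
    Source = x$term,
    `Sum Sq` = sprintf("%.4g", x$ss),
    Df = x$df,
    `Mean Sq` = ifelse(is.na(x$ms), "", sprintf("%.4g", x$ms)),
    `F value` = ifelse(is.na(x$f), "", sprintf("%.4g", x$f)),
    `Pr(>F)` = format_p(x$p),
    ` ` = x$signif,
    check.names = FALSE
  )
  cat("Analysis of variance (Type-III partial SS)\n")
  print(out, row.names = FALSE, right = TRUE)
  cat("---\n'**' p < 0.01, '*' p < 0.05\n")
  invisible(x)
}

#' Adequacy diagnostics of a response-surface fit
#'
#' Computes the fit-quality statistics conventional in design-of-experiments
#' reporting: the coefficient of determination R^2, its degrees-of-freedom-
#' adjusted version, the leave-one-out PRESS statistic and predicted R^2,
#' and "adequate precision" — the signal-to-noise ratio
#' `(max fitted - min fitted) / sqrt(p * MS_res / n)` over the design
#' points, with `p` the number of model parameters; values above 4 indicate
#' the surface discriminates adequately.
#'
#' PRESS and predicted R^2 require the raw response (they use the leverage
#' of each run: `press = sum((e_i / (1 - h_ii))^2)`); when only aggregate
#' sums of squares are supplied they are reported as `NA`.
#'
#' @param object An [rsm_fit()], or a [quad_surface()] with `design`,
#'   `residual_ss` and `total_ss` supplied.
#' @param design Design for the aggregate route.
#' @param residual_ss,total_ss Aggregate residual and corrected-total sums
#'   of squares.
#' @return An object of class `"adequacy_stats"`: list with `r2`, `adj_r2`,
#'   `pred_r2`, `press`, `adeq_precision`.
#' @examples
#' surf <- quad_surface(41.80, c(-0.50, -1.50, -2.75),
#'                      c(-0.50, 1.00, 0.00), c(-7.90, -8.40, -2.90))
#' des <- bbd_design(c("A", "B", "C"))
#' adequacy_stats(surf, design = des, residual_ss = 11.3, total_ss = 749.06)
#' @export
adequacy_stats <- function(object, design = NULL, residual_ss = NULL,
                           total_ss = NULL) {
  if (inherits(object, "rsm_fit")) {
    design <- object$design
    y <- object$response
    residual_ss <- sum(object$residuals^2)
    total_ss <- sum((y - mean(y))^2)
    h <- object$leverage
    if (any(h >= 1 - 1e-12)) {
      stop("a run has leverage 1: PRESS is undefined", call. = FALSE)
    }
    press <- sum((object$residuals / (1 - h))^2)
    fitted <- object$fitted.values
    n <- length(y)
  } else {
    if (is.null(design) || is.null(residual_ss) || is.null(total_ss)) {
      stop("aggregate route needs `design`, `residual_ss` and `total_ss`",
           call. = FALSE)
    }
    fitted <- predict(object, design)
    press <- NA_real_
    n <- nrow(design)
  }
  p <- 10L
  df_res <- n - p
  df_tot <- n - 1L
  r2 <- 1 - residual_ss / total_ss
  adj_r2 <- 1 - (residual_ss / df_res) / (total_ss / df_tot)
  pred_r2 <- if (is.na(press)) NA_real_ else 1 - press / total_ss
  ms_res <- residual_ss / df_res
  adeq <- (max(fitted) - min(fitted)) / sqrt(p * ms_res / n)
  structure(
    list(r2 = r2, adj_r2 = adj_r2, pred_r2 = pred_r2, press = press,
         adeq_precision = adeq, n = n, p = p),
    class = "adequacy_stats"
  )
}

#' @export
print.adequacy_stats <- function(x, ...) {
  cat("Model adequacy:\n")
  cat(sprintf("  R-squared        %.4f\n", x$r2))
  cat(sprintf("  Adjusted R-sq    %.4f\n", x$adj_r2))
  if (!is.na(x$pred_r2)) {
    cat(sprintf("  Predicted R-sq   %.4f   (PRESS %.4g)\n", x$pred_r2, x$press))
  } else {
    cat("  Predicted R-sq   unavailable (raw response not supplied)\n")
  }
  cat(sprintf("  Adeq precision   %.3f   (> 4 adequate)\n", x$adeq_precision))
  invisible(x)
}
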