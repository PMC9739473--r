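#' Bundled reference dataset: sorbent clean-up optimization
#'
#' The package ships, as plain-text tables under `extdata/`, the summary
#' results of a three-sorbent (C18, PSA, Z-Sep+) dispersive-SPE clean-up
#' optimization for a 43-drug antimicrobial panel in cured pork matrices:
#' the reported second-order regression equation in coded units, the
#' aggregate ANOVA quantities (residual and pure-error sums of squares and
#' degrees of freedom, corrected total), and the per-analyte decision
#' limit / detection capability / LOQ table for both matrices at a 50
#' ug/kg validation level. These give every example and check a realistic
#' anchor without any raw instrument data.
#'
#' @return `sorbent_surface_example()`: a [quad_surface()].
#'   `sorbent_anova_aggregates()`: a named list of aggregate scalars.
#'   `validation_limits_table()`: a data frame with columns `compound`,
#'   `group`, `matrix`, `cc_alpha`, `cc_beta`, `loq` (ug/kg).
#' @examples
#' surf <- sorbent_surface_example()
#' predict(surf, c(0, 0, 0))
#' @export
sorbent_surface_example <- function() {
  path <- system.file("extdata", "sorbent_surface.csv", package = "rsmval",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  est <- stats::setNames(tab$estimate, tab$term)
  quad_surface(est[["intercept"]],
               linear = est[c("A", "B", "C")],
               interaction = est[c("AB", "AC", "BC")],
               quadratic = est[c("A2", "B2", "C2")])
}

#' @rdname sorbent_surface_example
#' @export
sorbent_anova_aggregates <- function() {
  path <- system.file("extdata", "sorbent_anova_aggregates.csv",
                      package = "rsmval", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as.list(stats::setNames(tab$value, tab$quantity))
}

#' @rdname sorbent_surface_example
#' @export
validation_limits_table <- function() {
  path <- system.file("extdata", "validation_limits.csv", package = "rsmval",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
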