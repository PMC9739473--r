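table_schemas <- list(
  design = c("run_id", "point_type"),
  response = c("run_id", "y"),
  recovery = c("analyte", "matrix", "spike_level", "day", "replicate",
               "measured"),
  calibration = c("analyte", "matrix_flag", "level", "response")
)

numeric_cols <- list(
  design = character(0),
  response = "y",
  recovery = c("spike_level", "day", "replicate", "measured"),
  calibration = c("level", "response")
)

#' Read a delimited pipeline table with schema validation
#'
#' Reads one of the pipeline's comma-separated file formats and validates
#' it: headers are matched case-insensitively against the schema, missing
#' columns are reported by name, numeric columns are checked cell by cell
#' with the offending row number in the error, and an empty data section is
#' an explicit error rather than a downstream crash.
#'
#' @param path Path to a CSV file with a single header row.
#' @param schema One of `"design"`, `"response"`, `"recovery"`,
#'   `"calibration"`.
#' @return A validated `data.frame` (for `"design"`, a [bbd_design()]).
#' @export
read_tables <- function(path, schema = c("design", "response", "recovery",
                                         "calibration")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- ifelse(tolower(names(df)) %in% tolower(table_schemas[[schema]]) |
                        tolower(names(df)) %in% tolower(unlist(numeric_cols)),
                      tolower(names(df)), names(df))
  required <- table_schemas[[schema]]
  missing <- required[!tolower(required) %in% tolower(names(df))]
  if (length(missing)) {
    stop(sprintf("schema error in '%s': missing column(s) %s", path,
                 paste0('"', missing, '"', collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop(sprintf("empty table: '%s' has a header but no data rows", path),
         call. = FALSE)
  }
  for (col in intersect(numeric_cols[[schema]], names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad)) {
      stop(sprintf("unparseable numeric in '%s', column \"%s\", data row %d: %s",
                   path, col, bad[1], df[[col]][bad[1]]), call. = FALSE)
    }
    df[[col]] <- v
  }
  if (schema == "design") {
    # a trailing response column may ride along with the design
    fac_cols <- setdiff(names(df), c("run_id", "point_type", "y"))
    if (length(fac_cols) != 3L) {
      stop("schema error: a design file needs exactly 3 factor columns",
           call. = FALSE)
    }
    for (col in fac_cols) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]))
      if (length(bad)) {
        stop(sprintf("unparseable numeric in '%s', column \"%s\", data row %d",
                     path, col, bad[1]), call. = FALSE)
      }
      df[[col]] <- v
    }
    df <- structure(df, class = c("bbd_design", "data.frame"))
  }
  df
}

#' Write a design (optionally with response) to a CSV file
#'
#' @param design A [bbd_design()].
#' @param path Output path.
#' @param response Optional response vector written as a `y` column.
#' @param factors Optional [bbd_factor()] list: when supplied, a parallel
#'   file with `_actual` appended to the name is written in actual units.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path, response = NULL, factors = NULL) {
  out <- as.data.frame(design)
  if (!is.null(response)) {
    stopifnot(length(response) == nrow(out))
    out$y <- response
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(factors)) {
    act <- out
    nm <- design_factor_names(design)
    act[, nm] <- coded_to_actual(as.matrix(out[, nm]), factors)
    path2 <- sub("(\\.[^.]+)?$", "_actual\\1", path)
    utils::write.csv(act, path2, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write an ANOVA table as CSV
#'
#' @param x An [rsm_anova()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anova <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

anova_as_list <- function(a) {
  lapply(seq_len(nrow(a)), function(i) {
    list(term = a$term[i], ss = a$ss[i], df = a$df[i],
         ms = a$ms[i], f = a$f[i], p = a$p[i], signif = a$signif[i])
  })
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  known <- c("factors", "n_center", "vl", "window", "rounding", "seed",
             "n_analytes", "noise_cv", "sd_02vl", "n_replicates",
             "design_file", "response_file", "recovery_file",
             "calibration_file", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(n_center = 5L, vl = 50, window = c(80, 110),
                   rounding = "truncate", seed = 1L, n_analytes = 43L,
                   n_replicates = 3L)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  config
}

config_factors <- function(config) {
  f <- config$factors
  if (is.null(f)) {
    return(list(names = c("A", "B", "C"), specs = NULL))
  }
  if (is.character(f)) return(list(names = f, specs = NULL))
  if (is.data.frame(f)) f <- split(f, seq_len(nrow(f)))
  specs <- lapply(f, function(x) {
    bbd_factor(x$name, low = x$low, high = x$high,
               center = if (is.null(x$center)) (x$low + x$high) / 2 else x$center)
  })
  list(names = vapply(specs, `[[`, "", "name"), specs = specs)
}

#' Run the method-development pipeline end to end
#'
#' Composes the pipeline stages — design generation, simulated or file-based
#' response acquisition, surface fitting, ANOVA and adequacy, constrained
#' optimization, and spiked-recovery validation — under one configuration
#' with one seed, and writes a machine-readable JSON report plus delimited
#' tables. Identical configuration and seed give a byte-identical report.
#'
#' @param config A configuration list or path to a JSON configuration file.
#'   Recognized keys: `factors` (names, or name/low/high records),
#'   `n_center`, `vl`, `window`, `rounding`, `seed`, `n_analytes`,
#'   `noise_cv`, `sd_02vl`, `n_replicates`, `design_file`, `response_file`,
#'   `recovery_file`, `calibration_file`, `out_dir`. Unknown keys are
#'   rejected.
#' @param stages Subset of `c("design", "simulate", "fit", "anova",
#'   "optimize", "validate")`. Stage dependencies are checked: `fit` needs a
#'   design and a response (from a file or the `simulate` stage); `anova`
#'   and `optimize` need `fit`; `validate` needs recovery records.
#' @return The report, invisibly: a list with elements per executed stage.
#' @export
run_pipeline <- function(config,
                         stages = c("design", "simulate", "fit", "anova",
                                    "optimize", "validate")) {
  config <- resolve_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  fac <- config_factors(config)
  report <- list(config = list(seed = config$seed, vl = config$vl,
                               n_center = config$n_center,
                               window = config$window,
                               rounding = config$rounding))
  rule <- compliance_rule(config$window[1], config$window[2])

  design <- NULL
  if ("design" %in% stages) {
    design <- if (!is.null(config$design_file)) {
      read_tables(config$design_file, "design")
    } else if (!is.null(fac$specs)) {
      bbd_design(fac$specs, config$n_center)
    } else {
      bbd_design(fac$names, config$n_center)
    }
    report$design <- list(n_runs = nrow(design),
                          n_center = sum(design$point_type == "center"),
                          factors = design_factor_names(design))
  }

  truth <- NULL
  records <- NULL
  response <- NULL
  if ("simulate" %in% stages) {
    truth <- synthetic_truth(
      n_analytes = config$n_analytes, seed = config$seed,
      noise_cv = if (is.null(config$noise_cv)) 0.08 else config$noise_cv,
      sd_02vl = if (is.null(config$sd_02vl)) 0.55 else config$sd_02vl
    )
    if (!is.null(design)) {
      records <- simulate_recovery_experiment(
        truth, design, n_replicates = config$n_replicates,
        spike = config$vl, seed = config$seed
      )
      response <- count_response(records, design, rule)
    }
    report$simulate <- list(n_analytes = nrow(truth$analytes),
                            noise_cv = truth$noise_cv,
                            sd_02vl = truth$sd_02vl)
  }
  if (!is.null(config$response_file)) {
    rtab <- read_tables(config$response_file, "response")
    response <- rtab$y
  }

  fit <- NULL
  if ("fit" %in% stages) {
    missing <- c(if (is.null(design)) "a design (design stage or design_file)",
                 if (is.null(response)) "a response (simulate stage or response_file)")
    if (length(missing)) {
      stop("dependency error: stage 'fit' is missing ",
           paste(missing, collapse = " and "), call. = FALSE)
    }
    fit <- rsm_fit(design, response)
    report$fit <- list(coefficients = as.list(coef(fit)),
                       residual_ss = sum(residuals(fit)^2))
  }

  if ("anova" %in% stages) {
    if (is.null(fit)) {
      stop("dependency error: stage 'anova' needs stage 'fit' ",
           "(neither a raw response nor a fitted model is available)",
           call. = FALSE)
    }
    a <- rsm_anova(fit)
    adq <- adequacy_stats(fit)
    report$anova <- anova_as_list(a)
    report$adequacy <- list(r2 = adq$r2, adj_r2 = adq$adj_r2,
                            pred_r2 = adq$pred_r2, press = adq$press,
                            adeq_precision = adq$adeq_precision)
    if (!is.null(out_dir)) write_anova(a, file.path(out_dir, "anova.csv"))
  }

  if ("optimize" %in% stages) {
    if (is.null(fit)) {
      stop("dependency error: stage 'optimize' needs stage 'fit'",
           call. = FALSE)
    }
    opt <- optimize_surface(fit, factors = fac$specs,
                            rounding = config$rounding)
    report$optimum <- list(
      coded = as.list(opt$coded),
      actual = if (is.null(opt$actual)) NULL else as.list(opt$actual),
      predicted = opt$predicted, predicted_count = opt$predicted_count,
      on_boundary = opt$on_boundary
    )
  }

  if ("validate" %in% stages) {
    vrecords <- if (!is.null(config$recovery_file)) {
      read_tables(config$recovery_file, "recovery")
    } else if (!is.null(truth)) {
      simulate_quant_assets(truth, vl = config$vl,
                            seed = config$seed)$replicates_02vl
    }
    curves <- if (!is.null(config$calibration_file)) {
      read_tables(config$calibration_file, "calibration")
    } else if (!is.null(truth)) {
      simulate_quant_assets(truth, vl = config$vl, seed = config$seed)$curves
    }
    if (is.null(vrecords)) {
      stop("dependency error: stage 'validate' needs recovery records ",
           "(recovery_file or the simulate stage)", call. = FALSE)
    }
    vs <- validation_summary(vrecords, curves, rule = rule, vl = config$vl)
    report$validation <- list(
      n_combinations = nrow(vs$analytes),
      mean_cc_alpha = mean(vs$analytes$cc_alpha, na.rm = TRUE),
      mean_cc_beta = mean(vs$analytes$cc_beta, na.rm = TRUE),
      strong_me_share = if (all(is.na(vs$analytes$me))) NA_real_ else
        mean(vs$analytes$me_class == "strong", na.rm = TRUE)
    )
    if (!is.null(out_dir)) {
      utils::write.csv(vs$analytes, file.path(out_dir, "validation_summary.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    if (!is.null(design)) {
      write_design(design, file.path(out_dir, "design.csv"),
                   response = response, factors = fac$specs)
    }
  }
  invisible(report)
}
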