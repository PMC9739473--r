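#' Recovery-compliance rule
#'
#' The acceptance window applied to spiked-recovery results when counting
#' compliant analytes. Regulatory guidance recommends recoveries between
#' 80% and 110% for spikes above 10 ug/kg; both endpoints are treated as
#' compliant. The window is applied at all spike levels by default — wider
#' low-level windows, where wanted, are expressed by constructing a
#' different rule rather than hard-coding level logic.
#'
#' @param lower,upper Recovery window in percent (default 80 and 110).
#' @param level_threshold Spike level (ug/kg) above which the window is the
#'   recommended one; carried as metadata (default 10).
#' @return Object of class `"compliance_rule"`.
#' @export
compliance_rule <- function(lower = 80, upper = 110, level_threshold = 10) {
  if (!(is.finite(lower) && is.finite(upper) && lower < upper)) {
    stop("`lower` must be less than `upper`", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper,
                 level_threshold = level_threshold),
            class = "compliance_rule")
}

check_recovery_records <- function(records) {
  needed <- c("analyte", "spike_level", "measured")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("recovery records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) {
    stop("recovery records are empty", call. = FALSE)
  }
  if (any(records$spike_level <= 0)) {
    stop("spike_level must be positive", call. = FALSE)
  }
  if (any(records$measured < 0)) {
    stop("measured concentrations must be non-negative", call. = FALSE)
  }
  invisible(records)
}

#' Count analytes meeting the recovery window
#'
#' The design-of-experiments response: for one experimental condition,
#' computes each analyte's mean recovery (`100 * measured / spike_level`
#' averaged over replicates) and counts how many fall inside the compliance
#' window, endpoints included.
#'
#' @param records Data frame with columns `analyte`, `spike_level`,
#'   `measured` (long format; one row per replicate measurement), all for a
#'   single condition.
#' @param rule A [compliance_rule()].
#' @return Integer count of compliant analytes.
#' @examples
#' rec <- data.frame(analyte = c("a", "b"), spike_level = 50,
#'                   measured = c(45, 60))
#' compliant_count(rec)   # a: 90% in; b: 120% out -> 1
#' @export
compliant_count <- function(records, rule = compliance_rule()) {
  check_recovery_records(records)
  recovery <- 100 * records$measured / records$spike_level
  mean_rec <- tapply(recovery, records$analyte, mean)
  sum(mean_rec >= rule$lower & mean_rec <= rule$upper)
}

#' Decision limit and detection capability
#'
#' For analytes without a maximum residue limit, validated at a level of
#' `0.2 * VL`, the 2002/657/EC decision limit and detection capability are
#' `CCalpha = 0.2 VL + 1.64 SD` and `CCbeta = CCalpha + 1.64 SD`, where SD
#' is the standard deviation of measured concentrations at the 0.2 x VL
#' spike. The spacing identity `CCbeta - CCalpha = CCalpha - 0.2 VL` is
#' exact by construction.
#'
#' @param vl Validation level (ug/kg), e.g. 50.
#' @param sd_02vl Standard deviation of measured concentrations at the
#'   0.2 x VL spike (ug/kg), >= 0.
#' @return Named numeric vector `c(cc_alpha, cc_beta)` in ug/kg.
#' @examples
#' cc_limits(50, 0.549)   # approx 10.9, 11.8
#' @export
cc_limits <- function(vl, sd_02vl) {
  if (!is.finite(vl) || vl <= 0) stop("`vl` must be positive", call. = FALSE)
  if (!is.finite(sd_02vl) || sd_02vl < 0) {
    stop("`sd_02vl` must be non-negative", call. = FALSE)
  }
  cc_alpha <- 0.2 * vl + 1.64 * sd_02vl
  c(cc_alpha = cc_alpha, cc_beta = cc_alpha + 1.64 * sd_02vl)
}

#' Fit a calibration curve
#'
#' Ordinary least squares of instrument response on concentration level.
#' At least three distinct levels are required.
#'
#' @param levels Concentration levels (ug/L).
#' @param responses Instrument responses (arbitrary units).
#' @param context `"matrix"` (matrix-matched) or `"solvent"`.
#' @return Object of class `"calibration_curve"`: list with `slope`,
#'   `intercept`, `r2`, `context`, `levels`, `responses`.
#' @export
fit_calibration <- function(levels, responses, context = c("matrix", "solvent")) {
  context <- match.arg(context)
  if (length(unique(levels)) < 3L) {
    stop("at least 3 distinct calibration levels are required", call. = FALSE)
  }
  if (length(levels) != length(responses)) {
    stop("levels and responses differ in length", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, levels), responses)
  cf <- fit$coefficients
  if (!all(is.finite(cf))) stop("calibration fit failed", call. = FALSE)
  tot <- sum((responses - mean(responses))^2)
  r2 <- if (tot > 0) 1 - sum(fit$residuals^2) / tot else NA_real_
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]), r2 = r2,
                 context = context, levels = levels, responses = responses),
            class = "calibration_curve")
}

#' Matrix effect from calibration slope ratios
#'
#' `ME(%) = (S_mat / S_sol - 1) * 100`, the relative signal change caused
#' by co-extracted matrix. Effects within [-50, 50] percent (inclusive) are
#' classed `"mild_or_medium"`, anything beyond `"strong"` (suppression when
#' negative, enhancement when positive).
#'
#' @param matrix_curve A [fit_calibration()] object (or bare slope) for the
#'   matrix-matched curve.
#' @param solvent_curve Same, for the solvent curve; slope must be nonzero.
#' @return List with `me` (percent) and `class`.
#' @examples
#' matrix_effect(0.4, 0.8)   # -50%, mild_or_medium (boundary inclusive)
#' @export
matrix_effect <- function(matrix_curve, solvent_curve) {
  s_mat <- if (inherits(matrix_curve, "calibration_curve")) matrix_curve$slope
           else as.numeric(matrix_curve)
  s_sol <- if (inherits(solvent_curve, "calibration_curve")) solvent_curve$slope
           else as.numeric(solvent_curve)
  if (!is.finite(s_sol) || s_sol == 0) {
    stop("solvent slope is zero: matrix effect undefined", call. = FALSE)
  }
  me <- (s_mat / s_sol - 1) * 100
  list(me = me,
       class = if (me >= -50 && me <= 50) "mild_or_medium" else "strong")
}

#' Limit of quantification from signal-to-noise
#'
#' The LOQ is the concentration giving a signal-to-noise ratio of 10,
#' obtained by linear scaling from a reference spike:
#' `LOQ = 10 * conc / SN`.
#'
#' @param reference_conc Concentration (ug/kg) of the reference measurement.
#' @param sn_at_reference Signal-to-noise ratio observed there (> 0).
#' @return LOQ in ug/kg.
#' @examples
#' loq_estimate(0.2, 4)   # 0.5
#' @export
loq_estimate <- function(reference_conc, sn_at_reference) {
  if (!is.finite(sn_at_reference) || sn_at_reference <= 0) {
    stop("signal-to-noise must be positive", call. = FALSE)
  }
  if (!is.finite(reference_conc) || reference_conc <= 0) {
    stop("reference concentration must be positive", call. = FALSE)
  }
  10 * reference_conc / sn_at_reference
}

rsd_pct <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  100 * stats::sd(x) / mean(x)
}

# pooled within-day RSD: root-mean-square of per-day RSDs over days with
# at least two replicates
intra_day_rsd <- function(measured, day) {
  per_day <- tapply(measured, day, rsd_pct)
  per_day <- per_day[!is.na(per_day)]
  if (!length(per_day)) return(NA_real_)
  sqrt(mean(per_day^2))
}

#' Full 2002/657/EC validation summary
#'
#' Assembles, per analyte and matrix, the validation metrics reported for a
#' targeted multi-residue method: mean recovery and intra-/inter-day
#' precision at each spike level, CCalpha/CCbeta from the SD of measured
#' concentrations at the 0.2 x VL spike (pooled across days), the matrix
#' effect with its classification, linearity of the matrix-matched curve
#' (pass when R^2 > 0.99), and — when signal-to-noise observations are
#' supplied — the LOQ.
#'
#' Intra-day RSD is the pooled (root-mean-square) within-day RSD; inter-day
#' RSD is the RSD of all replicates across days. When the 0.2 x VL level is
#' absent for an analyte, CCalpha/CCbeta are reported `NA` rather than
#' defaulted.
#'
#' @param records Long-format recovery data: columns `analyte`, `matrix`,
#'   `spike_level`, `day`, `replicate`, `measured`.
#' @param curves Optional calibration data: columns `analyte`,
#'   `matrix_flag` (a matrix name or `"solvent"`), `level`, `response`.
#' @param rule A [compliance_rule()].
#' @param vl Validation level in ug/kg (default 50).
#' @param sn Optional signal-to-noise table: columns `analyte`, `matrix`,
#'   `reference_conc`, `sn`.
#' @return Object of class `"validation_summary"`: list with `analytes`
#'   (one row per analyte x matrix: `mean_recovery`, `intra_day_rsd`,
#'   `inter_day_rsd`, `cc_alpha`, `cc_beta`, `loq`, `me`, `me_class`,
#'   `linearity_r2`, `linearity_pass`), `levels` (per analyte x matrix x
#'   spike level), `vl` and `rule`.
#' @export
validation_summary <- function(records, curves = NULL,
                               rule = compliance_rule(), vl = 50, sn = NULL) {
  check_recovery_records(records)
  for (col in c("matrix", "day", "replicate")) {
    if (is.null(records[[col]])) {
      stop("recovery records lack column(s): ", col, call. = FALSE)
    }
  }
  records$recovery <- 100 * records$measured / records$spike_level
  lvl_key <- interaction(records$analyte, records$matrix, records$spike_level,
                         drop = TRUE)
  lvl_rows <- lapply(split(records, lvl_key), function(d) {
    data.frame(
      analyte = d$analyte[1], matrix = d$matrix[1],
      spike_level = d$spike_level[1],
      mean_recovery = mean(d$recovery),
      intra_day_rsd = intra_day_rsd(d$measured, d$day),
      inter_day_rsd = rsd_pct(d$measured),
      n = nrow(d),
      stringsAsFactors = FALSE
    )
  })
  levels_df <- do.call(rbind, lvl_rows)
  levels_df <- levels_df[order(levels_df$analyte, levels_df$matrix,
                               levels_df$spike_level), ]
  rownames(levels_df) <- NULL

  solvent_curves <- list()
  matrix_curves <- list()
  if (!is.null(curves)) {
    for (col in c("analyte", "matrix_flag", "level", "response")) {
      if (is.null(curves[[col]])) {
        stop("calibration data lack column(s): ", col, call. = FALSE)
      }
    }
    for (d in split(curves, interaction(curves$analyte, curves$matrix_flag,
                                        drop = TRUE))) {
      ctx <- if (identical(d$matrix_flag[1], "solvent")) "solvent" else "matrix"
      cv <- fit_calibration(d$level, d$response, context = ctx)
      if (ctx == "solvent") solvent_curves[[d$analyte[1]]] <- cv
      else matrix_curves[[paste(d$analyte[1], d$matrix_flag[1], sep = "\r")]] <- cv
    }
  }

  an_key <- interaction(records$analyte, records$matrix, drop = TRUE)
  an_rows <- lapply(split(records, an_key), function(d) {
    analyte <- d$analyte[1]; mat <- d$matrix[1]
    at02 <- d[abs(d$spike_level - 0.2 * vl) < 1e-9, ]
    if (nrow(at02) >= 2L) {
      cc <- cc_limits(vl, stats::sd(at02$measured))
    } else {
      cc <- c(cc_alpha = NA_real_, cc_beta = NA_real_)
    }
    mc <- matrix_curves[[paste(analyte, mat, sep = "\r")]]
    sc <- solvent_curves[[analyte]]
    me <- if (!is.null(mc) && !is.null(sc)) matrix_effect(mc, sc)
          else list(me = NA_real_, class = NA_character_)
    r2 <- if (!is.null(mc)) mc$r2 else NA_real_
    loq <- NA_real_
    if (!is.null(sn)) {
      row <- sn[sn$analyte == analyte & sn$matrix == mat, , drop = FALSE]
      if (nrow(row) == 1L) loq <- loq_estimate(row$reference_conc, row$sn)
    }
    data.frame(
      analyte = analyte, matrix = mat,
      mean_recovery = mean(d$recovery),
      intra_day_rsd = intra_day_rsd(d$measured / d$spike_level,
                                    paste(d$spike_level, d$day)),
      inter_day_rsd = {
        per_level <- tapply(seq_len(nrow(d)), d$spike_level,
                            function(i) rsd_pct(d$measured[i]))
        sqrt(mean(per_level^2, na.rm = TRUE))
      },
      cc_alpha = unname(cc["cc_alpha"]), cc_beta = unname(cc["cc_beta"]),
      loq = loq, me = me$me, me_class = me$class,
      linearity_r2 = r2,
      linearity_pass = if (is.na(r2)) NA else r2 > 0.99,
      stringsAsFactors = FALSE
    )
  })
  analytes_df <- do.call(rbind, an_rows)
  analytes_df <- analytes_df[order(analytes_df$analyte, analytes_df$matrix), ]
  rownames(analytes_df) <- NULL

  structure(list(analytes = analytes_df, levels = levels_df, vl = vl,
                 rule = rule),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("Validation summary: %d analyte x matrix combinations, VL = %g ug/kg\n",
              nrow(x$analytes), x$vl))
  cat(sprintf("Recovery window: %g-%g%%\n", x$rule$lower, x$rule$upper))
  print(utils::head(x$analytes, 10))
  if (nrow(x$analytes) > 10L) {
    cat("...", nrow(x$analytes) - 10L, "more rows\n")
  }
  invisible(x)
}
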