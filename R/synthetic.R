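with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Ground-truth parameters for simulated validation experiments
#'
#' Defines the data-generating process behind the synthetic spiked-recovery
#' experiments: each analyte has a quadratic true-recovery surface over the
#' coded clean-up factors (baseline recovery at the center, small linear and
#' interaction terms, negative curvature so recovery degrades toward the
#' region edges), a multiplicative Gaussian measurement noise CV, a pair of
#' solvent / matrix-matched calibration slopes, and a replicate SD at the
#' 0.2 x VL spike.
#'
#' Defaults emulate a 43-analyte multi-residue panel: baseline recoveries
#' 88-106%, curvature around -8% per coded unit squared (so several
#' analytes drift out of an 80-110% window at the design edges), noise CV
#' 8%, and SD 0.55 ug/kg at the 10 ug/kg spike.
#'
#' @param n_analytes Panel size (default 43).
#' @param seed Integer seed; fixes every downstream draw.
#' @param baseline_range Range of center-point true recoveries (%).
#' @param linear_sd,interaction_sd SDs of per-analyte linear and interaction
#'   surface terms (% per coded unit).
#' @param curvature_mean,curvature_sd Mean and SD of per-analyte quadratic
#'   terms (% per coded unit squared; mean should be negative).
#' @param noise_cv Measurement coefficient of variation (fraction, not %).
#' @param sd_02vl Replicate SD of measured concentration at the 0.2 x VL
#'   spike (ug/kg).
#' @param cal_noise_cv CV of calibration responses.
#' @param me_mean,me_sd Mean and SD of per-analyte matrix effects (%),
#'   which set the matrix-matched slope relative to the solvent slope.
#' @return Object of class `"synthetic_truth"`: list with an `analytes`
#'   data frame (surface and slope parameters per analyte) and the global
#'   noise settings.
#' @export
synthetic_truth <- function(n_analytes = 43L, seed = 1L,
                            baseline_range = c(88, 106),
                            linear_sd = 2, interaction_sd = 1,
                            curvature_mean = -8, curvature_sd = 3,
                            noise_cv = 0.08, sd_02vl = 0.55,
                            cal_noise_cv = 0.02,
                            me_mean = -15, me_sd = 25) {
  if (n_analytes < 1L) stop("need at least one analyte", call. = FALSE)
  if (noise_cv < 0 || cal_noise_cv < 0) {
    stop("noise CVs must be non-negative", call. = FALSE)
  }
  if (sd_02vl < 0) stop("sd_02vl must be non-negative", call. = FALSE)
  if (any(baseline_range <= 0) || any(baseline_range > 150)) {
    stop("baseline recoveries must lie in (0, 150]", call. = FALSE)
  }
  analytes <- with_seed(seed, {
    data.frame(
      analyte = sprintf("analyte_%02d", seq_len(n_analytes)),
      baseline = stats::runif(n_analytes, baseline_range[1], baseline_range[2]),
      lin_A = stats::rnorm(n_analytes, 0, linear_sd),
      lin_B = stats::rnorm(n_analytes, 0, linear_sd),
      lin_C = stats::rnorm(n_analytes, 0, linear_sd),
      int_AB = stats::rnorm(n_analytes, 0, interaction_sd),
      int_AC = stats::rnorm(n_analytes, 0, interaction_sd),
      int_BC = stats::rnorm(n_analytes, 0, interaction_sd),
      quad_A = stats::rnorm(n_analytes, curvature_mean, curvature_sd),
      quad_B = stats::rnorm(n_analytes, curvature_mean, curvature_sd),
      quad_C = stats::rnorm(n_analytes, curvature_mean, curvature_sd),
      slope_sol = stats::rlnorm(n_analytes, 0, 0.3),
      me_true = stats::rnorm(n_analytes, me_mean, me_sd),
      stringsAsFactors = FALSE
    )
  })
  analytes$slope_mat <- analytes$slope_sol * (1 + analytes$me_true / 100)
  structure(
    list(analytes = analytes, noise_cv = noise_cv, sd_02vl = sd_02vl,
         cal_noise_cv = cal_noise_cv, seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic truth: %d analytes, noise CV %.1f%%, SD(0.2 VL) %.3g ug/kg, seed %d\n",
    nrow(x$analytes), 100 * x$noise_cv, x$sd_02vl, x$seed))
  invisible(x)
}

#' True recovery surfaces evaluated at a coded point
#'
#' @param truth A [synthetic_truth()].
#' @param point Coded 3-vector.
#' @return Named vector of true recoveries (%), clipped at zero.
#' @export
truth_recovery <- function(truth, point) {
  a <- truth$analytes
  x <- as.numeric(point)
  stopifnot(length(x) == 3L)
  rec <- a$baseline +
    a$lin_A * x[1] + a$lin_B * x[2] + a$lin_C * x[3] +
    a$int_AB * x[1] * x[2] + a$int_AC * x[1] * x[3] + a$int_BC * x[2] * x[3] +
    a$quad_A * x[1]^2 + a$quad_B * x[2]^2 + a$quad_C * x[3]^2
  stats::setNames(pmax(rec, 0), a$analyte)
}

#' Simulate a spiked-recovery experiment across a design
#'
#' For every design run, every analyte's true recovery is its surface value
#' at the run's coded point; each replicate measurement is
#' `spike * recovery/100 * (1 + N(0, CV))`. The output is long-format
#' recovery data ready for [compliant_count()] run by run, giving the
#' response vector a response-surface fit consumes.
#'
#' @param truth A [synthetic_truth()].
#' @param design A [bbd_design()].
#' @param n_replicates Replicates per run (default 3, a triplicate
#'   validation run).
#' @param spike Spike level in ug/kg (default 50, the validation level).
#' @param matrix Matrix label for the records.
#' @param seed Seed (defaults to the truth's seed).
#' @return Data frame: `run_id`, `analyte`, `matrix`, `spike_level`, `day`,
#'   `replicate`, `measured`.
#' @export
simulate_recovery_experiment <- function(truth, design, n_replicates = 3L,
                                         spike = 50, matrix = "bacon",
                                         seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  pts <- coded_matrix(design)
  n_a <- nrow(truth$analytes)
  out <- with_seed(seed, {
    rows <- vector("list", nrow(pts))
    for (r in seq_len(nrow(pts))) {
      rec <- truth_recovery(truth, pts[r, ])
      eps <- stats::rnorm(n_a * n_replicates, 0, truth$noise_cv)
      rows[[r]] <- data.frame(
        run_id = design$run_id[r],
        analyte = rep(truth$analytes$analyte, times = n_replicates),
        matrix = matrix,
        spike_level = spike,
        day = 1L,
        replicate = rep(seq_len(n_replicates), each = n_a),
        measured = pmax(spike * rep(rec, times = n_replicates) / 100 *
                          (1 + eps), 0),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  out
}

#' Per-run compliant counts from a simulated experiment
#'
#' Convenience wrapper: applies [compliant_count()] within each design run
#' of a simulated record set, returning the response vector in run order.
#'
#' @param records Output of [simulate_recovery_experiment()].
#' @param design The design the records were simulated over.
#' @param rule A [compliance_rule()].
#' @return Integer vector, one count per design run.
#' @export
count_response <- function(records, design, rule = compliance_rule()) {
  vapply(design$run_id, function(id) {
    compliant_count(records[records$run_id == id, , drop = FALSE], rule)
  }, integer(1))
}

orthonormal_basis <- function(M, tol = 1e-8) {
  qrm <- qr(M, tol = tol)
  qr.Q(qrm)[, seq_len(qrm$rank), drop = FALSE]
}

#' Construct a response vector exactly consistent with a reported model
#'
#' Builds a response `y = X beta + e` whose least-squares refit on the
#' design returns exactly the supplied coefficients and whose ANOVA
#' reproduces prescribed residual and pure-error sums of squares. The error
#' `e` is placed orthogonally to the 10-dimensional model space: its
#' component in the center-replicate contrast subspace has squared norm
#' `pure_error_ss`, and its component in the remaining lack-of-fit subspace
#' has squared norm `residual_ss - pure_error_ss`. The direction within
#' each subspace is randomized by `seed`, so different seeds give different
#' response vectors with identical fit and identical ANOVA — the tool used
#' to reconstruct a published experiment from its printed regression
#' equation and ANOVA table when the raw runs were not published.
#'
#' @param model A `quad_surface` (or `rsm_fit`) supplying the coefficients.
#' @param residual_ss Target residual sum of squares (>= `pure_error_ss`).
#' @param pure_error_ss Target pure-error sum of squares (>= 0).
#' @param design A [bbd_design()] with at least 2 center replicates.
#' @param seed Integer seed for the subspace directions.
#' @return Numeric response vector of length `nrow(design)`.
#' @examples
#' surf <- quad_surface(41.80, c(-0.50, -1.50, -2.75),
#'                      c(-0.50, 1.00, 0.00), c(-7.90, -8.40, -2.90))
#' des <- bbd_design(c("A", "B", "C"))
#' y <- construct_consistent_response(surf, 11.3, 2.8, des, seed = 1)
#' fit <- rsm_fit(des, y)
#' all.equal(unname(coef(fit)), unname(coef(surf)))
#' @export
construct_consistent_response <- function(model, residual_ss, pure_error_ss,
                                          design, seed = 1L) {
  if (!(is.finite(residual_ss) && is.finite(pure_error_ss) &&
        pure_error_ss >= 0 && residual_ss >= pure_error_ss)) {
    stop("need 0 <= pure_error_ss <= residual_ss", call. = FALSE)
  }
  X <- rsm_model_matrix(design)
  n <- nrow(X)
  p <- ncol(X)
  center_rows <- which(design$point_type == "center")
  if (length(center_rows) < 2L) {
    stop("design needs at least 2 center replicates", call. = FALSE)
  }
  fitted <- drop(X %*% unname(model$coefficients))
  if (residual_ss == 0) return(fitted)

  qrx <- qr(X)
  Qfull <- qr.Q(qrx, complete = TRUE)
  resid_basis <- Qfull[, (p + 1L):n, drop = FALSE]

  # pure-error subspace: zero-sum contrasts over the center replicates
  # (orthogonal to every model column, which is constant across centers)
  ctr <- stats::contr.helmert(length(center_rows))
  pe_raw <- matrix(0, n, ncol(ctr))
  pe_raw[center_rows, ] <- ctr
  pe_basis <- orthonormal_basis(pe_raw)

  # lack-of-fit subspace: residual space minus the pure-error contrasts
  lof_raw <- resid_basis - pe_basis %*% crossprod(pe_basis, resid_basis)
  lof_basis <- orthonormal_basis(lof_raw)

  lof_ss <- residual_ss - pure_error_ss
  e <- with_seed(seed, {
    out <- numeric(n)
    if (pure_error_ss > 0) {
      z <- stats::rnorm(ncol(pe_basis))
      out <- out + pe_basis %*% (z / sqrt(sum(z^2)) * sqrt(pure_error_ss))
    }
    if (lof_ss > 0) {
      if (ncol(lof_basis) == 0L) {
        stop("infeasible split: no lack-of-fit degrees of freedom", call. = FALSE)
      }
      z <- stats::rnorm(ncol(lof_basis))
      out <- out + lof_basis %*% (z / sqrt(sum(z^2)) * sqrt(lof_ss))
    }
    drop(out)
  })
  fitted + e
}

#' Simulate calibration curves and low-level replicates
#'
#' Generates the quantification assets the validation stage consumes: per
#' analyte, a solvent and a matrix-matched calibration curve with responses
#' `slope * level * (1 + N(0, CV))`, and replicate measured concentrations
#' at the 0.2 x VL spike drawn as `N(0.2 VL, SD)` over a day/replicate
#' grid (default 3 days x 6 replicates).
#'
#' @param truth A [synthetic_truth()].
#' @param levels Calibration levels in ug/L (>= 3 distinct; default spans
#'   0.01-100).
#' @param matrix Matrix label.
#' @param n_days,n_replicates Replicate structure at the 0.2 x VL spike.
#' @param vl Validation level (ug/kg).
#' @param seed Seed (defaults to the truth's seed).
#' @return List with `curves` (columns `analyte`, `matrix_flag`, `level`,
#'   `response`) and `replicates_02vl` (columns `analyte`, `matrix`,
#'   `spike_level`, `day`, `replicate`, `measured`).
#' @export
simulate_quant_assets <- function(truth,
                                  levels = c(0.01, 0.1, 1, 5, 10, 50, 100),
                                  matrix = "bacon", n_days = 3L,
                                  n_replicates = 6L, vl = 50,
                                  seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (length(unique(levels)) < 3L) {
    stop("at least 3 distinct calibration levels are required", call. = FALSE)
  }
  a <- truth$analytes
  n_a <- nrow(a)
  n_l <- length(levels)
  with_seed(seed, {
    mk_curve <- function(slopes, flag) {
      data.frame(
        analyte = rep(a$analyte, each = n_l),
        matrix_flag = flag,
        level = rep(levels, times = n_a),
        response = rep(slopes, each = n_l) * rep(levels, times = n_a) *
          (1 + stats::rnorm(n_a * n_l, 0, truth$cal_noise_cv)),
        stringsAsFactors = FALSE
      )
    }
    curves <- rbind(mk_curve(a$slope_mat, matrix),
                    mk_curve(a$slope_sol, "solvent"))
    reps <- expand.grid(replicate = seq_len(n_replicates),
                        day = seq_len(n_days),
                        analyte = a$analyte,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    reps <- data.frame(
      analyte = reps$analyte, matrix = matrix, spike_level = 0.2 * vl,
      day = reps$day, replicate = reps$replicate,
      measured = pmax(stats::rnorm(nrow(reps), 0.2 * vl, truth$sd_02vl), 0),
      stringsAsFactors = FALSE
    )
    list(curves = curves, replicates_02vl = reps)
  })
}
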