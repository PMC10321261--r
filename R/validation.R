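# internal: tissue_params without the joint ve+vp <= 1 check, used while
# the optimizer explores the box-bounded space
.params_unchecked <- function(values) {
  p <- list(ktrans = NA_real_, ve = NA_real_, vp = NA_real_,
            fp = NA_real_, ps = NA_real_)
  p[names(values)] <- as.numeric(values)
  structure(p, class = "tissue_params")
}

#' Convert an SPGR signal-time curve back to concentration
#'
#' The inverse of [conc_curve_to_signal()]: the baseline signal is the
#' mean of the first `baseline_points` samples, M0 is calibrated from it
#' and the known T1,0 at the B1-corrected flip angle, the SPGR equation is
#' inverted per sample, \eqn{E_1 = (M_0 \sin\alpha - S) / (M_0 \sin\alpha
#' - S \cos\alpha)}, \eqn{R_1 = -\ln E_1 / TR}, and the relaxivity
#' relation gives \eqn{C = (R_1 - R_{1,0}) / r_1}.
#'
#' @param signal Positive signal vector (grey-level units).
#' @param tissue A [tissue_properties()] (T1,0, baseline signal unused —
#'   the baseline is re-estimated from the curve — and B1).
#' @param acq List/[dro_config()] with `tr_ms`, `flip_deg`,
#'   `r1_relaxivity`.
#' @param baseline_points Number of pre-contrast samples (>= 1).
#' @return Concentration vector in mM (baseline mean approximately 0).
#' @export
signal_to_conc <- function(signal, tissue, acq, baseline_points) {
  stopifnot(inherits(tissue, "tissue_properties"), baseline_points >= 1,
            all(signal > 0))
  alpha <- effective_flip_angle(acq$flip_deg, tissue$b1)
  a <- alpha * pi / 180
  s0 <- mean(signal[seq_len(baseline_points)])
  m0 <- m0_from_baseline(s0, tissue$t10_ms, acq$tr_ms, alpha)
  e1 <- (m0 * sin(a) - signal) / (m0 * sin(a) - signal * cos(a))
  bad <- which(!(e1 > 0 & e1 <= 1))
  if (length(bad))
    stop("SPGR inversion failed at sample(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         ": signal at or above saturation", call. = FALSE)
  r1 <- -log(e1) / (acq$tr_ms / 1000)
  (r1 - 1000 / tissue$t10_ms) / acq$r1_relaxivity
}

#' Fit a kinetic model to a concentration-time curve
#'
#' Bounded Levenberg-Marquardt least squares (via minpack.lm) minimizing
#' the sum of squared concentration residuals between the measured curve
#' and [forward_tissue_conc()] over the model's free parameters. Bounds
#' are `[0, 10]` for rate/flow parameters and `[1e-6, 1]` for volume
#' fractions; iteration cap 500, function tolerance 1e-10. Optimizer
#' failure is reported through `converged = FALSE`, never an exception.
#'
#' @param model Model id or spec.
#' @param conc Measured concentration curve (mM) on the dynamic grid.
#' @param aif_plasma Plasma AIF (mM) on the fitter's integration grid.
#' @param config A [dro_config()]; `integration_dt_s` here sets the
#'   fitter's quadrature interval, which may differ from the one used in
#'   generation.
#' @param init A [tissue_params()] of starting values (defaults to
#'   [default_fit_init()]).
#' @return List of class `fit_result`: `params` ([tissue_params()]),
#'   `residual_norm` (mM^2), `converged`, `n_iter`, `message`.
#' @export
fit_kinetic_model <- function(model, conc, aif_plasma, config,
                              init = default_fit_init(model)) {
  model <- kinetic_model(model)
  free <- model$free_params
  start <- vapply(free, function(f) init[[f]], 0)
  if (anyNA(start))
    stop("starting values missing for: ",
         paste(free[is.na(start)], collapse = ", "), call. = FALSE)
  is_frac <- free %in% c("ve", "vp")
  lower <- ifelse(is_frac, 1e-6, 0)
  upper <- ifelse(is_frac, 1, 10)
  resid_fn <- function(par) {
    p <- .params_unchecked(stats::setNames(par, free))
    conc - forward_tissue_conc(model, p, aif_plasma, config)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = pmin(pmax(start, lower), upper),
                       lower = lower, upper = upper, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500L, ftol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(params = .params_unchecked(stats::setNames(start, free)),
                residual_norm = NA_real_, converged = FALSE,
                n_iter = 0L, message = conditionMessage(fit))
  } else {
    out <- list(params = .params_unchecked(stats::setNames(fit$par, free)),
                residual_norm = fit$deviance,
                converged = fit$info %in% 1:4,
                n_iter = fit$niter, message = fit$message)
  }
  structure(out, class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  p <- unlist(x$params)
  p <- p[!is.na(p)]
  cat(sprintf("kinetic fit (%s): %s | SS = %.3e, %d iterations\n",
              if (x$converged) "converged" else "NOT converged",
              paste(sprintf("%s = %.4g", names(p), p), collapse = ", "),
              x$residual_norm, x$n_iter))
  invisible(x)
}

#' Estimate T1 from variable-flip-angle SPGR signals
#'
#' Linearized VFA fit: regression of \eqn{S/\sin\alpha} on
#' \eqn{S/\tan\alpha} (with B1-corrected angles) has slope \eqn{E_1 =
#' e^{-TR/T_1}}, so \eqn{T_1 = -TR / \ln E_1}.
#'
#' @param signals Signal at each flip angle (grey-level units, > 0).
#' @param flips_deg Nominal flip angles (degrees, >= 2 distinct).
#' @param b1 Transmit-field ratio used for angle correction.
#' @param tr_ms Repetition time (ms).
#' @return Estimated T1 in ms.
#' @export
t1_from_vfa <- function(signals, flips_deg, b1, tr_ms) {
  if (length(unique(flips_deg)) < 2L)
    stop("T1 estimation needs at least 2 distinct flip angles",
         call. = FALSE)
  stopifnot(length(signals) == length(flips_deg), all(signals > 0))
  a <- effective_flip_angle(flips_deg, b1) * pi / 180
  y <- signals / sin(a)
  x <- signals / tan(a)
  slope <- stats::coef(stats::lm(y ~ x))[[2L]]
  if (!is.finite(slope) || slope <= 0 || slope >= 1)
    stop("VFA T1 estimation failed: regression slope ",
         format(slope), " outside (0, 1)", call. = FALSE)
  -(tr_ms) / log(slope)
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{CCC = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' with population (1/n) moments, plus a 95% confidence interval from the
#' Fisher z-transformation with Lin's asymptotic variance. CCC combines
#' Pearson correlation with a bias-correction factor `c_b`; it is 1 only
#' for perfect agreement with the identity line.
#'
#' @param x,y Numeric vectors of equal length n >= 3; not both constant.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `ccc_result`: `ccc`, `ci_low`, `ci_high`, `n`,
#'   `pearson_r`, `c_b`.
#' @export
lin_ccc <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            !anyNA(x), !anyNA(y))
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0)
    stop("CCC undefined: both vectors are constant", call. = FALSE)
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else 0
  c_b <- if (r != 0) ccc / r else NA_real_
  if (1 - ccc^2 < 1e-12 || abs(r) < 1e-12 || 1 - r^2 < 0) {
    ci <- c(ccc, ccc)
  } else {
    u <- (mx - my) / (sx2 * sy2)^0.25
    var_z <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
                2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
                ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    var_z <- max(var_z, 0)
    z <- atanh(ccc)
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(z + c(-1, 1) * q * sqrt(var_z))
  }
  structure(list(ccc = ccc, ci_low = min(ci[1L], ccc),
                 ci_high = max(ci[2L], ccc), n = n, pearson_r = r,
                 c_b = c_b),
            class = "ccc_result")
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf("Lin's CCC = %.4f [%.4f, %.4f] (n = %d)\n",
              x$ccc, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' End-to-end DRO round-trip validation
#'
#' Reproduces the self-validation experiment: build the DRO from a
#' parameter grid, optionally push it through DICOM export and re-import,
#' convert one representative voxel per block back to concentration using
#' the known T1,0/B1 maps, fit the kinetic model with the standard
#' starting values, and score fitted against true values with Lin's CCC
#' per free parameter. For the extended Tofts model, blocks with a true
#' Ktrans of 0 (a largely non-physical case with poor convergence) are
#' excluded from the CCC.
#'
#' @param model_id Kinetic model identifier.
#' @param grid A `parameter_grid`; default the packaged grid for the
#'   model.
#' @param aif Blood [aif_curve()] or `NULL` for the synthetic population
#'   AIF.
#' @param config A [dro_config()] used for generation.
#' @param init Starting values ([tissue_params()]).
#' @param fit_integration_dt_s Quadrature interval the fitter assumes;
#'   defaults to the generation value (`config$integration_dt_s`), but
#'   can be set independently to study matched vs mismatched integration.
#' @param via_dicom If `TRUE`, the volume is exported to and re-read from
#'   DICOM (in `dicom_dir`) before inversion, exercising the full file
#'   round trip.
#' @param dicom_dir Directory for the DICOM round trip.
#' @param exclude_zero_ktrans Exclude blocks with true `ktrans == 0` from
#'   the CCC (default: only for the extended Tofts model).
#' @return Data frame with one row per free parameter: `parameter`,
#'   `ccc`, `ci_low`, `ci_high`, `n`; attributes `fits` (list of
#'   `fit_result`) and `truth`/`fitted` matrices.
#' @export
round_trip_validate <- function(model_id,
                                grid = default_parameter_grid(model_id),
                                aif = NULL,
                                config = dro_config(),
                                init = default_fit_init(model_id),
                                fit_integration_dt_s =
                                  config$integration_dt_s,
                                via_dicom = FALSE,
                                dicom_dir = file.path(tempdir(),
                                                      "dcedro_rt"),
                                exclude_zero_ktrans = NULL) {
  model <- kinetic_model(model_id)
  if (is.null(exclude_zero_ktrans))
    exclude_zero_ktrans <- model$model_id == "etofts"
  vol <- build_dro(grid, aif, config)

  if (via_dicom) {
    write_dro_dicom(vol, dicom_dir)
    back <- read_dro_dicom(dicom_dir)
    signal4d <- back$signal
    lab <- back$label_map
  } else {
    signal4d <- vol$signal
    lab <- vol$label_map
  }

  # plasma AIF on the fitter's integration grid, same bolus placement
  delay <- config$baseline_points * config$dt_s + config$tissue_delay_s
  duration <- (config$n_timepoints - 1L) * config$dt_s
  if (is.null(aif)) {
    n_aif <- ceiling(duration / config$integration_dt_s) + 1L
    aif <- synthetic_population_aif(config$integration_dt_s, n_aif)
  }
  fit_config <- config
  fit_config$integration_dt_s <- fit_integration_dt_s
  stride_fit <- as.integer(round(config$dt_s / fit_integration_dt_s))
  n_int_fit <- (config$n_timepoints - 1L) * stride_fit + 1L
  cp_fit <- resample_aif(blood_to_plasma(aif, config$hematocrit),
                         fit_integration_dt_s, n_int_fit, delay)

  n_blocks <- length(grid$rows)
  free <- model$free_params
  truth <- matrix(NA_real_, n_blocks, length(free),
                  dimnames = list(NULL, free))
  fitted <- truth
  fits <- vector("list", n_blocks)
  for (i in seq_len(n_blocks)) {
    vox <- which(lab == i, arr.ind = TRUE)[1L, ]
    sig <- signal4d[, 1L, vox[1L], vox[2L]]
    row <- grid$rows[[i]]
    tissue <- tissue_properties(row$t10_ms, row$s0, row$b1)
    conc <- signal_to_conc(sig, tissue, config, config$baseline_points)
    fit <- fit_kinetic_model(model, conc, cp_fit, fit_config, init)
    fits[[i]] <- fit
    for (f in free) {
      truth[i, f] <- row$params[[f]]
      fitted[i, f] <- fit$params[[f]]
    }
  }

  keep <- rep(TRUE, n_blocks)
  if (exclude_zero_ktrans && "ktrans" %in% free)
    keep <- truth[, "ktrans"] > 0
  res <- lapply(free, function(f) {
    cc <- lin_ccc(truth[keep, f], fitted[keep, f])
    data.frame(parameter = f, ccc = cc$ccc, ci_low = cc$ci_low,
               ci_high = cc$ci_high, n = cc$n)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "truth") <- truth
  attr(out, "fitted") <- fitted
  attr(out, "model_id") <- model$model_id
  out
}
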