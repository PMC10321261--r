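#' Per-voxel kinetic parameters
#'
#' Container for the kinetic indices of one simulated tissue. Which fields
#' must be present depends on the model: Patlak uses `ktrans` and `vp`;
#' Tofts `ktrans` and `ve`; extended Tofts `ktrans`, `ve` and `vp`; the
#' tissue-uptake model `fp`, `ps` and `vp`; the two-compartment exchange
#' model (2CXM) `fp`, `ps`, `ve` and `vp`.
#'
#' @param ktrans Volume transfer constant, min^-1.
#' @param ve Extravascular-extracellular volume fraction (dimensionless).
#' @param vp Plasma volume fraction (dimensionless).
#' @param fp Plasma flow, ml min^-1 ml^-1.
#' @param ps Permeability-surface-area product, min^-1.
#' @return An object of class `tissue_params` (named list; absent fields
#'   are `NA`).
#' @export
tissue_params <- function(ktrans = NA_real_, ve = NA_real_, vp = NA_real_,
                          fp = NA_real_, ps = NA_real_) {
  p <- list(ktrans = as.numeric(ktrans), ve = as.numeric(ve),
            vp = as.numeric(vp), fp = as.numeric(fp), ps = as.numeric(ps))
  for (nm in names(p)) {
    v <- p[[nm]]
    if (length(v) != 1L) stop("tissue_params fields must be scalars",
                              call. = FALSE)
    if (!is.na(v) && v < 0)
      stop("tissue parameter ", nm, " must be >= 0", call. = FALSE)
  }
  if (!is.na(p$ve) && p$ve > 1) stop("ve must be <= 1", call. = FALSE)
  if (!is.na(p$vp) && p$vp > 1) stop("vp must be <= 1", call. = FALSE)
  if (!is.na(p$ve) && !is.na(p$vp) && p$ve + p$vp > 1)
    stop("ve + vp must be <= 1", call. = FALSE)
  structure(p, class = "tissue_params")
}

# Registry of kinetic models. Each entry is a list:
#   model_id       identifier string
#   vascular_term  logical: add vp * Cp(t) outside the convolution?
#   free_params    character vector of fitted/required tissue_params fields
#   impulse        function(t_s, params) -> I(t) in min^-1 on a grid in s
#   validate       function(params) -> invisible(TRUE) or error
.model_registry <- new.env(parent = emptyenv())

#' Register a kinetic model plug-in
#'
#' User models follow the same contract as the built-ins: an impulse
#' response (residue function scaled by flow/transfer, units min^-1)
#' evaluated on a time grid in seconds, a flag saying whether the vascular
#' term `vp * Cp(t)` is added outside the convolution, and the set of free
#' parameters.
#'
#' @param model_id Name under which the model is registered.
#' @param impulse_response `function(t_s, params)` returning the impulse
#'   response in min^-1; must be finite at `t = 0` and non-negative.
#' @param vascular_term Logical; add `vp * Cp(t)` to the convolved curve.
#' @param free_params Character vector of `tissue_params` fields the model
#'   uses (and the fitter optimizes).
#' @param validate Optional `function(params)` raising an error on
#'   degenerate parameter combinations.
#' @return The model spec, invisibly.
#' @export
register_kinetic_model <- function(model_id, impulse_response,
                                   vascular_term, free_params,
                                   validate = NULL) {
  stopifnot(is.character(model_id), length(model_id) == 1L,
            is.function(impulse_response), is.logical(vascular_term),
            is.character(free_params))
  spec <- structure(
    list(model_id = model_id, vascular_term = vascular_term,
         free_params = free_params, impulse = impulse_response,
         validate = if (is.null(validate)) function(params) invisible(TRUE)
                    else validate),
    class = "kinetic_model")
  assign(model_id, spec, envir = .model_registry)
  invisible(spec)
}

#' Look up a kinetic model by name
#'
#' @param model_id One of `list_kinetic_models()` (built-ins: `"patlak"`,
#'   `"tofts"`, `"etofts"`, `"uptake"`, `"2cxm"`) or a registered plug-in.
#' @return The model spec (class `kinetic_model`).
#' @export
kinetic_model <- function(model_id) {
  if (inherits(model_id, "kinetic_model")) return(model_id)
  if (!exists(model_id, envir = .model_registry))
    stop("unknown kinetic model: ", model_id, " (available: ",
         paste(list_kinetic_models(), collapse = ", "), ")", call. = FALSE)
  get(model_id, envir = .model_registry)
}

#' @rdname kinetic_model
#' @export
list_kinetic_models <- function() sort(ls(envir = .model_registry))

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("kinetic model '%s': free parameters {%s}%s\n", x$model_id,
              paste(x$free_params, collapse = ", "),
              if (x$vascular_term) " + vascular term vp*Cp(t)" else ""))
  invisible(x)
}

.require_params <- function(params, fields, model_id) {
  for (f in fields)
    if (is.na(params[[f]]))
      stop("model '", model_id, "' requires parameter ", f, call. = FALSE)
}

# Built-in residue functions. All rates are user-facing in min^-1; the
# exponent arithmetic converts once to s^-1 (factor 1/60) because time
# grids are in seconds.
.register_builtin_models <- function() {
  register_kinetic_model(
    "tofts",
    impulse_response = function(t_s, params) {
      if (params$ktrans == 0) return(numeric(length(t_s)))
      kep_per_s <- params$ktrans / params$ve / 60
      params$ktrans * exp(-kep_per_s * t_s)
    },
    vascular_term = FALSE,
    free_params = c("ktrans", "ve"),
    validate = function(params) {
      .require_params(params, c("ktrans", "ve"), "tofts")
      if (params$ve == 0 && params$ktrans > 0)
        stop("degenerate Tofts parameters: ve = 0 with ktrans > 0 ",
             "(kep undefined)", call. = FALSE)
      invisible(TRUE)
    })

  register_kinetic_model(
    "etofts",
    impulse_response = function(t_s, params) {
      if (params$ktrans == 0) return(numeric(length(t_s)))
      kep_per_s <- params$ktrans / params$ve / 60
      params$ktrans * exp(-kep_per_s * t_s)
    },
    vascular_term = TRUE,
    free_params = c("ktrans", "ve", "vp"),
    validate = function(params) {
      .require_params(params, c("ktrans", "ve", "vp"), "etofts")
      if (params$ve == 0 && params$ktrans > 0)
        stop("degenerate extended-Tofts parameters: ve = 0 with ktrans > 0",
             call. = FALSE)
      invisible(TRUE)
    })

  register_kinetic_model(
    "patlak",
    impulse_response = function(t_s, params) rep(params$ktrans, length(t_s)),
    vascular_term = TRUE,
    free_params = c("ktrans", "vp"),
    validate = function(params) {
      .require_params(params, c("ktrans", "vp"), "patlak")
      invisible(TRUE)
    })

  register_kinetic_model(
    "uptake",
    impulse_response = function(t_s, params) {
      E <- params$ps / (params$ps + params$fp)      # extraction fraction
      tp_s <- params$vp / (params$ps + params$fp) * 60
      params$fp * (E + (1 - E) * exp(-t_s / tp_s))
    },
    vascular_term = FALSE,
    free_params = c("fp", "ps", "vp"),
    validate = function(params) {
      .require_params(params, c("fp", "ps", "vp"), "uptake")
      if (params$vp == 0)
        stop("degenerate tissue-uptake parameters: vp = 0", call. = FALSE)
      if (params$fp == 0 && params$ps == 0)
        stop("degenerate tissue-uptake parameters: fp = ps = 0",
             call. = FALSE)
      invisible(TRUE)
    })

  register_kinetic_model(
    "2cxm",
    impulse_response = function(t_s, params) {
      fp <- params$fp; ps <- params$ps; ve <- params$ve; vp <- params$vp
      s <- (fp + ps) / vp + ps / ve                 # min^-1
      disc <- s^2 - 4 * fp * ps / (vp * ve)
      d <- sqrt(max(disc, 0))
      k_pos <- (s + d) / 2
      k_neg <- (s - d) / 2
      if (k_pos == k_neg) {                         # repeated eigenvalue
        return(fp * exp(-k_pos / 60 * t_s))
      }
      a <- (k_pos - ps / ve - ps / vp) / (k_pos - k_neg)
      fp * (a * exp(-k_pos / 60 * t_s) + (1 - a) * exp(-k_neg / 60 * t_s))
    },
    vascular_term = FALSE,
    free_params = c("fp", "ps", "ve", "vp"),
    validate = function(params) {
      .require_params(params, c("fp", "ps", "ve", "vp"), "2cxm")
      if (params$vp == 0)
        stop("degenerate 2CXM parameters: vp = 0", call. = FALSE)
      if (params$ve == 0)
        stop("degenerate 2CXM parameters: ve = 0", call. = FALSE)
      invisible(TRUE)
    })
}

#' Evaluate a model's impulse response on a time grid
#'
#' Returns the residue function scaled by the transfer/flow constant
#' (units min^-1): Tofts/extended Tofts \eqn{K^{trans} e^{-k_{ep} t}};
#' Patlak a constant \eqn{K^{trans}}; tissue uptake \eqn{F_p [E + (1 - E)
#' e^{-t/T_p}]} with \eqn{E = PS/(PS + F_p)}, \eqn{T_p = v_p/(PS + F_p)};
#' 2CXM the biexponential eigen-decomposition of the two-compartment
#' system. Time is in seconds; rate parameters in min^-1 are converted
#' internally.
#'
#' @param model A model id or `kinetic_model` spec.
#' @param params A [tissue_params()] valid for the model.
#' @param t_grid_s Uniform time grid in seconds starting at 0.
#' @return Numeric vector, impulse response in min^-1.
#' @export
impulse_response <- function(model, params, t_grid_s) {
  model <- kinetic_model(model)
  stopifnot(inherits(params, "tissue_params"))
  model$validate(params)
  out <- model$impulse(t_grid_s, params)
  stopifnot(length(out) == length(t_grid_s))
  out
}

#' Trapezoidal convolution of impulse response and plasma AIF
#'
#' Computes the causal convolution \eqn{c(t_k) = \int_0^{t_k} I(t_k - \tau)
#' C_p(\tau) d\tau} by trapezoidal quadrature on a uniform grid. `impulse`
#' is in min^-1 and the grid spacing in seconds, so the quadrature carries
#' a 1/60 unit conversion; the result is in mM. The full discrete
#' convolution is evaluated by FFT and the trapezoidal end-point
#' half-weights applied as a boundary correction.
#'
#' @param impulse Impulse response samples (min^-1).
#' @param cp Plasma concentration samples (mM), same length.
#' @param dt_s Grid spacing (s).
#' @return Numeric vector of tissue concentrations (mM); element 1 is 0.
#' @export
convolve_trapezoid <- function(impulse, cp, dt_s) {
  n <- length(impulse)
  if (length(cp) != n)
    stop("impulse and cp must have equal length", call. = FALSE)
  stopifnot(dt_s > 0)
  if (n == 1L) return(0)
  full <- stats::convolve(impulse, rev(cp), type = "open")[seq_len(n)]
  c_mM <- (dt_s / 60) * (full - 0.5 * (impulse[1L] * cp + cp[1L] * impulse))
  c_mM[1L] <- 0
  c_mM
}

#' Forward kinetic model: parameters to tissue concentration curve
#'
#' Runs the convolution on the fine integration grid (spacing
#' `config$integration_dt_s`), adds the vascular term `vp * Cp(t)` for
#' models that carry one, and downsamples to the dynamic grid (spacing
#' `config$dt_s`) by taking the coinciding sample (point-sampled
#' acquisition, no averaging).
#'
#' @param model Model id or `kinetic_model` spec.
#' @param params A [tissue_params()] valid for the model.
#' @param aif_plasma Plasma concentration (mM) sampled on the integration
#'   grid; must cover `(n_timepoints - 1) * dt_s`.
#' @param config A [dro_config()] (fields `dt_s`, `n_timepoints`,
#'   `integration_dt_s` are used).
#' @return Tissue concentration (mM) at the `config$n_timepoints` dynamic
#'   sample times.
#' @export
forward_tissue_conc <- function(model, params, aif_plasma, config) {
  model <- kinetic_model(model)
  stride <- config$dt_s / config$integration_dt_s
  if (abs(stride - round(stride)) > 1e-9)
    stop("integration_dt_s must divide dt_s evenly", call. = FALSE)
  stride <- as.integer(round(stride))
  n_int <- (config$n_timepoints - 1L) * stride + 1L
  if (length(aif_plasma) < n_int)
    stop("integration grid too short: need ", n_int, " AIF samples, have ",
         length(aif_plasma), call. = FALSE)
  aif_plasma <- aif_plasma[seq_len(n_int)]
  t_int <- (seq_len(n_int) - 1) * config$integration_dt_s
  imp <- impulse_response(model, params, t_int)
  c_int <- convolve_trapezoid(imp, aif_plasma, config$integration_dt_s)
  if (model$vascular_term)
    c_int <- c_int + params$vp * aif_plasma
  c_int[seq(1L, n_int, by = stride)]
}
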