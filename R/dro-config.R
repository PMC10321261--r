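#' DRO generation configuration
#'
#' Acquisition and simulation settings for one digital reference object.
#' Defaults reproduce the sample-DRO configuration: 0.5 s time resolution,
#' 650 dynamic timepoints, 25 degree flip angle, hematocrit 0.45, 10
#' baseline points, zero tissue delay, plasma relaxivity 4.5 mM^-1 s^-1,
#' TR 5 ms, 1 mm pixels, 10 mm slices, 10-pixel blocks and a blood T1,0 of
#' 1664 ms, with the numerical integration interval equal to the dynamic
#' time resolution.
#'
#' @param dt_s Dynamic series time resolution (s).
#' @param n_timepoints Number of dynamic timepoints.
#' @param flip_deg Dynamic series excitation flip angle (degrees).
#' @param hematocrit Estimated hematocrit fraction.
#' @param baseline_points Number of pre-contrast frames; the bolus is
#'   placed so that exactly this many baseline frames precede enhancement.
#' @param tissue_delay_s Additional delay of the tissue AIF (s).
#' @param gd_dose_mmol_per_kg Contrast dose; metadata only (recorded in
#'   the output manifest, never used to scale the AIF).
#' @param r1_relaxivity Plasma longitudinal relaxivity (mM^-1 s^-1).
#' @param tr_ms Repetition time (ms).
#' @param te_ms Echo time (ms); header metadata only, no T2* modelling.
#' @param pixel_mm In-plane pixel dimension (mm).
#' @param slice_thickness_mm Slice thickness (mm).
#' @param pixels_per_block Side length of one homogeneous tissue block.
#' @param blood_t10_ms Baseline T1 of blood (ms), used for the in-image
#'   AIF region.
#' @param integration_dt_s Time interval of the trapezoidal integration
#'   grid (s); must divide `dt_s` evenly.
#' @param n_slices Number of (replicated) slices.
#' @param vfa_flips_deg Variable flip angles for the T1-mapping source
#'   images (degrees).
#' @param default_s0 Baseline signal assigned to grid rows lacking an S0
#'   column, and to the AIF region.
#' @param noise_sigma Gaussian noise standard deviation in grey-level
#'   units (0 disables noise).
#' @param seed Integer seed for noise and DICOM identifier generation.
#' @return Object of class `dro_config` (named list).
#' @export
dro_config <- function(dt_s = 0.5,
                       n_timepoints = 650L,
                       flip_deg = 25,
                       hematocrit = 0.45,
                       baseline_points = 10L,
                       tissue_delay_s = 0,
                       gd_dose_mmol_per_kg = 0.1,
                       r1_relaxivity = 4.5,
                       tr_ms = 5,
                       te_ms = 1.5,
                       pixel_mm = 1,
                       slice_thickness_mm = 10,
                       pixels_per_block = 10L,
                       blood_t10_ms = 1664,
                       integration_dt_s = dt_s,
                       n_slices = 1L,
                       vfa_flips_deg = c(2, 5, 10, 15),
                       default_s0 = 50,
                       noise_sigma = 0,
                       seed = 20230525L) {
  cfg <- list(dt_s = dt_s, n_timepoints = as.integer(n_timepoints),
              flip_deg = flip_deg, hematocrit = hematocrit,
              baseline_points = as.integer(baseline_points),
              tissue_delay_s = tissue_delay_s,
              gd_dose_mmol_per_kg = gd_dose_mmol_per_kg,
              r1_relaxivity = r1_relaxivity, tr_ms = tr_ms, te_ms = te_ms,
              pixel_mm = pixel_mm,
              slice_thickness_mm = slice_thickness_mm,
              pixels_per_block = as.integer(pixels_per_block),
              blood_t10_ms = blood_t10_ms,
              integration_dt_s = integration_dt_s,
              n_slices = as.integer(n_slices),
              vfa_flips_deg = vfa_flips_deg, default_s0 = default_s0,
              noise_sigma = noise_sigma, seed = as.integer(seed))
  stopifnot(cfg$dt_s > 0, cfg$integration_dt_s > 0,
            cfg$n_timepoints >= 1L, cfg$baseline_points >= 0L,
            cfg$n_timepoints >= cfg$baseline_points,
            cfg$pixels_per_block >= 1L, cfg$n_slices >= 1L,
            cfg$hematocrit >= 0, cfg$hematocrit < 1,
            cfg$tr_ms > 0, cfg$flip_deg > 0, cfg$flip_deg < 180,
            cfg$r1_relaxivity > 0, cfg$blood_t10_ms > 0,
            cfg$noise_sigma >= 0)
  stride <- cfg$dt_s / cfg$integration_dt_s
  if (abs(stride - round(stride)) > 1e-9)
    stop("integration_dt_s must divide dt_s evenly", call. = FALSE)
  structure(cfg, class = "dro_config")
}

#' @export
print.dro_config <- function(x, ...) {
  cat(sprintf(paste0("DRO config: %d timepoints @ %g s (integration dt %g s), ",
                     "flip %g deg, TR %g ms, Hct %g, %d baseline points\n"),
              x$n_timepoints, x$dt_s, x$integration_dt_s, x$flip_deg,
              x$tr_ms, x$hematocrit, x$baseline_points))
  invisible(x)
}

#' Build a config from a YAML or key=value file
#'
#' Keys mirror the argument names of [dro_config()]; unknown keys are an
#' error. Files ending in `.yaml`/`.yml` are parsed with the yaml package,
#' anything else as flat `key = value` lines.
#'
#' @param path Configuration file path.
#' @return A [dro_config()].
#' @export
dro_config_from_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs",
           call. = FALSE)
    vals <- yaml::read_yaml(path)
  } else {
    lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE,
                  invert = TRUE)
    kv <- strsplit(lines, "=", fixed = TRUE)
    vals <- lapply(kv, function(x) {
      v <- strsplit(trimws(x[2L]), ",", fixed = TRUE)[[1L]]
      num <- suppressWarnings(as.numeric(v))
      if (anyNA(num)) trimws(v) else num
    })
    names(vals) <- vapply(kv, function(x) trimws(x[1L]), "")
  }
  unknown <- setdiff(names(vals), names(formals(dro_config)))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(dro_config, vals)
}

.grid_kinetic_cols <- c(Ktrans = "ktrans", ve = "ve", vp = "vp",
                        Fp = "fp", PS = "ps")

#' Read a parameter-grid CSV
#'
#' One row per simulated tissue block. The header names columns from
#' `{Ktrans, ve, vp, Fp, PS, T10, B1, S0}`; the kinetic columns required
#' by `model_id` must be present, `T10` is always required, a missing `B1`
#' column defaults to 1 and a missing `S0` column to `default_s0`.
#'
#' @param path CSV path.
#' @param model_id Kinetic model the grid targets.
#' @param default_s0 Baseline signal used when the CSV has no `S0` column.
#' @return Object of class `parameter_grid`: list with `rows` (list of
#'   per-block lists `params` ([tissue_params()]), `t10_ms`, `b1`, `s0`)
#'   and `model_id`.
#' @export
read_parameter_grid <- function(path, model_id, default_s0 = 50) {
  if (!file.exists(path)) stop("grid file not found: ", path, call. = FALSE)
  model <- kinetic_model(model_id)
  tab <- utils::read.csv(path, check.names = FALSE)
  parameter_grid(tab, model_id, default_s0 = default_s0)
}

#' Build a parameter grid from a data frame
#'
#' @param tab Data frame with the columns described in
#'   [read_parameter_grid()].
#' @param model_id Kinetic model the grid targets.
#' @param default_s0 Baseline signal for rows lacking `S0`.
#' @return A `parameter_grid`.
#' @export
parameter_grid <- function(tab, model_id, default_s0 = 50) {
  model <- kinetic_model(model_id)
  need <- names(.grid_kinetic_cols)[.grid_kinetic_cols %in%
                                      model$free_params]
  missing_cols <- setdiff(c(need, "T10"), names(tab))
  if (length(missing_cols))
    stop("parameter grid is missing required column(s) for model '",
         model$model_id, "': ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) < 1L) stop("parameter grid has no rows", call. = FALSE)
  for (cn in intersect(c(need, "T10", "B1", "S0"), names(tab)))
    if (!is.numeric(tab[[cn]]))
      stop("non-numeric values in grid column ", cn, call. = FALSE)
  if (!"B1" %in% names(tab)) tab$B1 <- 1
  if (!"S0" %in% names(tab)) tab$S0 <- default_s0
  if (any(tab$T10 <= 0)) stop("T10 must be > 0", call. = FALSE)
  if (any(tab$B1 <= 0)) stop("B1 must be > 0", call. = FALSE)
  if (any(tab$S0 <= 0)) stop("S0 must be > 0", call. = FALSE)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    args <- list()
    for (cn in need) args[[.grid_kinetic_cols[[cn]]]] <- tab[[cn]][i]
    p <- do.call(tissue_params, args)
    model$validate(p)
    list(params = p, t10_ms = tab$T10[i], b1 = tab$B1[i], s0 = tab$S0[i])
  })
  structure(list(rows = rows, model_id = model$model_id),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("parameter grid for model '%s': %d tissue blocks\n",
              x$model_id, length(x$rows)))
  invisible(x)
}

#' Packaged default parameter grid for a model
#'
#' Loads the grid CSV shipped with the package for one of the five
#' built-in models. The grids cross kinetic parameter values typical of
#' tumor studies (e.g. Ktrans 0.01-0.35 min^-1 against ve 0.01-0.5 for
#' the Tofts model) with a spread of baseline T1 and B1 values; the
#' extended Tofts grid includes Ktrans = 0 rows, a largely non-physical
#' case used to exercise a validator's exclusion handling.
#'
#' @param model_id One of `"patlak"`, `"tofts"`, `"etofts"`, `"uptake"`,
#'   `"2cxm"`.
#' @param default_s0 Baseline signal level.
#' @return A `parameter_grid`.
#' @export
default_parameter_grid <- function(model_id, default_s0 = 50) {
  path <- system.file("extdata", paste0("grid_", model_id, ".csv"),
                      package = "dcedro")
  if (path == "")
    stop("no packaged default grid for model '", model_id, "'",
         call. = FALSE)
  read_parameter_grid(path, model_id, default_s0 = default_s0)
}

#' Default fit starting values per model
#'
#' The initial parameter values conventionally handed to the kinetic
#' optimizer: Patlak (Ktrans 0.1, vp 0.02); Tofts (Ktrans 0.1, ve 0.25);
#' extended Tofts (Ktrans 0.1, ve 0.25, vp 0.02); tissue uptake (Fp 0.5,
#' PS 0.125, vp 0.05); 2CXM (Fp 0.5, PS 0.125, ve 0.25, vp 0.05).
#'
#' @param model_id Model identifier.
#' @return A [tissue_params()] with the model's free parameters set.
#' @export
default_fit_init <- function(model_id) {
  model <- kinetic_model(model_id)
  switch(model$model_id,
         patlak = tissue_params(ktrans = 0.1, vp = 0.02),
         tofts  = tissue_params(ktrans = 0.1, ve = 0.25),
         etofts = tissue_params(ktrans = 0.1, ve = 0.25, vp = 0.02),
         uptake = tissue_params(fp = 0.5, ps = 0.125, vp = 0.05),
         `2cxm` = tissue_params(fp = 0.5, ps = 0.125, ve = 0.25,
                                vp = 0.05),
         stop("no default starting values for model '", model$model_id,
              "'; pass init explicitly", call. = FALSE))
}
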