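#' Lay out tissue blocks and the AIF strip on the image plane
#'
#' Each grid row occupies one `pixels_per_block` x `pixels_per_block`
#' square. Blocks tile row-major into a near-square arrangement
#' (`ceiling(sqrt(n))` block columns); a dedicated arterial-input strip
#' one block tall spans the full width at the bottom of the image. Labels:
#' `-1` background (unused block slots), `-2` AIF strip, otherwise the
#' 1-based grid-row index.
#'
#' @param grid A `parameter_grid` (or its row count).
#' @param config A [dro_config()].
#' @return Integer matrix label map (rows x cols, row 1 at image top).
#' @export
layout_blocks <- function(grid, config) {
  n <- if (inherits(grid, "parameter_grid")) length(grid$rows)
       else as.integer(grid)
  stopifnot(n >= 1L)
  ppb <- config$pixels_per_block
  ncol_b <- ceiling(sqrt(n))
  nrow_b <- ceiling(n / ncol_b)
  lab <- matrix(-1L, nrow = (nrow_b + 1L) * ppb, ncol = ncol_b * ppb)
  for (i in seq_len(n)) {
    br <- (i - 1L) %/% ncol_b
    bc <- (i - 1L) %% ncol_b
    lab[br * ppb + seq_len(ppb), bc * ppb + seq_len(ppb)] <- i
  }
  lab[nrow_b * ppb + seq_len(ppb), ] <- -2L
  lab
}

#' Build a digital reference object
#'
#' Runs the full forward pipeline for every tissue block: the blood AIF is
#' converted to plasma concentration via the hematocrit, resampled onto
#' the fine integration grid with the bolus placed at `baseline_points *
#' dt_s + tissue_delay_s` (so exactly `baseline_points` pre-contrast
#' frames exist), pushed through the kinetic model, converted to an SPGR
#' signal curve with the block's T1,0 / B1 / baseline signal, and written
#' into every voxel of the block. Voxels of the AIF strip carry the blood
#' concentration curve rendered with the blood T1,0. Ground-truth maps
#' (kinetic parameters, `t10_ms`, `r10_per_s`, `b1`, `s0`) and the
#' pre-contrast variable-flip-angle stack are populated alongside, and
#' the whole plane is replicated across `n_slices`.
#'
#' The AIF's native time origin is taken as bolus onset; its sampled
#' support (plus the bolus delay) must cover the dynamic duration.
#'
#' @param grid A `parameter_grid`.
#' @param aif An [aif_curve()] (blood compartment), or `NULL` to use
#'   [synthetic_population_aif()] over the required duration.
#' @param config A [dro_config()].
#' @return Object of class `dro_volume`: list with `signal` (4D array
#'   `[time, slice, row, col]`), `label_map`, `truth_maps` (named list of
#'   matrices), `vfa_stack`, `block_curves` (per block: `conc_mM`,
#'   `signal`), `aif_blood_dyn`, `config`, `model_id`.
#' @export
build_dro <- function(grid, aif = NULL, config = dro_config()) {
  stopifnot(inherits(grid, "parameter_grid"), inherits(config, "dro_config"))
  model <- kinetic_model(grid$model_id)
  delay <- config$baseline_points * config$dt_s + config$tissue_delay_s
  duration <- (config$n_timepoints - 1L) * config$dt_s
  if (is.null(aif)) {
    n_aif <- ceiling(duration / config$integration_dt_s) + 1L
    aif <- synthetic_population_aif(config$integration_dt_s, n_aif)
  }
  stopifnot(inherits(aif, "aif_curve"))
  if (aif$compartment != "blood")
    stop("build_dro expects a blood-compartment AIF", call. = FALSE)
  if (max(aif$time_s) + delay < duration)
    stop("AIF coverage error: curve ends ", max(aif$time_s),
         " s after bolus onset but the dynamic series needs ",
         duration - delay, " s", call. = FALSE)

  stride <- as.integer(round(config$dt_s / config$integration_dt_s))
  n_int <- (config$n_timepoints - 1L) * stride + 1L
  plasma <- blood_to_plasma(aif, config$hematocrit)
  cp_int <- resample_aif(plasma, config$integration_dt_s, n_int, delay)
  cb_dyn <- resample_aif(aif, config$dt_s, config$n_timepoints, delay)

  lab <- layout_blocks(grid, config)
  nr <- nrow(lab); nc <- ncol(lab)
  n_blocks <- length(grid$rows)

  block_curves <- vector("list", n_blocks)
  for (i in seq_len(n_blocks)) {
    row <- grid$rows[[i]]
    conc <- forward_tissue_conc(model, row$params, cp_int, config)
    tissue <- tissue_properties(row$t10_ms, row$s0, row$b1)
    sig <- conc_curve_to_signal(conc, tissue, config)
    block_curves[[i]] <- list(conc_mM = conc, signal = sig)
  }
  aif_tissue <- tissue_properties(config$blood_t10_ms, config$default_s0, 1)
  aif_signal <- conc_curve_to_signal(cb_dyn, aif_tissue, config)

  # truth maps
  param_fields <- model$free_params
  truth <- list()
  for (f in c(param_fields, "t10_ms", "r10_per_s", "b1", "s0"))
    truth[[f]] <- matrix(NA_real_, nr, nc)
  for (i in seq_len(n_blocks)) {
    idx <- lab == i
    row <- grid$rows[[i]]
    for (f in param_fields) truth[[f]][idx] <- row$params[[f]]
    truth$t10_ms[idx] <- row$t10_ms
    truth$r10_per_s[idx] <- 1000 / row$t10_ms
    truth$b1[idx] <- row$b1
    truth$s0[idx] <- row$s0
  }
  aif_idx <- lab == -2L
  truth$t10_ms[aif_idx] <- config$blood_t10_ms
  truth$r10_per_s[aif_idx] <- 1000 / config$blood_t10_ms
  truth$b1[aif_idx] <- 1
  truth$s0[aif_idx] <- config$default_s0

  # 4D signal array [time, slice, row, col]; background voxels stay 0
  plane <- matrix(0, config$n_timepoints, nr * nc)
  flat_lab <- as.vector(lab)
  for (i in seq_len(n_blocks))
    plane[, flat_lab == i] <- block_curves[[i]]$signal
  plane[, flat_lab == -2L] <- aif_signal
  signal <- array(0, dim = c(config$n_timepoints, config$n_slices, nr, nc))
  for (s in seq_len(config$n_slices))
    signal[, s, , ] <- plane

  vfa_t10 <- truth$t10_ms; vfa_t10[is.na(vfa_t10)] <- config$blood_t10_ms
  vfa_s0 <- truth$s0; vfa_s0[is.na(vfa_s0)] <- config$default_s0
  vfa_b1 <- truth$b1; vfa_b1[is.na(vfa_b1)] <- 1
  vfa <- synthesize_vfa_stack(vfa_t10, vfa_s0, vfa_b1, config,
                              config$vfa_flips_deg)

  vol <- structure(
    list(signal = signal, label_map = lab, truth_maps = truth,
         vfa_stack = vfa, block_curves = block_curves,
         aif_blood_dyn = cb_dyn, config = config,
         model_id = model$model_id),
    class = "dro_volume")
  if (config$noise_sigma > 0)
    vol <- add_noise(vol, config$noise_sigma, config$seed)
  vol
}

#' @export
print.dro_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf(paste0("DRO volume (model '%s'): %d timepoints x %d slice(s) ",
                     "x %d x %d voxels, %d tissue blocks\n"),
              x$model_id, d[1], d[2], d[3], d[4],
              length(x$block_curves)))
  invisible(x)
}

#' Add seeded Gaussian noise to a DRO volume
#'
#' Independent zero-mean Gaussian noise per voxel-timepoint on the
#' magnitude signal, clipped at 0. A rudimentary capability intended for
#' exercising analysis software, not for realistic noise simulation (no
#' Rician/k-space statistics).
#'
#' @param volume A `dro_volume`.
#' @param sigma Noise standard deviation in grey-level units (>= 0).
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @return The volume with noisy `signal` (and `noise_sigma` recorded);
#'   `sigma = 0` returns the input unchanged.
#' @export
add_noise <- function(volume, sigma, seed = volume$config$seed) {
  stopifnot(inherits(volume, "dro_volume"))
  if (sigma < 0) stop("noise sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(volume)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  noisy <- volume$signal + stats::rnorm(length(volume$signal), 0, sigma)
  volume$signal <- array(pmax(noisy, 0), dim = dim(volume$signal))
  volume$config$noise_sigma <- sigma
  volume
}
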