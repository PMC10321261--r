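#' Tissue signal-model properties
#'
#' Baseline (pre-contrast) properties of one simulated tissue used by the
#' SPGR signal stage: longitudinal relaxation time T1,0, baseline signal
#' level, and the transmit-field (B1) scale factor that multiplies the
#' nominal flip angle.
#'
#' @param t10_ms Baseline T1 in ms (> 0).
#' @param s0 Baseline signal in grey-level units (> 0).
#' @param b1 Transmit-field ratio (> 0, typically 0.5-1.5).
#' @return Object of class `tissue_properties`.
#' @export
tissue_properties <- function(t10_ms, s0, b1 = 1) {
  stopifnot(is.numeric(t10_ms), t10_ms > 0, is.numeric(s0), s0 > 0,
            is.numeric(b1), b1 > 0)
  structure(list(t10_ms = t10_ms, s0 = s0, b1 = b1),
            class = "tissue_properties")
}

#' Effective (B1-corrected) flip angle
#'
#' @param flip_deg Nominal excitation flip angle in degrees.
#' @param b1 Transmit-field scale factor (> 0).
#' @return `b1 * flip_deg` in degrees.
#' @export
effective_flip_angle <- function(flip_deg, b1) {
  if (any(b1 <= 0)) stop("B1 ratio must be > 0", call. = FALSE)
  b1 * flip_deg
}

#' Concentration to longitudinal relaxation rate
#'
#' Linear fast-exchange relaxivity relation \eqn{R_1 = R_{1,0} + r_1 C}.
#'
#' @param conc_mM Contrast agent concentration (mM), may be a vector.
#' @param r10_per_s Baseline relaxation rate \eqn{R_{1,0} = 1/T_{1,0}}
#'   (s^-1).
#' @param r1_relaxivity Longitudinal relaxivity r1 (mM^-1 s^-1).
#' @return R1 in s^-1.
#' @export
conc_to_relaxation_rate <- function(conc_mM, r10_per_s, r1_relaxivity) {
  r10_per_s + r1_relaxivity * conc_mM
}

#' Spoiled gradient-echo steady-state signal
#'
#' \deqn{S = M_0 \sin\alpha \frac{1 - E_1}{1 - \cos\alpha \, E_1}, \quad
#'       E_1 = e^{-TR \cdot R_1}}
#'
#' @param m0 Equilibrium magnetization in grey-level units (>= 0).
#' @param r1_per_s Longitudinal relaxation rate (s^-1), may be a vector.
#' @param tr_ms Repetition time in ms.
#' @param alpha_eff_deg Effective (B1-corrected) flip angle in degrees.
#' @return Signal in grey-level units, in `[0, m0]`.
#' @export
spgr_signal <- function(m0, r1_per_s, tr_ms, alpha_eff_deg) {
  stopifnot(all(m0 >= 0), tr_ms > 0)
  a <- alpha_eff_deg * pi / 180
  e1 <- exp(-(tr_ms / 1000) * r1_per_s)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Calibrate equilibrium magnetization from baseline signal
#'
#' The SPGR equation is linear in M0, so the M0 that reproduces the
#' observed pre-contrast signal `s0` at the tissue's `T1,0` is recovered in
#' closed form.
#'
#' @param s0 Baseline signal (> 0).
#' @param t10_ms Baseline T1 (ms).
#' @param tr_ms Repetition time (ms).
#' @param alpha_eff_deg Effective flip angle in degrees, in (0, 180).
#' @return M0 in grey-level units.
#' @export
m0_from_baseline <- function(s0, t10_ms, tr_ms, alpha_eff_deg) {
  if (any(s0 <= 0)) stop("baseline signal s0 must be > 0", call. = FALSE)
  stopifnot(alpha_eff_deg > 0, alpha_eff_deg < 180)
  s_unit <- spgr_signal(1, 1000 / t10_ms, tr_ms, alpha_eff_deg)
  s0 / s_unit
}

#' Convert a concentration-time curve to an SPGR signal-time curve
#'
#' Composition of the forward signal stages: B1-corrected flip angle, M0
#' calibration from the baseline signal, relaxivity relation, SPGR
#' equation. A zero concentration curve maps to a constant `s0`.
#'
#' @param conc Concentration curve (mM) on the dynamic grid.
#' @param tissue A [tissue_properties()].
#' @param acq A list/[dro_config()] with `tr_ms`, `flip_deg`,
#'   `r1_relaxivity`.
#' @return Signal curve in grey-level units.
#' @export
conc_curve_to_signal <- function(conc, tissue, acq) {
  stopifnot(inherits(tissue, "tissue_properties"))
  alpha <- effective_flip_angle(acq$flip_deg, tissue$b1)
  m0 <- m0_from_baseline(tissue$s0, tissue$t10_ms, acq$tr_ms, alpha)
  r1 <- conc_to_relaxation_rate(conc, 1000 / tissue$t10_ms,
                                acq$r1_relaxivity)
  spgr_signal(m0, r1, acq$tr_ms, alpha)
}

#' Synthesize pre-contrast variable-flip-angle images
#'
#' One image per flip angle, each the pre-contrast SPGR signal at the
#' B1-corrected angle per voxel, consistent by construction with the
#' exported T1,0 map. These are the source images a validator's VFA T1
#' mapping step consumes.
#'
#' @param t10_map,s0_map,b1_map Numeric matrices (same shape) of per-voxel
#'   baseline T1 (ms), baseline signal and B1 ratio.
#' @param acq List with `tr_ms` and (nominal dynamic) `flip_deg` — only
#'   `tr_ms` is used here.
#' @param vfa_flips_deg Vector of at least 2 distinct flip angles
#'   (degrees).
#' @return Named list of matrices, one per flip angle (`"flip_02"` etc.).
#' @export
synthesize_vfa_stack <- function(t10_map, s0_map, b1_map, acq,
                                 vfa_flips_deg) {
  if (length(unique(vfa_flips_deg)) < 2L)
    stop("VFA synthesis needs at least 2 distinct flip angles",
         call. = FALSE)
  out <- lapply(vfa_flips_deg, function(flip) {
    alpha <- effective_flip_angle(flip, b1_map)
    a <- alpha * pi / 180
    e1 <- exp(-(acq$tr_ms / 1000) * (1000 / t10_map))
    m0 <- s0_map / spgr_signal(1, 1000 / t10_map, acq$tr_ms,
                               effective_flip_angle(acq$flip_deg, b1_map))
    m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
  })
  names(out) <- sprintf("flip_%02g", vfa_flips_deg)
  out
}
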