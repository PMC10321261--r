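test_that("impulse responses match their closed forms and boundary values", {
  t_grid <- seq(0, 600, by = 0.5)

  # Tofts: I(0) = Ktrans, area = ve
  p <- tissue_params(ktrans = 0.1, ve = 0.25)
  imp <- impulse_response("tofts", p, t_grid)
  expect_equal(imp[1], 0.1)
  area <- stats::integrate(function(t)
    impulse_response("tofts", p, t) / 60, 0, Inf,
    rel.tol = 1e-12)$value
  expect_equal(area, 0.25, tolerance = 1e-9)

  # Patlak: constant residue
  expect_equal(impulse_response("patlak",
                                tissue_params(ktrans = 0.1, vp = 0.02),
                                t_grid),
               rep(0.1, length(t_grid)))

  # 2CXM with PS = 0 collapses to the single-compartment decay Fp e^(-Fp t / vp)
  p2 <- tissue_params(fp = 0.5, ps = 0, ve = 0.25, vp = 0.05)
  imp2 <- impulse_response("2cxm", p2, t_grid)
  expect_equal(imp2, 0.5 * exp(-(0.5 / 0.05 / 60) * t_grid),
               tolerance = 1e-12)

  # value at 0 equals Fp for uptake and 2CXM
  expect_equal(impulse_response("uptake",
                                tissue_params(fp = 0.5, ps = 0.125,
                                              vp = 0.05), 0), 0.5)
  expect_equal(impulse_response("2cxm",
                                tissue_params(fp = 0.5, ps = 0.125,
                                              ve = 0.25, vp = 0.05),
                                0), 0.5, tolerance = 1e-12)
})

test_that("uptake and 2CXM impulse responses agree with an ODE oracle", {
  skip_if_not_installed("deSolve")
  tt <- seq(0, 600, by = 0.25)        # 10 min, s
  tmin <- tt / 60

  # 2CXM: delta plasma input deposits Cp(0) = Fp/vp; I = vp Cp + ve Ce
  p <- tissue_params(fp = 0.5, ps = 0.125, ve = 0.25, vp = 0.05)
  rhs <- function(t, y, parms) {
    with(parms, list(c(-((fp + ps) / vp) * y[1] + (ps / vp) * y[2],
                       (ps / ve) * y[1] - (ps / ve) * y[2])))
  }
  sol <- deSolve::lsoda(c(p$fp / p$vp, 0), tmin, rhs, p,
                        rtol = 1e-11, atol = 1e-13)
  oracle <- p$vp * sol[, 2] + p$ve * sol[, 3]
  imp <- impulse_response("2cxm", p, tt)
  expect_lt(max(abs(imp - oracle) / pmax(abs(oracle), 1e-12)), 1e-6)

  # uptake: irreversible limit, no backflux; tissue accumulates PS*Cp
  pu <- tissue_params(fp = 0.5, ps = 0.125, vp = 0.05)
  rhs_u <- function(t, y, parms) {
    with(parms, list(c(-((fp + ps) / vp) * y[1], ps * y[1])))
  }
  sol_u <- deSolve::lsoda(c(pu$fp / pu$vp, 0), tmin, rhs_u, pu,
                          rtol = 1e-11, atol = 1e-13)
  oracle_u <- pu$vp * sol_u[, 2] + sol_u[, 3]
  imp_u <- impulse_response("uptake", pu, tt)
  expect_lt(max(abs(imp_u - oracle_u) / pmax(abs(oracle_u), 1e-12)), 1e-6)
})

test_that("degenerate parameter combinations are rejected", {
  t_grid <- c(0, 1)
  expect_error(impulse_response("tofts",
                                tissue_params(ktrans = 0.1, ve = 0),
                                t_grid), "degenerate")
  expect_error(impulse_response("uptake",
                                tissue_params(fp = 0.5, ps = 0.1, vp = 0),
                                t_grid), "degenerate")
  expect_error(impulse_response("2cxm",
                                tissue_params(fp = 0.5, ps = 0.1,
                                              ve = 0.25, vp = 0),
                                t_grid), "degenerate")
  # Ktrans = 0 Tofts voxels are identically zero, not an error
  expect_equal(impulse_response("tofts",
                                tissue_params(ktrans = 0, ve = 0.25),
                                t_grid), c(0, 0))
  expect_error(tissue_params(ktrans = -1), ">= 0")
  expect_error(tissue_params(ve = 0.8, vp = 0.3), "<= 1")
})

test_that("trapezoidal convolution matches a direct-summation oracle", {
  # constant integrand: c(t) = t in minutes
  n <- 5
  imp <- rep(1, n); cp <- rep(1, n)
  cc <- convolve_trapezoid(imp, cp, 60)
  expect_equal(cc, 0:(n - 1))
  expect_equal(cc[3], 2.0)   # 2 min of unit product

  expect_equal(convolve_trapezoid(imp, rep(0, n), 60), rep(0, n))
  expect_error(convolve_trapezoid(imp, cp[-1], 60), "equal length")

  # single nonzero Cp sample at tau = 0: only the half-weight boundary term
  cp1 <- c(2, rep(0, n - 1))
  expect_equal(convolve_trapezoid(imp, cp1, 60), c(0, rep(1, n - 1)))

  # random curves against the independent O(n^2) oracle
  set.seed(42)
  for (i in 1:5) {
    m <- 80
    imp_r <- stats::runif(m)
    cp_r <- stats::runif(m)
    expect_equal(convolve_trapezoid(imp_r, cp_r, 0.5),
                 trapz_conv_direct(imp_r, cp_r, 0.5), tolerance = 1e-10)
  }
})

test_that("forward model reproduces constant-AIF closed forms", {
  cfg <- dro_config(dt_s = 0.5, n_timepoints = 200L,
                    integration_dt_s = 0.5)
  n_int <- cfg$n_timepoints
  cp <- rep(1, n_int)                       # constant 1 mM plasma
  t_dyn <- (seq_len(cfg$n_timepoints) - 1) * cfg$dt_s

  # Patlak: C = vp C0 + Ktrans C0 t; exact under trapezoid (linear integrand)
  pk <- forward_tissue_conc("patlak",
                            tissue_params(ktrans = 0.1, vp = 0.02),
                            cp, cfg)
  expect_equal(pk, 0.02 + 0.1 * t_dyn / 60, tolerance = 1e-12)
  expect_equal(pk[t_dyn == 60], 0.12, tolerance = 1e-12)

  # Tofts: C = ve C0 (1 - e^(-kep t)) within quadrature tolerance
  p <- tissue_params(ktrans = 0.1, ve = 0.25)
  tf <- forward_tissue_conc("tofts", p, cp, cfg)
  kep_s <- 0.1 / 0.25 / 60
  expect_equal(tf, 0.25 * (1 - exp(-kep_s * t_dyn)), tolerance = 1e-6)

  # all kinetic parameters zero: identically zero curve
  z <- forward_tissue_conc("etofts",
                           tissue_params(ktrans = 0, ve = 0.25, vp = 0),
                           cp, cfg)
  expect_equal(z, rep(0, cfg$n_timepoints))
})

test_that("quadrature error is O(dt^2) and eTofts(vp=0) equals Tofts bitwise", {
  p <- tissue_params(ktrans = 0.2, ve = 0.2)
  kep_s <- 0.2 / 0.2 / 60
  err <- sapply(c(4, 2, 1), function(int_dt) {
    cfg <- dro_config(dt_s = 8, n_timepoints = 40L,
                      integration_dt_s = int_dt)
    n_int <- (cfg$n_timepoints - 1L) * (8 / int_dt) + 1L
    cp <- rep(1, n_int)
    t_dyn <- (seq_len(cfg$n_timepoints) - 1) * cfg$dt_s
    max(abs(forward_tissue_conc("tofts", p, cp, cfg) -
              0.2 * (1 - exp(-kep_s * t_dyn))))
  })
  expect_gt(err[1] / err[2], 3.3)
  expect_lt(err[1] / err[2], 4.7)
  expect_gt(err[2] / err[3], 3.3)
  expect_lt(err[2] / err[3], 4.7)

  cfg <- dro_config(dt_s = 0.5, n_timepoints = 100L)
  cp <- synthetic_population_aif(0.5, 100L)$conc_mM
  tof <- forward_tissue_conc("tofts", tissue_params(ktrans = 0.1, ve = 0.3),
                             cp, cfg)
  eto <- forward_tissue_conc("etofts",
                             tissue_params(ktrans = 0.1, ve = 0.3, vp = 0),
                             cp, cfg)
  expect_identical(tof, eto)
})

test_that("user models plug into the registry and the forward machinery", {
  register_kinetic_model(
    "const_test",
    impulse_response = function(t_s, params) rep(params$ktrans,
                                                 length(t_s)),
    vascular_term = FALSE,
    free_params = "ktrans")
  expect_true("const_test" %in% list_kinetic_models())
  cfg <- dro_config(n_timepoints = 10L)
  out <- forward_tissue_conc("const_test", tissue_params(ktrans = 0.1),
                             rep(1, 10), cfg)
  t_dyn <- (0:9) * 0.5
  expect_equal(out, 0.1 * t_dyn / 60, tolerance = 1e-12)
  expect_error(kinetic_model("no_such_model"), "unknown kinetic model")
})
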