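test_that("signal-to-concentration conversion is the exact SPGR inverse", {
  tissue <- tissue_properties(1000, 50, 0.95)
  acq <- list(tr_ms = 5, flip_deg = 25, r1_relaxivity = 4.5)
  conc <- c(rep(0, 10), 0.05, 0.4, 1.2, 2.5, 1.8, 0.9, 0.5, 0.3)
  sig <- conc_curve_to_signal(conc, tissue, acq)
  back <- signal_to_conc(sig, tissue, acq, baseline_points = 10)
  expect_lt(max(abs(back - conc)), 1e-9)

  # constant baseline maps to zero concentration
  flat <- signal_to_conc(rep(50, 20), tissue, acq, 10)
  expect_equal(flat, rep(0, 20), tolerance = 1e-12)

  # decoding with the wrong B1 biases the curve; the right B1 removes it
  tissue_gen <- tissue_properties(1000, 50, 0.9)
  sig2 <- conc_curve_to_signal(conc, tissue_gen, acq)
  wrong <- signal_to_conc(sig2, tissue_properties(1000, 50, 1), acq, 10)
  right <- signal_to_conc(sig2, tissue_gen, acq, 10)
  expect_gt(max(abs(wrong - conc)), 0.01)
  expect_lt(max(abs(right - conc)), 1e-9)
})

test_that("VFA T1 estimation is exact noise-free and B1-sensitive", {
  tr <- 5; flips <- c(2, 5, 10, 15)
  e1 <- exp(-tr / 1000)
  for (b1 in c(1, 0.9)) {
    a <- flips * b1 * pi / 180
    sig <- 1000 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
    expect_equal(t1_from_vfa(sig, flips, b1, tr), 1000,
                 tolerance = 1e-6)
  }
  a <- flips * 0.9 * pi / 180
  sig <- 1000 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
  biased <- t1_from_vfa(sig, flips, 1, tr)
  expect_gt(abs(biased - 1000) / 1000, 0.05)
  expect_error(t1_from_vfa(sig[c(1, 1)], c(10, 10), 1, tr), "distinct")
})

test_that("Lin's CCC reproduces hand-computed values and its invariances", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(lin_ccc(x, x)$ccc, 1)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4))$ccc, 4 / 7)
  xm <- c(-2, -1, 0, 1, 2)
  expect_equal(lin_ccc(xm, -xm)$ccc, -1)

  set.seed(3)
  a <- stats::rnorm(30); b <- a + stats::rnorm(30, 0, 0.3)
  r1 <- lin_ccc(a, b); r2 <- lin_ccc(b, a)
  expect_equal(r1$ccc, r2$ccc)
  perm <- sample(30)
  expect_equal(lin_ccc(a[perm], b[perm])$ccc, r1$ccc)
  # CCC = Pearson r times the bias-correction factor, c_b <= 1
  expect_equal(r1$ccc, r1$pearson_r * r1$c_b)
  expect_lte(r1$c_b, 1)
  expect_true(r1$ci_low <= r1$ccc && r1$ccc <= r1$ci_high)
  expect_error(lin_ccc(rep(1, 5), rep(2, 5)), "constant")
})

test_that("fitting a model's own noise-free curves recovers the parameters", {
  cfg <- dro_config(n_timepoints = 300L)
  n_int <- cfg$n_timepoints
  aif <- synthetic_population_aif(0.5, n_int + 10L)
  cp <- resample_aif(blood_to_plasma(aif, 0.45), 0.5, n_int, 5)

  truth <- list(
    tofts = tissue_params(ktrans = 0.2, ve = 0.3),
    etofts = tissue_params(ktrans = 0.15, ve = 0.35, vp = 0.04),
    patlak = tissue_params(ktrans = 0.08, vp = 0.03),
    uptake = tissue_params(fp = 0.6, ps = 0.1, vp = 0.06),
    `2cxm` = tissue_params(fp = 0.6, ps = 0.15, ve = 0.3, vp = 0.06))
  for (m in names(truth)) {
    conc <- forward_tissue_conc(m, truth[[m]], cp, cfg)
    fit <- fit_kinetic_model(m, conc, cp, cfg)
    expect_true(fit$converged)
    for (f in kinetic_model(m)$free_params) {
      expect_lt(abs(fit$params[[f]] - truth[[m]][[f]]) /
                  truth[[m]][[f]], 1e-3)
    }
  }

  # degenerate: all-zero concentration pins Ktrans at the lower bound
  z <- fit_kinetic_model("tofts", rep(0, cfg$n_timepoints), cp, cfg)
  expect_lt(z$params$ktrans, 1e-8)
  expect_lt(z$residual_norm, 1e-20)
})

test_that("a weakly identified 2CXM curve exposes optimizer local minima", {
  # short acquisition, very low PS: the default start converges to a
  # different (worse) minimum than a start near the truth
  cfg <- dro_config(n_timepoints = 120L)
  aif <- synthetic_population_aif(0.5, 140L)
  cp <- resample_aif(blood_to_plasma(aif, 0.45), 0.5, 120L, 5)
  p <- tissue_params(fp = 0.6, ps = 0.01, ve = 0.4, vp = 0.1)
  conc <- forward_tissue_conc("2cxm", p, cp, cfg)
  f_default <- fit_kinetic_model("2cxm", conc, cp, cfg)
  f_second <- fit_kinetic_model("2cxm", conc, cp, cfg,
                                init = tissue_params(fp = 0.6, ps = 0.02,
                                                     ve = 0.8, vp = 0.1))
  expect_lt(f_second$residual_norm, f_default$residual_norm / 10)
  expect_gt(abs(f_default$params$ve - p$ve), 0.1)
  expect_lt(abs(f_second$params$ve - p$ve), 1e-3)
})

test_that("round-trip validation scores near-perfect concordance in memory", {
  cfg <- small_config(n_timepoints = 150L)
  res <- round_trip_validate("etofts", grid = tiny_grid("etofts"),
                             config = cfg)
  expect_setequal(res$parameter, c("ktrans", "ve", "vp"))
  # true-Ktrans-0 blocks are excluded for the extended Tofts model
  expect_equal(unique(res$n), 3L)
  expect_true(all(res$ccc > 0.999))
  fits <- attr(res, "fits")
  expect_length(fits, 4L)
})

test_that("the DICOM round trip changes CCC by less than 1e-6", {
  cfg <- small_config(n_timepoints = 150L)
  tab <- data.frame(Ktrans = c(0.05, 0.1, 0.2, 0.35),
                    ve = c(0.1, 0.3, 0.5, 0.2), T10 = 1000,
                    B1 = c(0.9, 1, 1.1, 1))
  g <- parameter_grid(tab, "tofts")
  mem <- round_trip_validate("tofts", grid = g, config = cfg)
  dd <- tempfile("dicomrt")
  dcm <- round_trip_validate("tofts", grid = g, config = cfg,
                             via_dicom = TRUE, dicom_dir = dd)
  expect_lt(max(abs(mem$ccc - dcm$ccc)), 1e-6)
  expect_true(all(dcm$ccc > 0.9999))

  # concentration curves survive export/import within quantization
  vol <- build_dro(g, NULL, cfg)
  back <- read_dro_dicom(dd)
  i <- 3
  vox <- which(back$label_map == i, arr.ind = TRUE)[1, ]
  sig <- back$signal[, 1, vox[1], vox[2]]
  row <- g$rows[[i]]
  conc <- signal_to_conc(sig, tissue_properties(row$t10_ms, row$s0,
                                                row$b1),
                         cfg, cfg$baseline_points)
  truth <- vol$block_curves[[i]]$conc_mM
  expect_lt(max(abs(conc - truth)) / max(truth), 1e-3)
})
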