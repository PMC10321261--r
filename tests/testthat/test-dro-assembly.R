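test_that("parameter-grid CSVs are validated against the model's needs", {
  f <- write_tmp_csv(c("Ktrans,ve,T10", "0.1,0.25,1000", "0.2,0.5,1500"))
  g <- read_parameter_grid(f, "tofts")
  expect_length(g$rows, 2)
  expect_equal(sapply(g$rows, `[[`, "b1"), c(1, 1))
  expect_equal(sapply(g$rows, `[[`, "s0"), c(50, 50))
  expect_equal(g$rows[[2]]$params$ktrans, 0.2)

  f2 <- write_tmp_csv(c("Ktrans,T10", "0.1,1000"))
  expect_error(read_parameter_grid(f2, "tofts"), "missing required")
  f3 <- write_tmp_csv(c("Ktrans,ve,vp,T10", "0.1,0.8,0.3,1000"))
  expect_error(read_parameter_grid(f3, "etofts"), "<= 1")
  f4 <- write_tmp_csv(c("Ktrans,ve,T10", "0.1,abc,1000"))
  expect_error(read_parameter_grid(f4, "tofts"), "non-numeric")
})

test_that("packaged default grids load for all five models", {
  sizes <- c(patlak = 30, tofts = 30, etofts = 30, uptake = 27,
             `2cxm` = 24)
  for (m in names(sizes)) {
    g <- default_parameter_grid(m)
    expect_identical(g$model_id, m)
    expect_length(g$rows, unname(sizes[m]))
  }
  # eTofts grid carries Ktrans = 0 rows for the exclusion rule
  g <- default_parameter_grid("etofts")
  expect_true(any(sapply(g$rows, function(r) r$params$ktrans) == 0))
})

test_that("block layout tiles row-major with a bottom AIF strip", {
  cfg <- dro_config(pixels_per_block = 10L)
  lab <- layout_blocks(2, cfg)
  expect_equal(dim(lab), c(20, 20))          # 1 block-row + AIF strip
  expect_equal(sum(lab == 1), 100)
  expect_equal(sum(lab == 2), 100)
  expect_equal(sum(lab == -2), 200)          # full-width strip
  expect_true(all(lab[11:20, ] == -2))
  expect_true(all(lab[1:10, 1:10] == 1))     # row-major placement
  expect_true(all(lab %in% c(-2L, -1L, 1L, 2L)))

  lab1 <- layout_blocks(1, cfg)
  expect_equal(sum(lab1 == 1), 100)
  # partition: every voxel has exactly one label by construction
  expect_equal(sum(table(lab1)), length(lab1))
})

test_that("assembled volumes are homogeneous per block with exact truth maps", {
  cfg <- small_config(pixels_per_block = 4L)
  g <- tiny_grid("tofts")
  vol <- build_dro(g, NULL, cfg)
  expect_equal(dim(vol$signal)[1], cfg$n_timepoints)

  # all voxels in a block share one curve; truth maps hold the row values
  for (i in seq_along(g$rows)) {
    idx <- which(vol$label_map == i, arr.ind = TRUE)
    curves <- apply(idx, 1, function(v) vol$signal[, 1, v[1], v[2]])
    expect_equal(max(apply(curves, 1, function(x) diff(range(x)))), 0)
    expect_equal(vol$truth_maps$ktrans[idx[1, 1], idx[1, 2]],
                 g$rows[[i]]$params$ktrans)
    expect_equal(vol$truth_maps$ve[idx[1, 1], idx[1, 2]],
                 g$rows[[i]]$params$ve)
    expect_equal(vol$truth_maps$t10_ms[idx[1, 1], idx[1, 2]],
                 g$rows[[i]]$t10_ms)
  }

  # exactly baseline_points pre-contrast frames per tissue voxel
  idx <- which(vol$label_map == 1, arr.ind = TRUE)[1, ]
  curve <- vol$signal[, 1, idx[1], idx[2]]
  bp <- cfg$baseline_points
  expect_equal(diff(range(curve[1:bp])), 0)
  expect_true(any(curve[(bp + 2):(bp + 20)] != curve[1]))

  # deterministic: a second build is bitwise identical
  vol2 <- build_dro(g, NULL, cfg)
  expect_identical(vol$signal, vol2$signal)
})

test_that("changing one row's B1 changes its signal but not its concentration", {
  cfg <- small_config(pixels_per_block = 2L)
  tab <- data.frame(Ktrans = c(0.1, 0.1), ve = c(0.3, 0.3),
                    T10 = 1000, B1 = c(1, 1))
  tab2 <- tab; tab2$B1[2] <- 0.85
  v1 <- build_dro(parameter_grid(tab, "tofts"), NULL, cfg)
  v2 <- build_dro(parameter_grid(tab2, "tofts"), NULL, cfg)
  expect_identical(v1$block_curves[[1]]$signal, v2$block_curves[[1]]$signal)
  expect_false(isTRUE(all.equal(v1$block_curves[[2]]$signal,
                                v2$block_curves[[2]]$signal)))
  expect_identical(v1$block_curves[[2]]$conc_mM,
                   v2$block_curves[[2]]$conc_mM)
})

test_that("an AIF that ends before the dynamic window is a coverage error", {
  cfg <- small_config()
  short_aif <- synthetic_population_aif(0.5, 10L)   # 4.5 s of support
  expect_error(build_dro(tiny_grid("tofts"), short_aif, cfg), "coverage")
})

test_that("noise addition is seeded, clipped and sigma-faithful", {
  cfg <- small_config()
  vol <- build_dro(tiny_grid("tofts"), NULL, cfg)
  expect_identical(add_noise(vol, 0), vol)
  n1 <- add_noise(vol, 5, seed = 7)
  n2 <- add_noise(vol, 5, seed = 7)
  expect_identical(n1$signal, n2$signal)
  expect_false(identical(n1$signal, add_noise(vol, 5, seed = 8)$signal))
  expect_true(all(n1$signal >= 0))
  expect_error(add_noise(vol, -1), ">= 0")

  # sample sd of the added noise where clipping is negligible
  mask <- vol$signal >= 50
  expect_gt(sum(mask), 1e4)
  d <- (n1$signal - vol$signal)[mask]
  expect_lt(abs(stats::sd(d[1:1e4]) - 5), 0.15)
})

test_that("configs validate grid compatibility and read from files", {
  expect_error(dro_config(dt_s = 0.5, integration_dt_s = 0.3),
               "divide")
  f <- tempfile(fileext = ".txt")
  writeLines(c("dt_s = 2", "n_timepoints = 100", "flip_deg = 20",
               "vfa_flips_deg = 3,14"), f)
  cfg <- dro_config_from_file(f)
  expect_equal(cfg$dt_s, 2)
  expect_equal(cfg$n_timepoints, 100L)
  expect_equal(cfg$vfa_flips_deg, c(3, 14))
  writeLines("nonsense = 1", f)
  expect_error(dro_config_from_file(f), "unknown config key")
})
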