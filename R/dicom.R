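# Minimal DICOM Part 10 writer/reader: classic single-frame MR Image
# Storage, explicit VR little endian only. Covers the header subset DCE
# analysis tools read (timing, flip angle, TR, spacing, temporal position,
# rescale). Sequences (SQ) are neither written nor parsed.

.UID_MR_STORAGE <- "1.2.840.10008.5.1.4.1.1.4"
.UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.UID_IMPL_CLASS <- "2.25.432109876543210"

.STRING_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                 "PN", "SH", "ST", "TM", "UI", "UT")
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Deterministic UID factory: one context per export run, seeded from the
# config so test fixtures are byte-stable.
.uid_context <- function(seed) {
  ctx <- new.env(parent = emptyenv())
  ctx$base <- sprintf("2.25.%d", 100000L + (abs(as.integer(seed)) %% 899999L))
  ctx$n <- 0L
  ctx
}

.next_uid <- function(ctx) {
  ctx$n <- ctx$n + 1L
  sprintf("%s%07d", ctx$base, ctx$n)
}

.u16_to_signed <- function(x) {
  x <- as.integer(round(x))
  ifelse(x > 32767L, x - 65536L, x)
}

.raw_u16 <- function(x) writeBin(.u16_to_signed(x), raw(), size = 2L,
                                 endian = "little")

.raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                 endian = "little")

.encode_value <- function(vr, value) {
  if (vr %in% .STRING_VRS) {
    s <- if (vr %in% c("DS", "IS")) paste(vapply(value, format, "",
                                                 digits = 10),
                                          collapse = "\\")
         else paste(value, collapse = "\\")
    v <- charToRaw(s)
    if (length(v) %% 2L == 1L)
      v <- c(v, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    v
  } else if (vr == "US") {
    .raw_u16(value)
  } else if (vr == "UL") {
    .raw_u32(value)
  } else if (vr == "OB") {
    v <- as.raw(value)
    if (length(v) %% 2L == 1L) v <- c(v, as.raw(0L))
    v
  } else if (vr == "OW") {
    .raw_u16(value)
  } else stop("unsupported VR: ", vr, call. = FALSE)
}

.encode_element <- function(group, elem, vr, value) {
  v <- .encode_value(vr, value)
  hdr <- c(.raw_u16(group), .raw_u16(elem), charToRaw(vr))
  if (vr %in% .LONG_VRS) {
    c(hdr, as.raw(c(0L, 0L)), .raw_u32(length(v)), v)
  } else {
    if (length(v) > 65534L) stop("value too long for short VR",
                                 call. = FALSE)
    c(hdr, .raw_u16(length(v)), v)
  }
}

# elements: list of list(group, elem, vr, value); written sorted by tag
.write_dicom_raw <- function(elements) {
  ord <- order(vapply(elements, function(e) e$group * 65536 + e$elem, 0))
  body <- do.call(c, lapply(elements[ord], function(e)
    .encode_element(e$group, e$elem, e$vr, e$value)))
  body
}

.dicom_seconds_to_tm <- function(sec) {
  h <- floor(sec / 3600); sec <- sec - 3600 * h
  m <- floor(sec / 60); s <- sec - 60 * m
  sprintf("%02d%02d%09.6f", h, m, s)
}

#' Write one classic single-frame MR DICOM file
#'
#' Low-level writer used by the series exporters; explicit VR little
#' endian, unsigned 16-bit pixels.
#'
#' @param path Output file path.
#' @param pixels Integer matrix (image rows x columns) of stored values in
#'   `[0, 65535]`.
#' @param meta Named list of header fields: `sop_instance_uid`,
#'   `series_instance_uid`, `study_instance_uid`, `series_number`,
#'   `instance_number`, `series_description`, `flip_deg`, `tr_ms`,
#'   `te_ms`, `pixel_mm`, `slice_thickness_mm`, `slice_location`,
#'   `temporal_position`, `n_temporal_positions`, `acq_time_s`,
#'   `rescale_slope`, `rescale_intercept`.
#' @return `path`, invisibly.
#' @export
write_dicom_file <- function(path, pixels, meta) {
  if (any(pixels < 0 | pixels > 65535))
    stop("stored pixel values must lie in [0, 65535]", call. = FALSE)
  el <- function(group, elem, vr, value)
    list(group = group, elem = elem, vr = vr, value = value)
  tm <- .dicom_seconds_to_tm(8 * 3600 + meta$acq_time_s)
  ds <- list(
    el(0x0008, 0x0008, "CS", c("DERIVED", "SECONDARY", "SIMULATION")),
    el(0x0008, 0x0016, "UI", .UID_MR_STORAGE),
    el(0x0008, 0x0018, "UI", meta$sop_instance_uid),
    el(0x0008, 0x0020, "DA", "20230525"),
    el(0x0008, 0x0021, "DA", "20230525"),
    el(0x0008, 0x0022, "DA", "20230525"),
    el(0x0008, 0x0023, "DA", "20230525"),
    el(0x0008, 0x0030, "TM", "080000"),
    el(0x0008, 0x0031, "TM", "080000"),
    el(0x0008, 0x0032, "TM", tm),
    el(0x0008, 0x0033, "TM", tm),
    el(0x0008, 0x0060, "CS", "MR"),
    el(0x0008, 0x0070, "LO", "dcedro"),
    el(0x0008, 0x103E, "LO", meta$series_description),
    el(0x0010, 0x0010, "PN", "DRO^Digital"),
    el(0x0010, 0x0020, "LO", "DCEDRO"),
    el(0x0018, 0x0050, "DS", meta$slice_thickness_mm),
    el(0x0018, 0x0080, "DS", meta$tr_ms),
    el(0x0018, 0x0081, "DS", meta$te_ms),
    el(0x0018, 0x1314, "DS", meta$flip_deg),
    el(0x0020, 0x000D, "UI", meta$study_instance_uid),
    el(0x0020, 0x000E, "UI", meta$series_instance_uid),
    el(0x0020, 0x0010, "SH", "1"),
    el(0x0020, 0x0011, "IS", meta$series_number),
    el(0x0020, 0x0013, "IS", meta$instance_number),
    el(0x0020, 0x0032, "DS", c(0, 0, meta$slice_location)),
    el(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
    el(0x0020, 0x0100, "IS", meta$temporal_position),
    el(0x0020, 0x0105, "IS", meta$n_temporal_positions),
    el(0x0020, 0x1041, "DS", meta$slice_location),
    el(0x0028, 0x0002, "US", 1L),
    el(0x0028, 0x0004, "CS", "MONOCHROME2"),
    el(0x0028, 0x0010, "US", nrow(pixels)),
    el(0x0028, 0x0011, "US", ncol(pixels)),
    el(0x0028, 0x0030, "DS", c(meta$pixel_mm, meta$pixel_mm)),
    el(0x0028, 0x0100, "US", 16L),
    el(0x0028, 0x0101, "US", 16L),
    el(0x0028, 0x0102, "US", 15L),
    el(0x0028, 0x0103, "US", 0L),
    el(0x0028, 0x1052, "DS", meta$rescale_intercept),
    el(0x0028, 0x1053, "DS", meta$rescale_slope),
    el(0x7FE0, 0x0010, "OW", as.vector(t(pixels)))  # row-major
  )
  body <- .write_dicom_raw(ds)
  meta_el <- list(
    el(0x0002, 0x0001, "OB", c(0L, 1L)),
    el(0x0002, 0x0002, "UI", .UID_MR_STORAGE),
    el(0x0002, 0x0003, "UI", meta$sop_instance_uid),
    el(0x0002, 0x0010, "UI", .UID_EXPLICIT_LE),
    el(0x0002, 0x0012, "UI", .UID_IMPL_CLASS)
  )
  meta_body <- .write_dicom_raw(meta_el)
  group_len <- .encode_element(0x0002, 0x0000, "UL", length(meta_body))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta_body, body), con)
  invisible(path)
}

#' Read one DICOM file written in explicit VR little endian
#'
#' @param path File path.
#' @return List with `tags` (named list keyed `"GGGG,EEEE"`, decoded
#'   values), `pixels` (integer matrix of stored values) and `image`
#'   (numeric matrix after applying rescale slope/intercept).
#' @export
read_dicom_file <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 140L || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM Part 10 file: ", path, call. = FALSE)
  pos <- 133L
  tags <- list()
  u16 <- function(i) as.integer(buf[i]) + 256L * as.integer(buf[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  transfer <- NULL
  while (pos + 7L <= length(buf)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_VRS) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    vraw <- if (len > 0L) buf[vstart:(vstart + len - 1L)] else raw(0L)
    key <- sprintf("%04X,%04X", group, elem)
    val <- if (vr %in% .STRING_VRS) {
      while (length(vraw) &&
             vraw[length(vraw)] %in% as.raw(c(0L, 32L)))
        vraw <- vraw[-length(vraw)]
      s <- rawToChar(vraw)
      parts <- strsplit(s, "\\", fixed = TRUE)[[1L]]
      if (vr %in% c("DS", "IS")) as.numeric(parts) else parts
    } else if (vr %in% c("US", "OW")) {
      readBin(vraw, "integer", n = len %/% 2L, size = 2L, signed = FALSE,
              endian = "little")
    } else if (vr == "UL") {
      readBin(vraw, "integer", n = len %/% 4L, size = 4L,
              endian = "little")
    } else vraw
    tags[[key]] <- val
    if (key == "0002,0010") transfer <- val
    pos <- vstart + len
  }
  if (!is.null(transfer) && transfer != .UID_EXPLICIT_LE)
    stop("unsupported transfer syntax: ", transfer, call. = FALSE)
  nr <- tags[["0028,0010"]]; nc <- tags[["0028,0011"]]
  pixels <- matrix(tags[["7FE0,0010"]], nrow = nr, ncol = nc, byrow = TRUE)
  slope <- if (!is.null(tags[["0028,1053"]])) tags[["0028,1053"]] else 1
  inter <- if (!is.null(tags[["0028,1052"]])) tags[["0028,1052"]] else 0
  list(tags = tags, pixels = pixels, image = pixels * slope + inter)
}

#' Quantize a float-valued map to 16-bit stored pixels
#'
#' Linear rescale encoding: `intercept = min(map)`, `slope = (max - min) /
#' 65535` (slope 1 for a constant map); decoding `pixels * slope +
#' intercept` reproduces the map within `slope / 2` everywhere.
#'
#' @param map2d Numeric matrix with finite values.
#' @return List with `pixels` (integer matrix), `slope`, `intercept`.
#' @export
encode_float_map <- function(map2d) {
  if (any(!is.finite(map2d)))
    stop("float map contains non-finite values", call. = FALSE)
  lo <- min(map2d); hi <- max(map2d)
  slope <- if (hi > lo) (hi - lo) / 65535 else 1
  pix <- matrix(as.integer(round((map2d - lo) / slope)),
                nrow(map2d), ncol(map2d))
  list(pixels = pix, slope = slope, intercept = lo)
}

.series_meta <- function(volume, uid_ctx, study_uid, series_uid,
                         series_number, description) {
  cfg <- volume$config
  list(study_instance_uid = study_uid, series_instance_uid = series_uid,
       series_number = series_number, series_description = description,
       flip_deg = cfg$flip_deg, tr_ms = cfg$tr_ms, te_ms = cfg$te_ms,
       pixel_mm = cfg$pixel_mm,
       slice_thickness_mm = cfg$slice_thickness_mm,
       n_temporal_positions = 1L, temporal_position = 1L,
       acq_time_s = 0, rescale_slope = 1, rescale_intercept = 0)
}

#' Export the dynamic DRO series as DICOM
#'
#' One single-frame file per (slice, timepoint) under `outdir/dynamic/`.
#' Acquisition/content times advance by the dynamic time resolution per
#' frame and the temporal position identifier indexes the frame. A single
#' global rescale slope maps the peak signal near 60000 (headroom for
#' noise) so quantization error stays far below fitting tolerances.
#'
#' @param volume A `dro_volume`.
#' @param outdir Output directory (created if needed).
#' @param study_uid,uid_ctx Internal threading of identifiers when called
#'   from [write_dro_dicom()]; defaults make the call standalone.
#' @return Number of files written (`n_slices * n_timepoints`), invisibly
#'   a list with `files`, `slope`, `series_uid`.
#' @export
write_dynamic_series <- function(volume, outdir,
                                 uid_ctx = .uid_context(volume$config$seed),
                                 study_uid = .next_uid(uid_ctx)) {
  stopifnot(inherits(volume, "dro_volume"))
  cfg <- volume$config
  dir.create(file.path(outdir, "dynamic"), recursive = TRUE,
             showWarnings = FALSE)
  smax <- max(volume$signal)
  slope <- if (smax > 0) smax / 60000 else 1
  if (smax / slope > 65535)
    stop("signal exceeds 16-bit range after scaling; lower the baseline ",
         "signal or widen the rescale slope", call. = FALSE)
  series_uid <- .next_uid(uid_ctx)
  n_t <- cfg$n_timepoints; n_s <- cfg$n_slices
  files <- character(0L)
  inst <- 0L
  for (t in seq_len(n_t)) {
    for (s in seq_len(n_s)) {
      inst <- inst + 1L
      meta <- .series_meta(volume, uid_ctx, study_uid, series_uid, 1L,
                           "DCE dynamic series")
      meta$sop_instance_uid <- .next_uid(uid_ctx)
      meta$instance_number <- inst
      meta$temporal_position <- t
      meta$n_temporal_positions <- n_t
      meta$acq_time_s <- (t - 1L) * cfg$dt_s
      meta$slice_location <- (s - 1L) * cfg$slice_thickness_mm
      meta$rescale_slope <- slope
      meta$rescale_intercept <- 0
      pix <- round(volume$signal[t, s, , ] / slope)
      f <- file.path(outdir, "dynamic",
                     sprintf("dyn_t%04d_s%02d.dcm", t, s))
      write_dicom_file(f, pix, meta)
      files <- c(files, f)
    }
  }
  invisible(list(files = files, n_files = length(files), slope = slope,
                 series_uid = series_uid, study_uid = study_uid))
}

.write_map_series <- function(volume, outdir, subdir, description,
                              series_number, map2d, uid_ctx, study_uid,
                              flip_deg = volume$config$flip_deg) {
  cfg <- volume$config
  dir.create(file.path(outdir, subdir), recursive = TRUE,
             showWarnings = FALSE)
  enc <- encode_float_map(map2d)
  series_uid <- .next_uid(uid_ctx)
  files <- character(0L)
  for (s in seq_len(cfg$n_slices)) {
    meta <- .series_meta(volume, uid_ctx, study_uid, series_uid,
                         series_number, description)
    meta$sop_instance_uid <- .next_uid(uid_ctx)
    meta$instance_number <- s
    meta$slice_location <- (s - 1L) * cfg$slice_thickness_mm
    meta$rescale_slope <- enc$slope
    meta$rescale_intercept <- enc$intercept
    meta$flip_deg <- flip_deg
    f <- file.path(outdir, subdir, sprintf("%s_s%02d.dcm", subdir, s))
    write_dicom_file(f, enc$pixels, meta)
    files <- c(files, f)
  }
  list(series = subdir, description = description,
       series_uid = series_uid, files = files)
}

#' Export the supporting DICOM series of a DRO
#'
#' Writes the variable-flip-angle source images (one series per flip
#' angle, flip angle in the header), the B1 map, the T1,0 and R1,0 maps,
#' and one ground-truth map series per kinetic parameter, each with the
#' linear rescale encoding of [encode_float_map()].
#'
#' @inheritParams write_dynamic_series
#' @return Manifest: list of per-series entries (name, description, UID,
#'   files).
#' @export
write_support_series <- function(volume, outdir,
                                 uid_ctx = .uid_context(volume$config$seed),
                                 study_uid = .next_uid(uid_ctx)) {
  stopifnot(inherits(volume, "dro_volume"))
  cfg <- volume$config
  manifest <- list()
  k <- 0L
  for (i in seq_along(cfg$vfa_flips_deg)) {
    flip <- cfg$vfa_flips_deg[i]
    manifest[[length(manifest) + 1L]] <-
      .write_map_series(volume, outdir, sprintf("vfa_flip%02g", flip),
                        sprintf("VFA source image, flip %g deg", flip),
                        10L + i, volume$vfa_stack[[i]], uid_ctx, study_uid,
                        flip_deg = flip)
  }
  fill <- function(m, default) { m[is.na(m)] <- default; m }
  manifest[[length(manifest) + 1L]] <-
    .write_map_series(volume, outdir, "b1_map", "B1 transmit field map",
                      20L, fill(volume$truth_maps$b1, 1), uid_ctx,
                      study_uid)
  manifest[[length(manifest) + 1L]] <-
    .write_map_series(volume, outdir, "t1_map", "baseline T1 map (ms)",
                      21L, fill(volume$truth_maps$t10_ms,
                                cfg$blood_t10_ms), uid_ctx, study_uid)
  manifest[[length(manifest) + 1L]] <-
    .write_map_series(volume, outdir, "r1_map", "baseline R1 map (1/s)",
                      22L, fill(volume$truth_maps$r10_per_s,
                                1000 / cfg$blood_t10_ms), uid_ctx,
                      study_uid)
  params <- kinetic_model(volume$model_id)$free_params
  for (j in seq_along(params)) {
    pm <- params[j]
    manifest[[length(manifest) + 1L]] <-
      .write_map_series(volume, outdir, paste0("param_", pm),
                        sprintf("ground-truth %s map", pm), 30L + j,
                        fill(volume$truth_maps[[pm]], 0), uid_ctx,
                        study_uid)
  }
  manifest
}

#' Export a complete DRO as DICOM plus sidecar manifest
#'
#' Dynamic series, supporting series and a JSON manifest recording the
#' configuration, the block label map, the per-block ground-truth
#' parameters, the AIF-strip location and the series layout. All series
#' share one study instance UID; identifiers are generated
#' deterministically from `config$seed`.
#'
#' @param volume A `dro_volume`.
#' @param outdir Output directory.
#' @return Path of the manifest JSON, invisibly.
#' @export
write_dro_dicom <- function(volume, outdir) {
  stopifnot(inherits(volume, "dro_volume"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  uid_ctx <- .uid_context(volume$config$seed)
  study_uid <- .next_uid(uid_ctx)
  dyn <- write_dynamic_series(volume, outdir, uid_ctx, study_uid)
  support <- write_support_series(volume, outdir, uid_ctx, study_uid)
  grid_rows <- lapply(volume$block_curves, function(b) NULL)
  params <- kinetic_model(volume$model_id)$free_params
  lab <- volume$label_map
  blocks <- lapply(seq_along(volume$block_curves), function(i) {
    truth <- lapply(params, function(p)
      volume$truth_maps[[p]][which(lab == i)[1L]])
    names(truth) <- params
    c(list(label = i), truth,
      list(t10_ms = volume$truth_maps$t10_ms[which(lab == i)[1L]],
           b1 = volume$truth_maps$b1[which(lab == i)[1L]],
           s0 = volume$truth_maps$s0[which(lab == i)[1L]]))
  })
  aif_rows <- range(which(apply(lab == -2L, 1L, any)))
  manifest <- list(
    model_id = volume$model_id,
    config = unclass(volume$config),
    study_instance_uid = study_uid,
    dynamic = list(n_files = dyn$n_files, rescale_slope = dyn$slope,
                   series_uid = dyn$series_uid),
    series = lapply(support, function(s)
      s[c("series", "description", "series_uid")]),
    label_map = lab,
    blocks = blocks,
    aif_region = list(label = -2L, row_first = aif_rows[1L],
                      row_last = aif_rows[2L]))
  path <- file.path(outdir, "dro_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a DICOM DRO directory
#'
#' Reconstructs the 4D dynamic signal (rescale applied) and the manifest
#' written by [write_dro_dicom()].
#'
#' @param outdir Directory previously written by [write_dro_dicom()].
#' @return List with `signal` (4D array `[time, slice, row, col]`),
#'   `label_map`, `manifest`, `study_uid`, and `meta` of the first
#'   dynamic file.
#' @export
read_dro_dicom <- function(outdir) {
  manifest_path <- file.path(outdir, "dro_manifest.json")
  if (!file.exists(manifest_path))
    stop("no dro_manifest.json under ", outdir, call. = FALSE)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  files <- sort(list.files(file.path(outdir, "dynamic"),
                           pattern = "\\.dcm$", full.names = TRUE))
  if (!length(files)) stop("no dynamic DICOM files under ", outdir,
                           call. = FALSE)
  first <- read_dicom_file(files[1L])
  nr <- nrow(first$image); nc <- ncol(first$image)
  n_t <- as.integer(first$tags[["0020,0105"]])
  n_s <- length(files) %/% n_t
  signal <- array(0, dim = c(n_t, n_s, nr, nc))
  for (f in files) {
    d <- read_dicom_file(f)
    t <- as.integer(d$tags[["0020,0100"]])
    s <- as.integer(round(d$tags[["0020,1041"]] /
                            max(d$tags[["0018,0050"]], 1e-9))) + 1L
    if (s < 1L || s > n_s) s <- 1L
    signal[t, s, , ] <- d$image
  }
  lm <- manifest$label_map
  lab <- if (is.matrix(lm)) matrix(as.integer(lm), nrow(lm), ncol(lm))
         else matrix(as.integer(unlist(lm)), nrow = length(lm),
                     byrow = TRUE)
  list(signal = signal, label_map = lab, manifest = manifest,
       study_uid = first$tags[["0020,000D"]], meta = first$tags)
}
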