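# shared fixtures: small configs, constant AIFs, and an independent
# direct-summation trapezoid oracle for the FFT convolution path

small_config <- function(...) {
  args <- list(...)
  if (!"n_timepoints" %in% names(args)) args$n_timepoints <- 60L
  do.call(dro_config, args)
}

tiny_grid <- function(model_id = "tofts") {
  tab <- switch(model_id,
    tofts = data.frame(Ktrans = c(0.05, 0.2), ve = c(0.2, 0.4),
                       T10 = c(1000, 1400), B1 = c(1, 0.9)),
    etofts = data.frame(Ktrans = c(0, 0.05, 0.1, 0.2),
                        ve = c(0.2, 0.25, 0.3, 0.4),
                        vp = c(0.02, 0.04, 0.05, 0.02), T10 = 1000,
                        B1 = 1),
    patlak = data.frame(Ktrans = c(0.05, 0.2), vp = c(0.02, 0.1),
                        T10 = 1000),
    stop("no tiny grid for ", model_id))
  parameter_grid(tab, model_id)
}

# direct O(n^2) trapezoidal quadrature of the convolution integral,
# independent of the FFT implementation under test
trapz_conv_direct <- function(imp, cp, dt_s) {
  n <- length(imp)
  out <- numeric(n)
  for (k in 2:n) {
    integrand <- imp[k:1] * cp[1:k]
    out[k] <- (dt_s / 60) *
      (sum(integrand) - 0.5 * (integrand[1L] + integrand[k]))
  }
  out
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
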