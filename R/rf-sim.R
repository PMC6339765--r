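#' Linear-array probe and imaging configuration
#'
#' Acquisition parameters of the simulated linear array plus the imaged
#' sub-region of the phantom.  Defaults: 3.5 MHz center frequency, 100 MHz
#' sampling, 512 scan lines at 0.08 mm lateral spacing, 70 mm transmit
#' focus, and a 50 mm deep imaged window starting at 45 mm depth that
#' encircles the default tumor.  The pulse is a Gaussian-modulated sinusoid
#' with the given fractional bandwidth; the lateral point-spread function is
#' a Gaussian of width `beam_sigma_mm` (separable convolutional PSF model).
#'
#' @param center_frequency_hz Transducer center frequency, Hz.
#' @param sampling_frequency_hz RF sampling frequency, Hz; must exceed twice
#'   the center frequency.
#' @param n_lines Number of scan lines.
#' @param lateral_spacing_mm Lateral spacing between scan lines, mm.
#' @param pitch_mm,kerf_mm,element_height_mm Array element geometry, mm
#'   (metadata in the convolutional model).
#' @param focus_depth_mm Transmit focus, mm.
#' @param fractional_bandwidth Pulse -6 dB fractional bandwidth.
#' @param beam_sigma_mm Lateral PSF standard deviation, mm.
#' @param depth_origin_mm,depth_span_mm Axial extent of the imaged window,
#'   mm (depth measured from the probe face).
#' @param lateral_origin_mm Lateral position of the first scan line, mm;
#'   `NULL` centers the aperture on the phantom-width implied by
#'   `lateral_center_mm`.
#' @param lateral_center_mm Lateral midline used when centering, mm.
#' @param sound_speed_m_s Speed of sound, m/s.
#' @return An object of class `probe_config`.
#' @export
probe_config <- function(center_frequency_hz = 3.5e6,
                         sampling_frequency_hz = 100e6,
                         n_lines = 512,
                         lateral_spacing_mm = 0.08,
                         pitch_mm = 0.44, kerf_mm = 0.05,
                         element_height_mm = 5,
                         focus_depth_mm = 70,
                         fractional_bandwidth = 0.6,
                         beam_sigma_mm = 0.4,
                         depth_origin_mm = 45, depth_span_mm = 50,
                         lateral_origin_mm = NULL,
                         lateral_center_mm = 30,
                         sound_speed_m_s = 1540) {
  stopifnot(sampling_frequency_hz > 2 * center_frequency_hz,
            n_lines >= 2, lateral_spacing_mm > 0,
            fractional_bandwidth > 0, beam_sigma_mm > 0,
            depth_span_mm > 0, depth_origin_mm >= 0, sound_speed_m_s > 0)
  width <- (n_lines - 1) * lateral_spacing_mm
  if (is.null(lateral_origin_mm))
    lateral_origin_mm <- lateral_center_mm - width / 2
  n_samples <- ceiling(2 * depth_span_mm * 1e-3 / sound_speed_m_s *
                         sampling_frequency_hz)
  structure(list(center_frequency_hz = center_frequency_hz,
                 sampling_frequency_hz = sampling_frequency_hz,
                 n_lines = as.integer(n_lines),
                 lateral_spacing_mm = lateral_spacing_mm,
                 pitch_mm = pitch_mm, kerf_mm = kerf_mm,
                 element_height_mm = element_height_mm,
                 focus_depth_mm = focus_depth_mm,
                 fractional_bandwidth = fractional_bandwidth,
                 beam_sigma_mm = beam_sigma_mm,
                 depth_origin_mm = depth_origin_mm,
                 depth_span_mm = depth_span_mm,
                 lateral_origin_mm = lateral_origin_mm,
                 sound_speed_m_s = sound_speed_m_s,
                 n_samples = as.integer(n_samples)),
            class = "probe_config")
}

#' @export
print.probe_config <- function(x, ...) {
  cat(sprintf("Probe: %g MHz / fs %g MHz, %d lines @ %g mm, depth [%g, %g] mm (%d samples)\n",
              x$center_frequency_hz / 1e6, x$sampling_frequency_hz / 1e6,
              x$n_lines, x$lateral_spacing_mm, x$depth_origin_mm,
              x$depth_origin_mm + x$depth_span_mm, x$n_samples))
  invisible(x)
}

# run expr with a private RNG stream; global .Random.seed is restored
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Seed random point scatterers over the imaged region
#'
#' Uniform random positions over the imaged window with standard-normal
#' amplitudes; amplitudes of scatterers inside the tumor are set to zero so
#' the tumor appears hypoechoic.  Reproducible for a fixed seed.
#'
#' @param geometry A [phantom_geometry()].
#' @param probe A [probe_config()] defining the imaged region.
#' @param density Scatterers per mm^2 of imaged area (> 0).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `scatterer_set`: data frame columns
#'   `axial_mm`, `lateral_mm`, `amplitude`.
#' @export
seed_scatterers <- function(geometry, probe, density = 10, seed = NULL) {
  stopifnot(inherits(geometry, "phantom_geometry"),
            inherits(probe, "probe_config"))
  if (!is.numeric(density) || density <= 0)
    stop("seed_scatterers: density must be positive")
  z0 <- probe$depth_origin_mm
  z1 <- min(z0 + probe$depth_span_mm, geometry$axial_mm)
  x0 <- max(probe$lateral_origin_mm, 0)
  x1 <- min(probe$lateral_origin_mm +
              (probe$n_lines - 1) * probe$lateral_spacing_mm,
            geometry$lateral_mm)
  n <- round(density * (z1 - z0) * (x1 - x0))
  s <- with_seed(seed, {
    data.frame(axial_mm = stats::runif(n, z0, z1),
               lateral_mm = stats::runif(n, x0, x1),
               amplitude = stats::rnorm(n))
  })
  mid <- geometry$lateral_mm / 2
  inside <- s$axial_mm >= geometry$tumor_axial[1] &
    s$axial_mm <= geometry$tumor_axial[2] &
    abs(s$lateral_mm - mid) <= geometry$tumor_lateral_mm / 2
  s$amplitude[inside] <- 0
  class(s) <- c("scatterer_set", "data.frame")
  s
}

#' Displace scatterers by an interpolated displacement field
#'
#' Shifts every scatterer by the bilinearly interpolated (axial, lateral)
#' displacement; amplitudes are unchanged.  With `probe_frame = TRUE`
#' (the default, matching how a clinical probe sees compressed tissue) the
#' axial displacements are first re-expressed relative to the moving
#' probe--tissue interface, i.e. the field value at depth 0 of the same
#' lateral position is subtracted, so material at the probe face does not
#' move in frame coordinates.
#'
#' @param scatterers A [seed_scatterers()] set.
#' @param field A `displacement_field` covering all scatterer positions.
#' @param probe_frame Re-reference axial displacement to the probe face?
#' @return A `scatterer_set` with displaced positions.
#' @export
displace_scatterers <- function(scatterers, field, probe_frame = TRUE) {
  stopifnot(inherits(scatterers, "scatterer_set"),
            inherits(field, "displacement_field"))
  ux <- interp_bilinear(field$axial_mm, field$lateral_mm, field$ux_mm,
                        scatterers$axial_mm, scatterers$lateral_mm)
  uy <- interp_bilinear(field$axial_mm, field$lateral_mm, field$uy_mm,
                        scatterers$axial_mm, scatterers$lateral_mm)
  if (probe_frame) {
    u0 <- interp_bilinear(field$axial_mm, field$lateral_mm, field$ux_mm,
                          rep(field$axial_mm[1], nrow(scatterers)),
                          scatterers$lateral_mm)
    ux <- ux - u0
  }
  out <- scatterers
  out$axial_mm <- scatterers$axial_mm + ux
  out$lateral_mm <- scatterers$lateral_mm + uy
  out
}

# Gaussian-modulated pulse sampled at fs; +- 4 sigma support
probe_pulse <- function(probe) {
  fs <- probe$sampling_frequency_hz
  fc <- probe$center_frequency_hz
  sigma_f <- probe$fractional_bandwidth * fc / 2.355   # -6 dB width -> sd
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(4 * sigma_t * fs)
  t <- (-half:half) / fs
  exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * fc * t)
}

# FFT-based linear convolution of each column of M with kernel k, centered
conv_lines <- function(M, k) {
  n <- nrow(M); nk <- length(k); nf <- stats::nextn(n + nk - 1L, 2)
  K <- stats::fft(c(k, numeric(nf - nk)))
  P <- rbind(M, matrix(0, nf - n, ncol(M)))
  out <- Re(stats::mvfft(stats::mvfft(P) * K, inverse = TRUE)) / nf
  ctr <- (nk + 1L) %/% 2L
  out[ctr:(ctr + n - 1L), , drop = FALSE]
}

#' Synthesize an RF frame from a scatterer set
#'
#' Convolutional point-spread-function model: every scatterer contributes a
#' Gaussian-enveloped sinusoid at its round-trip delay 2 z / c, weighted by
#' its amplitude and by a lateral Gaussian across neighboring scan lines.
#' Sub-sample delays are preserved by linear splitting between adjacent
#' samples before convolution with the pulse.  Deterministic given the set
#' and configuration.
#'
#' @param scatterers A `scatterer_set`.
#' @param probe A [probe_config()].
#' @param time_s Deformation-state label stored with the frame.
#' @return An object of class `rf_frame`: list with `samples`
#'   (n_samples x n_lines matrix) and acquisition metadata.
#' @export
synthesize_rf <- function(scatterers, probe, time_s = 0) {
  stopifnot(inherits(scatterers, "scatterer_set"),
            inherits(probe, "probe_config"))
  if (nrow(scatterers) == 0) stop("synthesize_rf: empty scatterer set")
  ns <- probe$n_samples; nl <- probe$n_lines
  fs <- probe$sampling_frequency_hz; c0 <- probe$sound_speed_m_s
  act <- scatterers[scatterers$amplitude != 0, , drop = FALSE]
  img <- matrix(0, ns, nl)
  if (nrow(act) > 0) {
    # fractional sample of the round-trip delay, 1-based
    samp <- (2 * (act$axial_mm - probe$depth_origin_mm) * 1e-3 / c0) * fs + 1
    line <- (act$lateral_mm - probe$lateral_origin_mm) /
      probe$lateral_spacing_mm + 1
    sig_l <- probe$beam_sigma_mm / probe$lateral_spacing_mm
    kl <- ceiling(3 * sig_l)
    s0 <- floor(samp); fr <- samp - s0
    idx <- integer(0); val <- numeric(0)
    for (dl in -kl:kl) {
      lc <- as.integer(round(line)) + dl
      w <- act$amplitude *
        exp(-((lc - line) * probe$lateral_spacing_mm)^2 /
              (2 * probe$beam_sigma_mm^2))
      ok <- lc >= 1L & lc <= nl
      for (ds in 0:1) {
        sj <- as.integer(s0) + ds
        wk <- w * (if (ds == 0) 1 - fr else fr)
        keep <- ok & sj >= 1L & sj <= ns & wk != 0
        idx <- c(idx, sj[keep] + (lc[keep] - 1L) * ns)
        val <- c(val, wk[keep])
      }
    }
    if (length(idx) > 0) {
      agg <- rowsum(val, idx)
      img[as.integer(rownames(agg))] <- agg[, 1]
    }
    img <- conv_lines(img, probe_pulse(probe))
  }
  structure(list(samples = img,
                 fs_hz = fs,
                 line_spacing_mm = probe$lateral_spacing_mm,
                 depth_origin_mm = probe$depth_origin_mm,
                 lateral_origin_mm = probe$lateral_origin_mm,
                 sound_speed_m_s = c0,
                 center_frequency_hz = probe$center_frequency_hz,
                 time_s = time_s),
            class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("RF frame at t = %g s: %d samples x %d lines, fs = %g MHz\n",
              x$time_s, nrow(x$samples), ncol(x$samples), x$fs_hz / 1e6))
  invisible(x)
}

# envelope of each line via the analytic signal (FFT Hilbert transform)
rf_envelope <- function(samples) {
  n <- nrow(samples)
  if (n < 2) return(abs(samples))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::mvfft(stats::mvfft(samples) * h, inverse = TRUE) / n)
}

#' B-mode image from an RF frame
#'
#' Envelope detection via the analytic-signal magnitude, normalization to
#' the frame maximum, and log compression to \[0, 1\] over the given dynamic
#' range.  An all-zero frame maps to an all-zero image.
#'
#' @param frame An `rf_frame`.
#' @param dynamic_range_db Dynamic range of the display mapping, dB (> 0).
#' @return Matrix (samples x lines) with values in \[0, 1\].
#' @export
bmode <- function(frame, dynamic_range_db = 40) {
  stopifnot(inherits(frame, "rf_frame"), dynamic_range_db > 0)
  env <- rf_envelope(frame$samples)
  mx <- max(env)
  if (mx == 0) return(env)
  db <- 20 * log10(pmax(env / mx, 10^(-dynamic_range_db / 20 - 1)))
  pmax(1 + db / dynamic_range_db, 0)
}

#' Read or write an RF frame as plain text
#'
#' Same self-describing text container as [write_displacement_field()]:
#' `# key: value` metadata followed by the sample matrix as a
#' tab-separated block with 17 significant digits (bit-exact round trip).
#'
#' @param frame An `rf_frame`.
#' @param path Output file.
#' @return `read_rf_frame()`: the reconstructed frame.
#' @export
write_rf_frame <- function(frame, path) {
  stopifnot(inherits(frame, "rf_frame"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c("fs_hz", "line_spacing_mm", "depth_origin_mm",
            "lateral_origin_mm", "sound_speed_m_s", "center_frequency_hz",
            "time_s")
  writeLines(c("# elastinv rf_frame v1",
               vapply(meta, function(k)
                 sprintf("# %s: %.17g", k, frame[[k]]), "")), con)
  utils::write.table(format(frame$samples, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_rf_frame
#' @export
read_rf_frame <- function(path) {
  lines <- readLines(path)
  meta_ln <- grep("^# [a-z_]+: ", lines, value = TRUE)
  keys <- sub("^# ([a-z_]+): .*$", "\\1", meta_ln)
  vals <- as.numeric(sub("^# [a-z_]+: ", "", meta_ln))
  body <- lines[!startsWith(lines, "#")]
  samples <- matrix(as.numeric(unlist(strsplit(body, "\t"))),
                    nrow = length(body), byrow = TRUE)
  out <- c(list(samples = samples), as.list(stats::setNames(vals, keys)))
  class(out) <- "rf_frame"
  out
}
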