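# shared fixtures: small scenes keep the RF/tracking tests fast

tiny_probe <- function(n_lines = 48, lateral_spacing_mm = 0.2,
                       depth_origin_mm = 60, depth_span_mm = 20, ...) {
  probe_config(n_lines = n_lines, lateral_spacing_mm = lateral_spacing_mm,
               depth_origin_mm = depth_origin_mm,
               depth_span_mm = depth_span_mm, ...)
}

# wrap a bare matrix as an rf_frame (synthetic tracking scenes)
as_rf_frame <- function(samples, fs_hz = 100e6, line_spacing_mm = 0.2,
                        depth_origin_mm = 0) {
  structure(list(samples = samples, fs_hz = fs_hz,
                 line_spacing_mm = line_spacing_mm,
                 depth_origin_mm = depth_origin_mm,
                 lateral_origin_mm = 0, sound_speed_m_s = 1540,
                 center_frequency_hz = 3.5e6, time_s = 0),
            class = "rf_frame")
}

# band-limited speckle matrix (filtered white noise at the carrier)
speckle_matrix <- function(ns, nl, seed) {
  set.seed(seed)
  x <- matrix(stats::rnorm(ns * nl), ns, nl)
  t <- seq(-40, 40) / 100e6
  pulse <- exp(-t^2 / (2 * (0.18e-6)^2)) * cos(2 * pi * 3.5e6 * t)
  apply(x, 2, function(col)
    stats::filter(col, pulse, sides = 2, circular = TRUE))
}

# frequency-domain sub-sample axial shift of every line
shift_lines_subsample <- function(M, delta) {
  n <- nrow(M)
  k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n
  ph <- exp(-2i * pi * k * delta / n)
  Re(stats::mvfft(stats::mvfft(M) * ph, inverse = TRUE)) / n
}

reference_tumor <- function() mr_params(10000, 6667, name = "tumor")
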