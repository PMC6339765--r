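geom <- phantom_geometry()
mats <- breast_materials()
ld <- load_spec()

test_that("geometry and load validation catch malformed inputs", {
  expect_error(phantom_geometry(layers = c(fat = 30, fibroglandular = 80)),
               "sum")
  expect_error(phantom_geometry(tumor_axial = c(10, 75)), "single layer")
  expect_error(load_spec(frequency_hz = 0), "frequency_hz")
  expect_equal(traction_at(ld, 0), 0)
  expect_equal(traction_at(ld, 2.5), 5000)  # quarter period of 0.1 Hz
})

test_that("layer stretches solve the stress law and are stress-continuous", {
  s0 <- solve_layer_stretches(geom, mats, 0)
  expect_true(all(s0 == 1))
  # round trip through the forward stress law, single layer
  sig_star <- cauchy_stress_uniaxial(mats$tumor, 0.95)
  s <- solve_layer_stretches(geom, mats, -sig_star)
  expect_equal(unname(s["tumor"]), 0.95, tolerance = 1e-8)
  # continuity: every layer's stress equals the applied stress
  tr <- 3000
  s <- solve_layer_stretches(geom, mats, tr)
  for (nm in names(s))
    expect_lt(abs(cauchy_stress_uniaxial(mats[[nm]], s[nm]) - (-tr)), 1e-6)
  expect_error(solve_layer_stretches(geom, mats, 1e9), "bracketed")
  expect_error(solve_layer_stretches(geom, mats["fat"], 100), "material")
})

test_that("displacement field obeys fixed boundary, linear limit, monotonicity", {
  # zero crossing of the sinusoid gives a zero field
  f0 <- displacement_field_at(geom, mats, ld, 5)  # sin(pi) = 0
  expect_equal(max(abs(f0$ux_mm)), 0, tolerance = 1e-12)
  f <- displacement_field_at(geom, mats, ld, 2.5)
  expect_equal(unname(f$ux_mm[nrow(f$ux_mm), ]),
               rep(0, length(f$lateral_mm)))   # fixed face
  # homogeneous phantom, tiny load: u linear in depth, slope -traction/E
  hg <- phantom_geometry(layers = c(fat = 100), tumor_axial = c(65, 75))
  hmats <- list(fat = mats$fat, tumor = mats$fat)
  tiny <- load_spec(amplitude_pa = 20)  # strain ~1e-3
  fh <- displacement_field_at(hg, hmats, tiny, 2.5)
  slope <- diff(fh$ux_mm[, 1]) / diff(fh$axial_mm)
  expect_equal(mean(slope), 20 / youngs_from_mr(mats$fat),
               tolerance = 0.01)
  expect_lt(diff(range(slope)), 1e-4)
  # |axial displacement| grows with |traction|
  u1 <- max(abs(displacement_field_at(geom, mats, ld, 8.0)$ux_mm))
  u2 <- max(abs(displacement_field_at(geom, mats, ld, 9.5)$ux_mm))
  expect_gt(u1, u2)  # |sin| larger at 8.0 s than at 9.5 s
  # quasi-static: field depends only on sin(2 pi f t)
  f_a <- displacement_field_at(geom, mats, ld, 8.0)
  f_b <- displacement_field_at(geom, mats, ld, 8.0 + 10)  # +1 period
  expect_equal(f_a$ux_mm, f_b$ux_mm, tolerance = 1e-12)
})

test_that("elastic reference scales as 1/E and exists per instant", {
  expect_equal(max(abs(elastic_reference_field(geom, mats,
                                               load_spec(amplitude_pa = 0),
                                               8.0)$ux_mm)), 0)
  tiny <- load_spec(amplitude_pa = 20)
  pts <- tumor_points(geom)
  ref_pt <- data.frame(axial_mm = geom$tumor_axial[2], lateral_mm = 30)
  rel <- function(e) {
    f <- elastic_reference_field(geom, mats, tiny, 2.5, e_pa = e)
    sample_axial(f, pts) - sample_axial(f, ref_pt)
  }
  expect_equal(rel(500) / rel(1000), rep(2, 12), tolerance = 0.01)
  fields <- lapply(ld$sample_times_s, function(t)
    elastic_reference_field(geom, mats, ld, t))
  expect_length(fields, 8)
  expect_equal(vapply(fields, function(f) f$time_s, 0), ld$sample_times_s)
})

test_that("sample_axial matches an independent bilinear interpolation", {
  f <- displacement_field_at(geom, mats, ld, 8.0)
  # constant / zero fields
  fz <- f; fz$ux_mm[] <- 0
  expect_equal(sample_axial(fz, tumor_points(geom)), rep(0, 12))
  fc <- f; fc$ux_mm[] <- 3.25
  expect_equal(sample_axial(fc, tumor_points(geom)), rep(3.25, 12))
  # off-grid point against a hand-rolled bilinear formula
  p <- data.frame(axial_mm = 67.3, lateral_mm = 30.6)
  iz <- findInterval(p$axial_mm, f$axial_mm)
  ix <- findInterval(p$lateral_mm, f$lateral_mm)
  tz <- (p$axial_mm - f$axial_mm[iz]) / diff(f$axial_mm[iz + 0:1])
  tx <- (p$lateral_mm - f$lateral_mm[ix]) / diff(f$lateral_mm[ix + 0:1])
  o <- f$ux_mm[iz, ix] * (1 - tz) * (1 - tx) +
    f$ux_mm[iz + 1, ix] * tz * (1 - tx) +
    f$ux_mm[iz, ix + 1] * (1 - tz) * tx +
    f$ux_mm[iz + 1, ix + 1] * tz * tx
  expect_equal(sample_axial(f, p), o)
  expect_error(sample_axial(f, data.frame(axial_mm = 150, lateral_mm = 30)),
               "outside")
  # time-major, point-minor ordering over two instants
  fields <- lapply(c(8.0, 9.0), function(t)
    displacement_field_at(geom, mats, ld, t))
  v <- sample_axial(fields, tumor_points(geom))
  expect_length(v, 24)
  expect_equal(v[1:12], sample_axial(fields[[1]], tumor_points(geom)))
})

test_that("displacement fields round-trip through the text format", {
  f <- displacement_field_at(geom, mats, ld, 8.25)
  tmp <- tempfile(fileext = ".txt")
  write_displacement_field(f, tmp)
  g <- read_displacement_field(tmp)
  expect_identical(g$ux_mm, f$ux_mm)
  expect_identical(g$uy_mm, f$uy_mm)
  expect_identical(g$axial_mm, f$axial_mm)
  expect_equal(g$time_s, 8.25)
  expect_equal(g$role, "post")
})
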