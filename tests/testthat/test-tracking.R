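test_that("identical frames track to zero shift with unit correlation", {
  M <- speckle_matrix(600, 24, seed = 11)
  pre <- as_rf_frame(M)
  cfg <- tracking_config(window_samples = 81, window_lines = 5,
                         search_axial = 10, search_lateral = 2,
                         subsample = "none")
  est <- ncc_track(pre, pre, cfg)
  ok <- !est$flagged
  expect_true(any(ok))
  expect_equal(est$axial_shift_samples[ok], rep(0, sum(ok)))
  expect_true(all(est$correlation[ok] > 0.999))
})

test_that("integer-sample rigid shifts are recovered exactly", {
  M <- speckle_matrix(700, 20, seed = 12)
  pre <- as_rf_frame(M)
  for (k in c(3, 9)) {
    post <- as_rf_frame(rbind(matrix(0, k, ncol(M)), M[1:(nrow(M) - k), ]))
    cfg <- tracking_config(window_samples = 81, window_lines = 5,
                           search_axial = 15, search_lateral = 2,
                           subsample = "none")
    est <- ncc_track(pre, post, cfg)
    keep <- !est$flagged & est$axial_mm > 0.2 & est$axial_mm < 4.8
    expect_true(all(est$axial_shift_samples[keep] == k))
  }
})

test_that("parabolic refinement resolves a 0.3-sample shift", {
  M <- speckle_matrix(800, 16, seed = 13)
  pre <- as_rf_frame(M)
  post <- as_rf_frame(shift_lines_subsample(M, 0.3))
  cfg <- tracking_config(window_samples = 101, window_lines = 5,
                         search_axial = 6, search_lateral = 1,
                         subsample = "parabolic")
  est <- ncc_track(pre, post, cfg)
  keep <- !est$flagged & est$axial_mm > 0.5 & est$axial_mm < 5.5
  expect_lt(abs(mean(est$axial_shift_samples[keep]) - 0.3), 0.1)
})

test_that("guided search equals exhaustive search with fewer evaluations", {
  M <- speckle_matrix(600, 20, seed = 14)
  pre <- as_rf_frame(M)
  k <- 5
  post <- as_rf_frame(rbind(matrix(0, k, ncol(M)), M[1:(nrow(M) - k), ]))
  base <- list(window_samples = 61, window_lines = 5,
               search_axial = 20, search_lateral = 3, subsample = "none")
  g <- ncc_track(pre, post, do.call(tracking_config, c(base, guided = TRUE)))
  e <- ncc_track(pre, post, do.call(tracking_config, c(base, guided = FALSE)))
  keep <- !g$flagged
  expect_equal(g$axial_shift_samples[keep], e$axial_shift_samples[keep])
  expect_equal(g$lateral_shift_lines[keep], e$lateral_shift_lines[keep])
  expect_lt(attr(g, "n_evals"), attr(e, "n_evals"))
})

test_that("degenerate windows are flagged, not fatal", {
  M <- speckle_matrix(400, 12, seed = 15)
  M[1:150, ] <- 0   # a dead zone
  pre <- as_rf_frame(M)
  cfg <- tracking_config(window_samples = 61, window_lines = 5,
                         search_axial = 5, search_lateral = 1)
  est <- ncc_track(pre, pre, cfg)
  dead <- est$axial_mm < 0.6
  expect_true(all(est$flagged[dead]))
  expect_true(any(!est$flagged))
})

test_that("strain is the least-squares slope of displacement vs depth", {
  # fabricate an estimate grid with a linear ramp: slope 0.02
  z <- seq(1, 20, by = 0.5)
  est <- data.frame(axial_mm = z, lateral_mm = 0,
                    axial_shift_samples = 0, lateral_shift_lines = 0,
                    axial_shift_mm = 0.02 * z, lateral_shift_mm = 0,
                    correlation = 1, flagged = FALSE)
  class(est) <- c("displacement_estimate", "data.frame")
  st <- strain_from_displacement(est, kernel = 5)
  expect_equal(st$strain, rep(0.02, nrow(st)), tolerance = 1e-12)
  est$axial_shift_mm <- 1.5  # constant displacement: zero strain
  expect_equal(strain_from_displacement(est, kernel = 4)$strain,
               rep(0, nrow(st) + 1), tolerance = 1e-12)
  expect_error(strain_from_displacement(est, kernel = 100), "kernel")
})

test_that("displacement error metric matches its definition", {
  est <- data.frame(axial_mm = 1:10, lateral_mm = 0,
                    axial_shift_samples = 0, lateral_shift_lines = 0,
                    axial_shift_mm = seq(0.1, 1, by = 0.1),
                    lateral_shift_mm = 0, correlation = 1, flagged = FALSE)
  class(est) <- c("displacement_estimate", "data.frame")
  truth <- est$axial_shift_mm
  expect_equal(displacement_error(est, truth)$percent, 0)
  est2 <- est; est2$axial_shift_mm <- truth * 1.1
  expect_equal(displacement_error(est2, truth)$percent, 10)
  # randomized perturbation: MAE ~ E|N(0, s)| = s sqrt(2/pi)
  set.seed(99)
  s <- 0.05
  reps <- replicate(200, {
    e3 <- est; e3$axial_shift_mm <- truth + rnorm(10, 0, s)
    displacement_error(e3, truth)$mae_mm
  })
  expect_equal(mean(reps), s * sqrt(2 / pi), tolerance = 0.05)
})

test_that("RF tracking beats envelope tracking across speckle realizations", {
  geom <- phantom_geometry()
  mats <- breast_materials()
  # imaged region away from the tumor; ~1% strain compression
  pr <- tiny_probe(n_lines = 40, depth_origin_mm = 20, depth_span_mm = 15)
  tiny <- load_spec(amplitude_pa = 200)
  f <- displacement_field_at(geom, mats, tiny, 2.5)
  cfg <- tracking_config(search_axial = 60, search_lateral = 2,
                         window_lines = 5)
  err_rf <- err_bm <- numeric(10)
  for (i in 1:10) {
    s <- seed_scatterers(geom, pr, density = 8, seed = 100 + i)
    pre <- synthesize_rf(s, pr)
    post <- synthesize_rf(displace_scatterers(s, f), pr)
    grid <- expand.grid(axial_mm = seq(22, 33, by = 1.5),
                        lateral_mm = seq(27, 33, by = 1.5))
    est_rf <- ncc_track(pre, post, cfg, centers = grid)
    pre_b <- pre; pre_b$samples <- elastinv:::rf_envelope(pre$samples)
    post_b <- post; post_b$samples <- elastinv:::rf_envelope(post$samples)
    est_bm <- ncc_track(pre_b, post_b, cfg, centers = grid)
    err_rf[i] <- displacement_error(est_rf, f)$mae_mm
    err_bm[i] <- displacement_error(est_bm, f)$mae_mm
  }
  expect_true(all(is.finite(c(err_rf, err_bm))))
  expect_lt(mean(err_rf), mean(err_bm))
})
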