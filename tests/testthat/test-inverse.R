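geom <- phantom_geometry()
mats <- breast_materials()
ld <- load_spec()

test_that("modulus regression recovers linear scalings exactly", {
  d <- c(-0.1, -0.2, -0.35, -0.5)
  expect_equal(estimate_modulus(d, d), 1)
  expect_equal(estimate_modulus(d, d / 2), 2)
  expect_equal(estimate_modulus(d, d / 2, e_ref_pa = 10), 20)
  expect_error(estimate_modulus(rep(0, 4), d), "zero norm")
  expect_error(estimate_modulus(d, -d), "slope")
})

test_that("a linear-elastic tumor round-trips through the forward model", {
  lin <- list(fat = mats$fat, fibroglandular = mats$fibroglandular,
              tumor = linear_elastic(1e5))
  tiny <- load_spec(amplitude_pa = 50)  # small load
  obs <- simulate_observations(geom, lin, tiny)
  e <- estimate_modulus(obs$ref_disp, obs$y_realt)
  expect_equal(e, 1e5, tolerance = 0.01)
})

test_that("stress sets are proportional, with calibrated jitter", {
  expect_equal(build_stress_set(1e5, 0.1), 1e4)
  eps <- seq(-0.1, -0.01, by = 0.01)
  expect_equal(build_stress_set(2e4, eps), 2e4 * eps)
  sig <- build_stress_set(1e5, rep(0.05, 1e4), jitter = 0.01, seed = 42)
  rel <- sig / (1e5 * 0.05) - 1
  expect_equal(stats::sd(rel), 0.01, tolerance = 3 / sqrt(2e4))
  expect_equal(mean(rel), 0, tolerance = 3 * 0.01 / sqrt(1e4))
})

test_that("fit_mr inverts exact Mooney-Rivlin data to machine precision", {
  truth <- reference_tumor()
  eps <- -seq(0.01, 0.10, by = 0.01)
  sig <- stress_from_strain(truth, eps)
  fit <- fit_mr(eps, sig)
  expect_equal(fit$c10, truth$c10, tolerance = 1e-9)
  expect_equal(fit$c01, truth$c01, tolerance = 1e-9)
  # permutation invariance
  p <- sample(length(eps))
  fit2 <- fit_mr(eps[p], sig[p])
  expect_equal(fit2$c10, fit$c10)
  # agrees with stats::lm on the same linearized regression
  lam <- 1 + eps
  g <- 2 * (lam^2 - 1 / lam)
  co <- unname(coef(stats::lm(I(sig / g) ~ I(1 / lam))))
  expect_equal(c(fit$c10, fit$c01), co, tolerance = 1e-8)
  expect_error(fit_mr(rep(0.1, 5), rep(1, 5)), "distinct")
  expect_error(fit_mr(c(0, 0.1), c(0, 1)), "zero strain")
})

test_that("fitting a linear law at small strain recovers E/6 in the sum", {
  e_star <- 6e4
  eps <- 1e-3 * (1:10)
  fit <- fit_mr(eps, e_star * eps)
  expect_equal(fit$c10 + fit$c01, e_star / 6, tolerance = 0.02)
})

test_that("the iteration decays strains geometrically and terminates", {
  obs <- simulate_observations(geom, mats, ld)
  # impossible tolerances, no decay: runs to the cap, not converged
  res <- mr_iterate(obs, geom, mats, ld,
                    schedule = strain_schedule(decay = 1.0),
                    tol = mr_tolerances(e_displacement = 1e-15,
                                        e_elastic = 1e-15,
                                        max_iterations = 5))
  expect_false(res$converged)
  expect_equal(res$iterations, 5)
  expect_equal(unique(res$trace$strain_scale), 0.6)
  res2 <- mr_iterate(obs, geom, mats, ld,
                     schedule = strain_schedule(decay = 0.8),
                     tol = mr_tolerances(e_displacement = 1e-15,
                                         e_elastic = 1e-15,
                                         max_iterations = 4))
  expect_equal(res2$trace$strain_scale,
               0.6 * 0.8^(0:3), tolerance = 1e-12)
})

test_that("noise-free self-consistent data recover modulus and stiffness sum", {
  obs <- simulate_observations(geom, mats, ld)
  res <- mr_iterate(obs, geom, mats, ld)
  expect_true(res$converged)
  expect_lte(res$iterations, 50)
  e_true <- youngs_from_mr(mats$tumor)
  # the effective modulus and C10 + C01 are recovered tightly ...
  expect_lt(percent_error(e_true, res$e_realt), 2)
  expect_lt(percent_error(e_true, youngs_from_mr(res$params)), 2)
  expect_lt(percent_error(res$e_realt, res$trace$e_estt[res$iterations]), 1)
  # ... and the displacement residual shrinks monotonically
  expect_true(all(diff(res$trace$resid_disp) <= 1e-12))
  # convergence satisfied the active (exact-mode) criterion
  k <- res$iterations
  expect_lte(res$trace$resid_disp[k], res$tolerances$e_displacement)
  expect_lte(res$trace$resid_elastic[k], res$tolerances$e_elastic)
})

test_that("a linear-elastic tumor yields 6(C10+C01) within 2% of E*", {
  lin <- list(fat = mats$fat, fibroglandular = mats$fibroglandular,
              tumor = linear_elastic(1e5))
  obs <- simulate_observations(geom, lin, ld)
  res <- mr_iterate(obs, geom, mats, ld)
  expect_true(res$converged)
  expect_equal(res$e_realt, 1e5, tolerance = 1e-6)
  expect_lt(percent_error(1e5, youngs_from_mr(res$params)), 2)
})

test_that("percent error matches its definition", {
  expect_equal(percent_error(5, 5), 0)
  expect_equal(percent_error(200, 150), 25)
  expect_equal(percent_error(-200, -150), 25)
  expect_error(percent_error(0, 1), "nonzero")
})
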