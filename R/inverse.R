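#' Observation set for the inversion
#'
#' Pairs the measured axial displacements of the selected tumor points at
#' the selected instants (`y_realt`) with the congruent displacements of the
#' unit-modulus elastic reference tumor (`ref_disp`).  Both vectors are
#' ordered time-major, point-minor, and are expressed relative to the
#' tumor's distal (probe-far) interface so that they isolate the tumor's
#' own deformation (see the methods vignette).
#'
#' @param y_realt Measured axial displacements, mm.
#' @param ref_disp Elastic-reference displacements, mm (not all zero).
#' @param points Data frame of the sampled points (`axial_mm`,
#'   `lateral_mm`).
#' @param times_s Sampling instants, s.
#' @param e_ref_pa Modulus of the elastic reference, Pa (default 1).
#' @return An object of class `observation_set`.
#' @export
observation_set <- function(y_realt, ref_disp, points, times_s,
                            e_ref_pa = 1) {
  stopifnot(is.numeric(y_realt), is.numeric(ref_disp),
            length(y_realt) == length(ref_disp),
            length(y_realt) == nrow(as.data.frame(points)) * length(times_s))
  if (all(ref_disp == 0))
    stop("observation_set: reference displacements are all zero")
  structure(list(y_realt = y_realt, ref_disp = ref_disp,
                 points = as.data.frame(points), times_s = times_s,
                 e_ref_pa = e_ref_pa),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("Observation set: %d points x %d instants (|y| max %.4g mm)\n",
              nrow(x$points), length(x$times_s), max(abs(x$y_realt))))
  invisible(x)
}

#' Effective Young's modulus from displacement regression
#'
#' Regresses the measured displacements on the elastic-reference
#' displacements through the origin, s = (D'D)^-1 D'Y, and converts the
#' slope to a modulus.  Under linear-elastic scaling the tumor displacement
#' is proportional to 1/E, so Y = D (E_ref / E) and E = E_ref / s.
#'
#' @param ref_disp Reference displacement vector D (positive norm).
#' @param y Measured displacement vector, congruent with `ref_disp`.
#' @param e_ref_pa Reference modulus, Pa.
#' @return Estimated modulus, Pa.
#' @export
estimate_modulus <- function(ref_disp, y, e_ref_pa = 1) {
  stopifnot(is.numeric(ref_disp), is.numeric(y),
            length(ref_disp) == length(y), length(y) >= 1)
  dd <- sum(ref_disp^2)
  if (dd == 0) stop("estimate_modulus: reference displacements have zero norm")
  s <- sum(ref_disp * y) / dd
  if (!is.finite(s) || s <= 0)
    stop("estimate_modulus: non-positive regression slope (", signif(s, 4),
         "); measured and reference displacements are inconsistent")
  e_ref_pa / s
}

#' Construct a stress set from a strain set
#'
#' sigma_i = E epsilon_i, optionally jittered multiplicatively by
#' (1 + N(0, jitter)) per element (seeded) so the set conforms less rigidly
#' to the linear law.
#'
#' @param e_pa Modulus, Pa.
#' @param strains Nonzero strain set.
#' @param jitter Relative standard deviation of the multiplicative jitter
#'   (0 disables it).
#' @param seed Integer seed for the jitter draws, or `NULL`.
#' @return Stress vector, Pa.
#' @export
build_stress_set <- function(e_pa, strains, jitter = 0, seed = NULL) {
  stopifnot(is.numeric(strains), all(strains != 0), jitter >= 0)
  sig <- e_pa * strains
  if (jitter > 0)
    sig <- sig * (1 + with_seed(seed, stats::rnorm(length(sig), 0, jitter)))
  sig
}

#' Least-squares Mooney-Rivlin fit of a stress-strain set
#'
#' Fits sigma = 2 ((1+eps)^2 - (1+eps)^-1) (C10 + (1+eps)^-1 C01) by linear
#' least squares: with g(eps) = 2 ((1+eps)^2 - (1+eps)^-1), sigma/g is
#' regressed on \[1, (1+eps)^-1\] via the normal equations.
#'
#' @param strains Strain set (> -1, at least two distinct nonzero values).
#' @param stresses Congruent stress set, Pa.
#' @return An [mr_params()] object.
#' @export
fit_mr <- function(strains, stresses) {
  stopifnot(is.numeric(strains), is.numeric(stresses),
            length(strains) == length(stresses), length(strains) >= 2)
  if (any(strains <= -1)) stop("fit_mr: strains must be > -1")
  if (any(strains == 0)) stop("fit_mr: zero strain gives no information")
  lam <- 1 + strains
  if (length(unique(lam)) < 2)
    stop("fit_mr: need at least two distinct strains (design matrix rank < 2)")
  g <- 2 * (lam^2 - 1 / lam)
  z <- stresses / g
  X <- cbind(1, 1 / lam)
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-14)
    stop("fit_mr: design matrix numerically rank deficient")
  co <- drop(solve(XtX, crossprod(X, z)))
  mr_params(co[1], co[2], name = "fitted")
}

#' Strain schedule of the iterative algorithm
#'
#' The fictitious strain set used to construct stress-strain pairs: a set of
#' high strains in the first iteration, multiplied by a constant decay
#' factor each subsequent iteration.  The sign is normally resolved at run
#' time (`"auto"`) to the sign of the deformation the observations were
#' collected under.
#'
#' @param initial Initial strain magnitudes (default 10 values evenly
#'   spanning \[0.06, 0.60\]).
#' @param decay Per-iteration decay factor in (0, 1\].
#' @param jitter Relative stress jitter passed to [build_stress_set()].
#' @param seed Seed for the jitter draws.
#' @param sign `"auto"`, `+1` or `-1`.
#' @return An object of class `strain_schedule`.
#' @export
strain_schedule <- function(initial = seq(0.06, 0.60, length.out = 10),
                            decay = 0.9, jitter = 0, seed = NULL,
                            sign = "auto") {
  stopifnot(is.numeric(initial), all(is.finite(initial)), all(initial > 0),
            decay > 0, decay <= 1, jitter >= 0)
  if (!identical(sign, "auto")) stopifnot(sign %in% c(-1, 1))
  structure(list(initial = initial, decay = decay, jitter = jitter,
                 seed = seed, sign = sign),
            class = "strain_schedule")
}

#' Convergence tolerances of the iterative algorithm
#'
#' Absolute tolerances for exact mode (displacement and modulus residuals
#' against the observations) and successive-iterate tolerances for noisy
#' mode.  `NULL` entries are resolved at run time to the documented
#' defaults: 1% of max |y_realt| and 1% of E_realt for the absolute pair,
#' 0.1% for the successive-iterate (primed) pair.
#'
#' @param e_displacement,e_elastic Absolute tolerances (mm, Pa).
#' @param e_displacement_p,e_elastic_p Successive-iterate tolerances.
#' @param max_iterations Iteration cap.
#' @return An object of class `mr_tolerances`.
#' @export
mr_tolerances <- function(e_displacement = NULL, e_elastic = NULL,
                          e_displacement_p = NULL, e_elastic_p = NULL,
                          max_iterations = 50) {
  chk <- function(v) is.null(v) || (is.numeric(v) && v > 0)
  stopifnot(chk(e_displacement), chk(e_elastic), chk(e_displacement_p),
            chk(e_elastic_p), max_iterations >= 1)
  structure(list(e_displacement = e_displacement, e_elastic = e_elastic,
                 e_displacement_p = e_displacement_p,
                 e_elastic_p = e_elastic_p,
                 max_iterations = as.integer(max_iterations)),
            class = "mr_tolerances")
}

# forward-resimulated observation vector for candidate tumor material
observe_tumor <- function(geometry, materials, load, times_s, points,
                          reference = FALSE, e_ref_pa = 1) {
  pts <- as.data.frame(points)
  ref_pt <- data.frame(axial_mm = geometry$tumor_axial[2],
                       lateral_mm = pts$lateral_mm)
  unlist(lapply(times_s, function(t) {
    f <- if (reference)
      elastic_reference_field(geometry, materials, load, t, e_pa = e_ref_pa)
    else displacement_field_at(geometry, materials, load, t)
    sample_axial(f, pts) - sample_axial(f, ref_pt)
  }), use.names = FALSE)
}

#' Assemble observations from the forward model
#'
#' Convenience generator of a self-consistent [observation_set()]: samples
#' the forward model's tumor-point axial displacements (relative to the
#' tumor's distal interface) at the load's sample times, together with the
#' unit-modulus elastic-reference displacements.
#'
#' @param geometry A [phantom_geometry()].
#' @param materials Named material list including the true `tumor`.
#' @param load A [load_spec()].
#' @param points Sampled points; default [tumor_points()] (12).
#' @param e_ref_pa Reference modulus, Pa.
#' @return An `observation_set`.
#' @export
simulate_observations <- function(geometry, materials, load,
                                  points = tumor_points(geometry),
                                  e_ref_pa = 1) {
  y <- observe_tumor(geometry, materials, load, load$sample_times_s, points)
  d <- observe_tumor(geometry, materials, load, load$sample_times_s, points,
                     reference = TRUE, e_ref_pa = e_ref_pa)
  observation_set(y, d, points, load$sample_times_s, e_ref_pa)
}

#' Iterative Mooney-Rivlin parameter estimation
#'
#' The full iterative algorithm: (i) estimate the tumor's effective modulus
#' E_realt by regressing the measured displacements on the unit-modulus
#' elastic-reference displacements; (ii) construct a stress set sigma =
#' E_realt * eps over the scheduled strain set (optionally jittered); (iii)
#' fit (C10, C01) by least squares; (iv) re-simulate the phantom with the
#' candidate tumor, sample the same points/instants (Y_estt) and re-estimate
#' the modulus (E_estt); (v) test convergence - in `"exact"` mode the
#' residuals against (y_realt, E_realt), in `"noisy"` mode the differences
#' between successive iterates (both with the infinity norm on the
#' displacement vector); (vi) on failure multiply the strain set by the
#' decay factor and repeat.
#'
#' @param obs An [observation_set()].
#' @param geometry A [phantom_geometry()].
#' @param materials Named material list of the known (non-tumor) layers; any
#'   `tumor` entry is ignored and replaced by the iterates.
#' @param load A [load_spec()] (the observations' loading).
#' @param schedule A [strain_schedule()].
#' @param tol An [mr_tolerances()].
#' @param mode `"exact"` (noise-free observations) or `"noisy"`.
#' @return An object of class `estimation_result`: `e_realt`, final
#'   `params`, `converged`, `iterations`, the final `y_estt`, and a `trace`
#'   data frame with one row per iteration (strain scale, c10, c01, e_estt,
#'   residuals and successive differences).
#' @export
mr_iterate <- function(obs, geometry, materials, load,
                       schedule = strain_schedule(),
                       tol = mr_tolerances(),
                       mode = c("exact", "noisy")) {
  mode <- match.arg(mode)
  stopifnot(inherits(obs, "observation_set"),
            inherits(schedule, "strain_schedule"),
            inherits(tol, "mr_tolerances"))
  e_realt <- estimate_modulus(obs$ref_disp, obs$y_realt, obs$e_ref_pa)
  y_scale <- max(abs(obs$y_realt))
  e_disp <- if (is.null(tol$e_displacement)) 0.01 * y_scale else tol$e_displacement
  e_el <- if (is.null(tol$e_elastic)) 0.01 * e_realt else tol$e_elastic
  e_disp_p <- if (is.null(tol$e_displacement_p)) 0.001 * y_scale else tol$e_displacement_p
  e_el_p <- if (is.null(tol$e_elastic_p)) 0.001 * e_realt else tol$e_elastic_p
  sgn <- schedule$sign
  if (identical(sgn, "auto")) {
    # sign of the deformation the observations were collected under
    s_times <- -traction_at(load, obs$times_s)
    sgn <- sign(sum(s_times * abs(s_times)))
    if (sgn == 0) sgn <- 1
  }
  strains <- sgn * schedule$initial
  kmax <- tol$max_iterations
  trace <- data.frame(iteration = integer(0), strain_scale = numeric(0),
                      c10 = numeric(0), c01 = numeric(0),
                      e_estt = numeric(0), resid_disp = numeric(0),
                      resid_elastic = numeric(0), diff_disp = numeric(0),
                      diff_elastic = numeric(0), accepted = logical(0))
  prev_y <- NULL; prev_e <- NULL
  converged <- FALSE
  params <- NULL; y_estt <- NULL
  for (k in seq_len(kmax)) {
    sig <- build_stress_set(e_realt, strains, schedule$jitter,
                            if (is.null(schedule$seed)) NULL
                            else schedule$seed + k)
    params <- fit_mr(strains, sig)
    mats_k <- materials
    mats_k$tumor <- params
    y_estt <- observe_tumor(geometry, mats_k, load, obs$times_s, obs$points)
    e_estt <- estimate_modulus(obs$ref_disp, y_estt, obs$e_ref_pa)
    rd <- max(abs(y_estt - obs$y_realt))
    re <- abs(e_estt - e_realt)
    dd <- if (is.null(prev_y)) NA_real_ else max(abs(y_estt - prev_y))
    de <- if (is.null(prev_e)) NA_real_ else abs(e_estt - prev_e)
    ok <- if (mode == "exact") (rd <= e_disp && re <= e_el)
    else (!is.na(dd) && dd <= e_disp_p && de <= e_el_p)
    trace <- rbind(trace, data.frame(
      iteration = k, strain_scale = max(abs(strains)),
      c10 = params$c10, c01 = params$c01, e_estt = e_estt,
      resid_disp = rd, resid_elastic = re,
      diff_disp = dd, diff_elastic = de, accepted = ok))
    if (ok) { converged <- TRUE; break }
    prev_y <- y_estt; prev_e <- e_estt
    strains <- strains * schedule$decay
  }
  structure(list(e_realt = e_realt, params = params,
                 converged = converged, iterations = nrow(trace),
                 y_estt = y_estt, mode = mode,
                 tolerances = list(e_displacement = e_disp, e_elastic = e_el,
                                   e_displacement_p = e_disp_p,
                                   e_elastic_p = e_el_p),
                 trace = trace),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf(paste0("Mooney-Rivlin estimation (%s mode): %s after %d ",
                     "iteration(s)\n  E_realt = %.6g Pa; C10 = %.6g Pa, ",
                     "C01 = %.6g Pa (E = %.6g Pa)\n"),
              x$mode, if (x$converged) "converged" else "NOT converged",
              x$iterations, x$e_realt, x$params$c10, x$params$c01,
              youngs_from_mr(x$params)))
  invisible(x)
}

#' Percent error of an estimate
#'
#' 100 |true - est| / |true|, the error metric used in the result tables.
#'
#' @param true True value (nonzero).
#' @param est Estimate.
#' @return Percent error.
#' @export
percent_error <- function(true, est) {
  stopifnot(is.numeric(true), is.numeric(est))
  if (any(true == 0)) stop("percent_error: true value must be nonzero")
  100 * abs(true - est) / abs(true)
}
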