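#' End-to-end run configuration
#'
#' Bundles every stage's configuration.  `default_run_config()` reproduces
#' the headline study conditions: the three-material breast phantom, the
#' 5 kPa / 0.1 Hz sinusoidal load sampled at the eight instants
#' 7.75-9.50 s, the 3.5 MHz / 100 MHz probe with 512 lines at 0.08 mm, 12
#' tumor points, the default strain schedule and tolerances.
#'
#' @param geometry,materials,load,probe,tracking,schedule,tolerances Stage
#'   configurations (see the respective constructors).
#' @param n_points Number of tumor sampling points.
#' @param scatterer_density Scatterers per mm^2.
#' @param ladder_step_pa Traction increment of the multi-frame tracking
#'   ladder, Pa: tracked mode accumulates displacements over a sequence of
#'   frames whose surface traction changes by at most this much, keeping
#'   the inter-frame strain small enough for speckle correlation.
#' @param seed Master seed for scatterer seeding.
#' @return An object of class `run_config`.
#' @export
run_config <- function(geometry = phantom_geometry(),
                       materials = breast_materials(),
                       load = load_spec(),
                       probe = probe_config(),
                       tracking = tracking_config(),
                       schedule = strain_schedule(),
                       tolerances = mr_tolerances(),
                       n_points = 12,
                       scatterer_density = 10,
                       ladder_step_pa = 250,
                       seed = 1) {
  stopifnot(inherits(geometry, "phantom_geometry"),
            inherits(load, "load_spec"), inherits(probe, "probe_config"),
            inherits(tracking, "tracking_config"),
            inherits(schedule, "strain_schedule"),
            inherits(tolerances, "mr_tolerances"),
            n_points >= 1, scatterer_density > 0, ladder_step_pa > 0,
            length(seed) >= 1)
  structure(list(geometry = geometry, materials = materials, load = load,
                 probe = probe, tracking = tracking, schedule = schedule,
                 tolerances = tolerances, n_points = n_points,
                 scatterer_density = scatterer_density,
                 ladder_step_pa = ladder_step_pa, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with (possibly partial) sections `geometry`,
#'   `materials`, `load`, `probe`, `tracking`, `schedule`, `tolerances`,
#'   `pipeline`; omitted entries keep their defaults.  `materials` may be a
#'   path to a material CSV or a list of `{c10_pa, c01_pa}` entries.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 reads exponents like 3.5e6 (no sign) as strings; coerce them
  fix_num <- function(v) {
    if (is.character(v) && length(v) == 1 &&
        grepl("^[+-]?[0-9.]+([eE][+-]?[0-9]+)?$", v)) as.numeric(v) else v
  }
  take <- function(ctor, section) {
    args <- y[[section]]
    if (is.null(args)) ctor() else do.call(ctor, lapply(args, fix_num))
  }
  geom_args <- y$geometry
  if (!is.null(geom_args$layers)) geom_args$layers <- unlist(geom_args$layers)
  if (!is.null(geom_args$tumor_axial))
    geom_args$tumor_axial <- as.numeric(geom_args$tumor_axial)
  geometry <- if (is.null(geom_args)) phantom_geometry()
  else do.call(phantom_geometry, geom_args)
  materials <- if (is.null(y$materials)) breast_materials()
  else if (is.character(y$materials)) read_material_table(y$materials)
  else {
    ms <- lapply(names(y$materials), function(nm)
      mr_params(y$materials[[nm]]$c10_pa, y$materials[[nm]]$c01_pa, name = nm))
    stats::setNames(ms, names(y$materials))
  }
  if (!is.null(y$load$sample_times_s))
    y$load$sample_times_s <- as.numeric(y$load$sample_times_s)
  pl <- y$pipeline
  run_config(geometry = geometry, materials = materials,
             load = take(load_spec, "load"),
             probe = take(probe_config, "probe"),
             tracking = take(tracking_config, "tracking"),
             schedule = take(strain_schedule, "schedule"),
             tolerances = take(mr_tolerances, "tolerances"),
             n_points = if (is.null(pl$n_points)) 12 else pl$n_points,
             scatterer_density = if (is.null(pl$scatterer_density)) 10
             else pl$scatterer_density,
             seed = if (is.null(pl$seed)) 1 else pl$seed)
}

#' Run the full simulation-tracking-inversion pipeline
#'
#' Simulates the pre-deformation state and the eight post-deformation
#' states, synthesizes RF frames from a seeded scatterer phantom warped by
#' the forward displacement fields (probe coordinates), tracks the tumor
#' points plus a distal reference point in every frame pair, assembles the
#' observation vector (displacements relative to the tumor's distal
#' interface, so the probe-frame offset cancels), and runs the iterative
#' inversion.  With `use_tracking = FALSE` the tracking stage is bypassed
#' and the forward model's displacements are used directly (the
#' inverse-crime configuration).
#'
#' @param cfg A [run_config()].
#' @param use_tracking Track RF frames (`TRUE`) or bypass (`FALSE`)?
#' @param out_dir Optional directory for artifacts (observations, trace and
#'   result files).
#' @param mode Convergence mode passed to [mr_iterate()].
#' @return The [mr_iterate()] `estimation_result`, with the observation set
#'   attached as attribute `observations` (and, in tracked mode, the mean
#'   absolute tracking error in mm as attribute `tracking_mae_mm`).
#' @export
run_pipeline <- function(cfg, use_tracking = TRUE, out_dir = NULL,
                         mode = c("exact", "noisy")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "run_config"))
  geometry <- cfg$geometry; load <- cfg$load
  pts <- tumor_points(geometry, cfg$n_points)
  known <- cfg$materials
  obs_true <- simulate_observations(geometry, known, load, pts)
  tracking_mae <- NULL
  if (use_tracking) {
    tr <- track_ladder(cfg, pts)
    tracking_mae <- mean(abs(tr$y - obs_true$y_realt))
    obs <- observation_set(tr$y, obs_true$ref_disp, pts,
                           load$sample_times_s)
  } else {
    obs <- obs_true
  }
  res <- mr_iterate(obs, geometry, known, load, cfg$schedule,
                    cfg$tolerances, mode = mode)
  attr(res, "observations") <- obs
  if (!is.null(tracking_mae)) attr(res, "tracking_mae_mm") <- tracking_mae
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$trace, file.path(out_dir, "trace.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(y_realt = obs$y_realt,
                                ref_disp = obs$ref_disp),
                     file.path(out_dir, "observations.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(e_realt = res$e_realt, c10 = res$params$c10,
           c01 = res$params$c01, e_estt = res$trace$e_estt[res$iterations],
           converged = res$converged, iterations = res$iterations,
           seed = cfg$seed[1]),
      file.path(out_dir, "result.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

# Lagrangian multi-frame tracking along a traction ladder.
#
# The quasi-static load is recorded continuously, so tracked mode follows
# material points through a sequence of frames whose traction changes by at
# most ladder_step_pa, keeping the inter-frame strain small enough for
# speckle correlation, and accumulates the small inter-frame shifts.
# Because the tumor is anechoic (zero-amplitude scatterers), its interior
# carries no speckle; the tracked windows sit on the echogenic
# proximal/distal tumor boundaries and interior-point displacements are
# interpolated linearly between them - the standard treatment of an
# anechoic inclusion.  The accumulated displacement is read out at every
# sampled instant's traction; the returned observation vector holds the
# interior-point displacements relative to the distal boundary, time-major.
track_ladder <- function(cfg, pts) {
  geometry <- cfg$geometry; load <- cfg$load
  trac_j <- traction_at(load, load$sample_times_s)
  if (length(unique(sign(trac_j[trac_j != 0]))) > 1)
    stop("track_ladder: sampled instants mix load signs; use one half-cycle")
  sgn <- sign(trac_j[which.max(abs(trac_j))])
  if (sgn == 0) sgn <- 1
  mag <- sort(unique(c(abs(trac_j),
                       seq(0, max(abs(trac_j)), by = cfg$ladder_step_pa))))
  mag <- mag[mag > 0]
  ladder <- sgn * mag
  ta <- geometry$tumor_axial
  lat <- pts$lateral_mm[1]
  # proximal and distal tumor boundary windows
  centers0 <- data.frame(axial_mm = c(ta[1], ta[2]),
                         lateral_mm = lat)
  scat <- seed_scatterers(geometry, cfg$probe, cfg$scatterer_density,
                          seed = cfg$seed[1])
  prev <- synthesize_rf(scat, cfg$probe, time_s = 0)
  pos_ax <- centers0$axial_mm
  pos_lat <- centers0$lateral_mm
  acc <- numeric(2L)
  u_at <- matrix(NA_real_, 2L, length(trac_j))
  for (s in ladder) {
    f <- field_at_traction(geometry, cfg$materials, s)
    frame <- synthesize_rf(displace_scatterers(scat, f), cfg$probe)
    est <- ncc_track(prev, frame, cfg$tracking,
                     centers = data.frame(axial_mm = pos_ax,
                                          lateral_mm = pos_lat))
    if (any(est$flagged))
      stop("run_pipeline: tracking flagged a window at traction ", s, " Pa")
    # ncc_track sorts windows; map back to the point order
    ord <- order(order(pos_lat, pos_ax))
    dax <- est$axial_shift_mm[ord]
    dlat <- est$lateral_shift_mm[ord]
    acc <- acc + dax
    pos_ax <- pos_ax + dax
    pos_lat <- pos_lat + dlat
    hit <- which(abs(abs(trac_j) - abs(s)) < 1e-9)
    for (j in hit) u_at[, j] <- acc
    prev <- frame
  }
  if (anyNA(u_at)) stop("track_ladder: some instants were not reached")
  # interior points by linear interpolation between the boundaries;
  # observation is relative to the distal boundary
  w <- (ta[2] - pts$axial_mm) / (ta[2] - ta[1])
  y <- as.vector(vapply(seq_along(trac_j),
                        function(j) w * (u_at[1, j] - u_at[2, j]),
                        numeric(nrow(pts))))
  list(y = y, u = u_at)
}

#' Inject multiplicative Gaussian displacement noise
#'
#' y_i (1 + N(0, level/100)) i.i.d., the perturbation model of the
#' noise-robustness study.
#'
#' @param y Displacement vector.
#' @param level_percent Noise level in percent (>= 0).
#' @param seed Integer seed or `NULL`.
#' @return Perturbed vector.
#' @export
inject_displacement_noise <- function(y, level_percent, seed = NULL) {
  stopifnot(is.numeric(y), level_percent >= 0)
  if (level_percent == 0) return(y)
  y * (1 + with_seed(seed, stats::rnorm(length(y), 0, level_percent / 100)))
}

#' Noise-robustness sweep
#'
#' Perturbs the observation vector with i.i.d. multiplicative Gaussian
#' noise at each level and seed, re-runs the inversion (noisy mode, i.e.
#' successive-iterate convergence; exact mode for level 0), and tabulates
#' the recovered constants and their percent errors against the true tumor.
#'
#' @param cfg A [run_config()] (the tracking stage is bypassed; noise is
#'   applied to the sampled observation vector, which is what the inversion
#'   consumes).
#' @param levels Noise levels, percent.
#' @param n_seeds Realizations per level (>= 1); seeds are
#'   `seed0 + 1:n_seeds`.
#' @param seed0 Seed offset.
#' @return An object of class `eval_report`: data frame with one row per
#'   (level, seed) and columns `c10`, `c01`, `err_c10`, `err_c01`,
#'   `err_e_estt`, `err_y_estt`, `converged`; attribute `summary` holds the
#'   per-level medians.
#' @export
noise_sweep <- function(cfg, levels = c(2, 5, 8, 10), n_seeds = 20,
                        seed0 = 1000) {
  stopifnot(inherits(cfg, "run_config"), n_seeds >= 1, all(levels >= 0))
  geometry <- cfg$geometry
  pts <- tumor_points(geometry, cfg$n_points)
  obs0 <- simulate_observations(geometry, cfg$materials, cfg$load, pts)
  truth <- cfg$materials$tumor
  rows <- list()
  for (lv in levels) {
    seeds <- if (lv == 0) seed0 else seed0 + seq_len(n_seeds)
    for (sd in seeds) {
      y <- inject_displacement_noise(obs0$y_realt, lv, seed = sd)
      obs <- observation_set(y, obs0$ref_disp, pts, cfg$load$sample_times_s)
      res <- mr_iterate(obs, geometry, cfg$materials, cfg$load,
                        cfg$schedule, cfg$tolerances,
                        mode = if (lv == 0) "exact" else "noisy")
      k <- res$iterations
      rows[[length(rows) + 1L]] <- data.frame(
        level = lv, seed = sd,
        c10 = res$params$c10, c01 = res$params$c01,
        err_c10 = percent_error(truth$c10, res$params$c10),
        err_c01 = percent_error(truth$c01, res$params$c01),
        err_e_estt = percent_error(res$e_realt, res$trace$e_estt[k]),
        err_y_estt = 100 * mean(abs(res$y_estt - obs$y_realt)) /
          mean(abs(obs$y_realt)),
        iterations = k, converged = res$converged)
    }
  }
  rep <- do.call(rbind, rows)
  class(rep) <- c("eval_report", "data.frame")
  agg <- stats::aggregate(
    rep[c("err_c10", "err_c01", "err_e_estt", "err_y_estt")],
    by = list(level = rep$level), FUN = stats::median)
  attr(rep, "summary") <- agg
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Noise-robustness sweep (medians per level):\n")
  print(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}
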