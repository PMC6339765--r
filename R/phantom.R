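#' Layered breast-phantom geometry
#'
#' Describes the reduced phantom used throughout the package: an axial stack
#' of tissue layers (probe face at depth 0, fully constrained face at the
#' opposite side) with a rectangular tumor region embedded in one layer.
#' Defaults reproduce a 100 x 60 x 20 mm three-material phantom:
#' 20 mm of fat over 80 mm of fibroglandular tissue, with a 10 mm tumor
#' centered at 70 mm depth and 10 mm wide laterally.
#'
#' @param axial_mm,lateral_mm,elev_mm Overall extent, mm.  The elevational
#'   extent is metadata only (the model is an imaging-plane reduction).
#' @param layers Named numeric vector of layer thicknesses, mm, ordered from
#'   the probe face inward; must sum to `axial_mm`.
#' @param tumor_axial Axial interval `c(z0, z1)` of the tumor, mm; must lie
#'   strictly inside a single layer.
#' @param tumor_lateral_mm Lateral extent of the tumor, mm, centered on the
#'   phantom midline.
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(axial_mm = 100, lateral_mm = 60, elev_mm = 20,
                             layers = c(fat = 20, fibroglandular = 80),
                             tumor_axial = c(65, 75),
                             tumor_lateral_mm = 10) {
  stopifnot(axial_mm > 0, lateral_mm > 0, elev_mm > 0,
            is.numeric(layers), length(layers) >= 1, !is.null(names(layers)),
            all(layers > 0),
            length(tumor_axial) == 2, tumor_axial[1] < tumor_axial[2],
            tumor_lateral_mm > 0, tumor_lateral_mm <= lateral_mm)
  if (abs(sum(layers) - axial_mm) > 1e-9)
    stop("phantom_geometry: layer thicknesses must sum to axial_mm")
  edges <- cumsum(c(0, layers))
  host <- which(edges[-length(edges)] <= tumor_axial[1] &
                edges[-1] >= tumor_axial[2])
  if (length(host) != 1)
    stop("phantom_geometry: tumor interval must lie inside a single layer")
  structure(list(axial_mm = axial_mm, lateral_mm = lateral_mm,
                 elev_mm = elev_mm, layers = layers,
                 tumor_axial = tumor_axial,
                 tumor_lateral_mm = tumor_lateral_mm,
                 host_layer = names(layers)[host]),
            class = "phantom_geometry")
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf("Phantom %g x %g x %g mm; layers: %s; tumor [%g, %g] mm x %g mm (in %s)\n",
              x$axial_mm, x$lateral_mm, x$elev_mm,
              paste(sprintf("%s %g mm", names(x$layers), x$layers), collapse = ", "),
              x$tumor_axial[1], x$tumor_axial[2], x$tumor_lateral_mm,
              x$host_layer))
  invisible(x)
}

#' Sinusoidal surface-load specification
#'
#' A quasi-static sinusoidal surface traction: traction(t) =
#' amplitude * sin(2 pi f t), with compression counted positive.  The
#' default frequency of 0.1 Hz is low enough that inertia is negligible and
#' the phantom is in equilibrium at every instant; the default sample times
#' are the eight consecutive instants 7.75-9.50 s used by the pipeline.
#'
#' @param amplitude_pa Peak surface traction, Pa (compressive positive).
#' @param frequency_hz Load frequency, Hz (> 0).
#' @param sample_times_s Strictly increasing sampling instants, s.
#' @return An object of class `load_spec`.
#' @export
load_spec <- function(amplitude_pa = 5000, frequency_hz = 0.1,
                      sample_times_s = seq(7.75, 9.50, by = 0.25)) {
  stopifnot(is.numeric(amplitude_pa), length(amplitude_pa) == 1L,
            is.finite(amplitude_pa),
            frequency_hz > 0, length(sample_times_s) >= 1,
            all(diff(sample_times_s) > 0))
  structure(list(amplitude_pa = amplitude_pa, frequency_hz = frequency_hz,
                 sample_times_s = sample_times_s), class = "load_spec")
}

#' @rdname load_spec
#' @param load A `load_spec`.
#' @param t Time, s.
#' @return `traction_at()`: the instantaneous surface traction, Pa
#'   (compressive positive).
#' @export
traction_at <- function(load, t) {
  stopifnot(inherits(load, "load_spec"), all(t >= 0))
  load$amplitude_pa * sin(2 * pi * load$frequency_hz * t)
}

# axial stress at stretch lambda for either material class
axial_stress <- function(material, stretch) {
  if (inherits(material, "mr_params"))
    cauchy_stress_uniaxial(material, stretch)
  else if (inherits(material, "linear_elastic"))
    material$e_pa * (stretch - 1)
  else stop("unknown material class: ", paste(class(material), collapse = "/"))
}

# lateral stretch at axial stretch lambda (incompressible MR; linear via nu)
lateral_stretch <- function(material, stretch) {
  if (inherits(material, "mr_params")) stretch^(-0.5)
  else 1 - material$nu * (stretch - 1)
}

# stretch solving axial_stress(material, lambda) = sigma
solve_stretch <- function(material, sigma, layer = "?") {
  if (inherits(material, "linear_elastic"))
    return(1 + sigma / material$e_pa)
  if (sigma == 0) return(1)
  f <- function(l) cauchy_stress_uniaxial(material, l) - sigma
  lo <- 0.2; hi <- 3
  if (f(lo) * f(hi) > 0)
    stop(sprintf("solve_layer_stretches: stress %g Pa not bracketed in lambda [%g, %g] for layer '%s'",
                 sigma, lo, hi, layer))
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# ordered (material, z0, z1) stack for a lateral position; tumor column gets
# the host layer split around the tumor interval
column_stack <- function(geometry, lateral_mm) {
  edges <- cumsum(c(0, geometry$layers))
  st <- data.frame(material = names(geometry$layers),
                   z0 = edges[-length(edges)], z1 = edges[-1],
                   stringsAsFactors = FALSE)
  mid <- geometry$lateral_mm / 2
  in_tumor <- abs(lateral_mm - mid) <= geometry$tumor_lateral_mm / 2
  if (!in_tumor) return(st)
  i <- match(geometry$host_layer, st$material)
  ta <- geometry$tumor_axial
  parts <- data.frame(
    material = c(st$material[i], "tumor", st$material[i]),
    z0 = c(st$z0[i], ta[1], ta[2]),
    z1 = c(ta[1], ta[2], st$z1[i]),
    stringsAsFactors = FALSE)
  parts <- parts[parts$z1 > parts$z0, ]
  out <- rbind(st[seq_len(i - 1), ], parts,
               st[seq_len(nrow(st)) > i, ])
  rownames(out) <- NULL
  out
}

#' Per-layer stretches under a uniform axial traction
#'
#' In the reduced series (uniaxial) model every layer of a column carries
#' the same axial Cauchy stress sigma = -traction (compression positive
#' traction gives sigma < 0).  Each layer's stretch solves
#' `cauchy_stress_uniaxial(params, lambda) = -traction` with a safeguarded
#' root finder on lambda in \[0.2, 3\]; stress continuity across layers holds
#' by construction.
#'
#' @param geometry A [phantom_geometry()].
#' @param materials Named list of [mr_params()] / [linear_elastic()] objects
#'   resolving every layer name and `"tumor"`.
#' @param traction Surface traction, Pa (compressive positive).
#' @return Named numeric vector of stretches, one per distinct material in
#'   the tumor column (including `"tumor"`).
#' @export
solve_layer_stretches <- function(geometry, materials, traction) {
  stopifnot(inherits(geometry, "phantom_geometry"), is.finite(traction))
  st <- column_stack(geometry, geometry$lateral_mm / 2)
  mats <- unique(st$material)
  missing <- setdiff(mats, names(materials))
  if (length(missing) > 0)
    stop("solve_layer_stretches: no material parameters for: ",
         paste(missing, collapse = ", "))
  sigma <- -traction
  vapply(mats, function(m) solve_stretch(materials[[m]], sigma, m),
         0)
}

# per-column axial/lateral displacement profiles on a depth grid
column_profiles <- function(stack, materials, sigma, z) {
  lam <- vapply(seq_len(nrow(stack)),
                function(i) solve_stretch(materials[[stack$material[i]]],
                                          sigma, stack$material[i]), 0)
  lat <- vapply(seq_len(nrow(stack)),
                function(i) lateral_stretch(materials[[stack$material[i]]],
                                            lam[i]), 0)
  # u(z) = int_z^L (1 - lambda) dzeta, piecewise linear; u(L) = 0
  seg <- (1 - lam) * (stack$z1 - stack$z0)
  cum_below <- rev(cumsum(rev(seg)))            # integral from z0_i to L
  idx <- findInterval(z, stack$z0, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L; idx[idx > nrow(stack)] <- nrow(stack)
  u <- (1 - lam[idx]) * (stack$z1[idx] - z) +
    ifelse(idx < nrow(stack), cum_below[pmin(idx + 1L, nrow(stack))], 0)
  list(ux = u, lat = lat[idx], lam = lam[idx])
}

#' Quasi-static displacement field of the layered phantom
#'
#' Computes the in-plane displacement field at time `t` under the sinusoidal
#' load.  Axial displacement at depth z is the integral of (1 - lambda) from
#' z to the fixed face (so it vanishes on the fixed boundary row and is
#' positive toward the fixed face under compression); lateral displacement
#' spreads symmetrically about the phantom midline with the material's
#' lateral stretch.  The field depends on t only through sin(2 pi f t)
#' (quasi-static, no history).
#'
#' @param geometry A [phantom_geometry()].
#' @param materials Named list of materials (see [solve_layer_stretches()]).
#' @param load A [load_spec()].
#' @param t Time, s (>= 0).
#' @param grid_dz_mm,grid_dx_mm Grid spacing, mm.
#' @param role Frame role label, `"pre"` or `"post"`.
#' @return An object of class `displacement_field`: list with `axial_mm`,
#'   `lateral_mm` (grid vectors), `ux_mm`, `uy_mm` (matrices, axial x
#'   lateral), `time_s`, `role`.
#' @export
displacement_field_at <- function(geometry, materials, load, t,
                                  grid_dz_mm = 1, grid_dx_mm = 1,
                                  role = "post") {
  stopifnot(inherits(load, "load_spec"), length(t) == 1L, t >= 0)
  field_at_traction(geometry, materials, traction_at(load, t),
                    grid_dz_mm = grid_dz_mm, grid_dx_mm = grid_dx_mm,
                    role = role, time_s = t)
}

# displacement field under a given instantaneous surface traction
field_at_traction <- function(geometry, materials, traction,
                              grid_dz_mm = 1, grid_dx_mm = 1,
                              role = "post", time_s = NA_real_) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  sigma <- -traction
  z <- seq(0, geometry$axial_mm, by = grid_dz_mm)
  x <- seq(0, geometry$lateral_mm, by = grid_dx_mm)
  mid <- geometry$lateral_mm / 2
  in_col <- column_profiles(column_stack(geometry, mid), materials, sigma, z)
  out_col <- column_profiles(column_stack(geometry, -1), materials, sigma, z)
  tumor_cols <- abs(x - mid) <= geometry$tumor_lateral_mm / 2
  ux <- matrix(0, length(z), length(x))
  uy <- matrix(0, length(z), length(x))
  for (j in seq_along(x)) {
    col <- if (tumor_cols[j]) in_col else out_col
    ux[, j] <- col$ux
    uy[, j] <- (col$lat - 1) * (x[j] - mid)
  }
  structure(list(axial_mm = z, lateral_mm = x, ux_mm = ux, uy_mm = uy,
                 time_s = time_s, role = role),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("Displacement field (%s) at t = %g s: %d x %d grid, |ux| max %.4g mm\n",
              x$role, x$time_s, length(x$axial_mm), length(x$lateral_mm),
              max(abs(x$ux_mm))))
  invisible(x)
}

#' Displacement field with a linear-elastic reference tumor
#'
#' Same kinematics as [displacement_field_at()] but with the tumor governed
#' by the linear law epsilon = sigma / E (default: the unit-modulus,
#' nu = 0.5 "elastic tumor" of the inversion algorithm).  All other layers
#' keep their known hyperelastic laws.
#'
#' @inheritParams displacement_field_at
#' @param e_pa Reference tumor modulus, Pa (> 0); default 1.
#' @param nu Poisson's ratio of the reference tumor (0.5 = incompressible).
#' @return A `displacement_field`.
#' @export
elastic_reference_field <- function(geometry, materials, load, t,
                                    e_pa = 1, nu = 0.5,
                                    grid_dz_mm = 1, grid_dx_mm = 1) {
  materials$tumor <- linear_elastic(e_pa, nu, name = "elastic tumor")
  displacement_field_at(geometry, materials, load, t,
                        grid_dz_mm = grid_dz_mm, grid_dx_mm = grid_dx_mm,
                        role = "reference")
}

# bilinear interpolation of matrix M gridded on (gz rows, gx cols)
interp_bilinear <- function(gz, gx, M, z, x) {
  stopifnot(length(z) == length(x))
  if (any(z < gz[1] - 1e-9) || any(z > gz[length(gz)] + 1e-9) ||
      any(x < gx[1] - 1e-9) || any(x > gx[length(gx)] + 1e-9))
    stop("interp_bilinear: query point outside grid support")
  iz <- pmin(pmax(findInterval(z, gz), 1L), length(gz) - 1L)
  ix <- pmin(pmax(findInterval(x, gx), 1L), length(gx) - 1L)
  tz <- (z - gz[iz]) / (gz[iz + 1L] - gz[iz])
  tx <- (x - gx[ix]) / (gx[ix + 1L] - gx[ix])
  M[cbind(iz, ix)] * (1 - tz) * (1 - tx) +
    M[cbind(iz + 1L, ix)] * tz * (1 - tx) +
    M[cbind(iz, ix + 1L)] * (1 - tz) * tx +
    M[cbind(iz + 1L, ix + 1L)] * tz * tx
}

#' Sample axial displacements at points over a set of fields
#'
#' Bilinearly interpolates the axial displacement of one or several
#' displacement fields at the given points.  With several fields the result
#' is ordered time-major, point-minor: all points of the first field, then
#' all points of the second, and so on.
#'
#' @param fields A `displacement_field` or a list of them (one per instant).
#' @param points Data frame or 2-column matrix with columns
#'   `axial_mm`, `lateral_mm`.
#' @return Numeric vector of axial displacements, mm (length
#'   `nrow(points) * length(fields)`).
#' @export
sample_axial <- function(fields, points) {
  if (inherits(fields, "displacement_field")) fields <- list(fields)
  stopifnot(all(vapply(fields, inherits, TRUE, "displacement_field")))
  pts <- as.data.frame(points)
  if (!all(c("axial_mm", "lateral_mm") %in% names(pts))) {
    stopifnot(ncol(pts) == 2)
    names(pts) <- c("axial_mm", "lateral_mm")
  }
  unlist(lapply(fields, function(f)
    interp_bilinear(f$axial_mm, f$lateral_mm, f$ux_mm,
                    pts$axial_mm, pts$lateral_mm)), use.names = FALSE)
}

#' Default tumor sampling points
#'
#' Evenly spaced depths strictly inside the tumor interval at the phantom's
#' lateral midline; the inversion uses 12 of them by default.
#'
#' @param geometry A [phantom_geometry()].
#' @param n Number of points.
#' @return Data frame with columns `axial_mm`, `lateral_mm`.
#' @export
tumor_points <- function(geometry, n = 12) {
  stopifnot(inherits(geometry, "phantom_geometry"), n >= 1)
  ta <- geometry$tumor_axial
  h <- diff(ta) / (2 * n)
  data.frame(axial_mm = seq(ta[1] + h, ta[2] - h, length.out = n),
             lateral_mm = geometry$lateral_mm / 2)
}

#' Read or write a displacement field as plain text
#'
#' Self-describing text format: `# key: value` header lines (grid vectors,
#' time, role) followed by the ux and uy matrices as tab-separated blocks.
#' Numbers are written with 17 significant digits so doubles round-trip
#' exactly.
#'
#' @param field A `displacement_field`.
#' @param path Output file.
#' @return `read_displacement_field()`: the reconstructed field.
#' @export
write_displacement_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  writeLines(c(
    "# elastinv displacement_field v1",
    paste0("# time_s: ", sprintf("%.17g", field$time_s)),
    paste0("# role: ", field$role),
    paste0("# axial_mm: ", num(field$axial_mm)),
    paste0("# lateral_mm: ", num(field$lateral_mm)),
    "# block: ux_mm"), con)
  utils::write.table(format(field$ux_mm, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines("# block: uy_mm", con)
  utils::write.table(format(field$uy_mm, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_displacement_field
#' @export
read_displacement_field <- function(path) {
  lines <- readLines(path)
  hdr <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), lines, value = TRUE)[1]
    sub(paste0("^# ", key, ": "), "", ln)
  }
  z <- as.numeric(strsplit(hdr("axial_mm"), " ")[[1]])
  x <- as.numeric(strsplit(hdr("lateral_mm"), " ")[[1]])
  blocks <- grep("^# block: ", lines)
  read_block <- function(from, n) {
    rows <- lines[(from + 1):(from + n)]
    matrix(as.numeric(unlist(strsplit(rows, "\t"))), nrow = n, byrow = TRUE)
  }
  structure(list(axial_mm = z, lateral_mm = x,
                 ux_mm = read_block(blocks[1], length(z)),
                 uy_mm = read_block(blocks[2], length(z)),
                 time_s = as.numeric(hdr("time_s")),
                 role = hdr("role")),
            class = "displacement_field")
}
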