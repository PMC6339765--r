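#' Mooney-Rivlin material parameters
#'
#' Container for the two Mooney-Rivlin hyperelastic constants of an
#' incompressible (or nearly incompressible) soft tissue.  The strain energy
#' is W = C10 (I1 - 3) + C01 (I2 - 3) + (1/D) (J - 1)^2; under strict
#' incompressibility (J = 1, the package default) the volumetric constant
#' `d_vol` is stored but unused.  The initial shear modulus is
#' mu0 = 2 (C10 + C01) and the small-strain Young's modulus of the
#' incompressible material is E = 3 mu0 = 6 (C10 + C01).
#'
#' @param c10,c01 Mooney-Rivlin constants, Pa.  Their sum must be positive
#'   (positive initial shear modulus); either constant alone may be negative.
#' @param d_vol Optional volumetric constant, 1/Pa, `NULL` for strict
#'   incompressibility.  Must be non-negative when present.
#' @param name Optional material name used in printing and error messages.
#' @return An object of class `mr_params`.
#' @examples
#' tumor <- mr_params(10000, 6667)
#' youngs_from_mr(tumor)
#' @export
mr_params <- function(c10, c01, d_vol = NULL, name = NULL) {
  stopifnot(is.numeric(c10), length(c10) == 1L, is.finite(c10),
            is.numeric(c01), length(c01) == 1L, is.finite(c01))
  if (c10 + c01 <= 0)
    stop("mr_params: C10 + C01 must be positive (mu0 = 2(C10+C01) > 0), got ",
         c10 + c01)
  if (!is.null(d_vol)) {
    stopifnot(is.numeric(d_vol), length(d_vol) == 1L, is.finite(d_vol))
    if (d_vol < 0) stop("mr_params: d_vol must be >= 0")
  }
  structure(list(c10 = c10, c01 = c01, d_vol = d_vol, name = name),
            class = "mr_params")
}

#' @export
print.mr_params <- function(x, ...) {
  cat(sprintf("Mooney-Rivlin material%s: C10 = %g Pa, C01 = %g Pa (E = %g Pa)\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$c10, x$c01, youngs_from_mr(x)))
  invisible(x)
}

#' Linear-elastic material
#'
#' Minimal linear-elastic counterpart of [mr_params()], used for the
#' unit-modulus elastic reference tumor of the inversion algorithm and for
#' linear-limit checks.  Axial stress is sigma = E (lambda - 1); the lateral
#' stretch is 1 - nu (lambda - 1).
#'
#' @param e_pa Young's modulus, Pa (> 0).
#' @param nu Poisson's ratio; only the incompressible value 0.5 is used by
#'   the pipeline but any value in \[0, 0.5\] is accepted.
#' @param name Optional material name.
#' @return An object of class `linear_elastic`.
#' @export
linear_elastic <- function(e_pa, nu = 0.5, name = NULL) {
  stopifnot(is.numeric(e_pa), length(e_pa) == 1L, is.finite(e_pa), e_pa > 0,
            is.numeric(nu), length(nu) == 1L, nu >= 0, nu <= 0.5)
  structure(list(e_pa = e_pa, nu = nu, name = name), class = "linear_elastic")
}

#' @export
print.linear_elastic <- function(x, ...) {
  cat(sprintf("Linear-elastic material%s: E = %g Pa, nu = %g\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$e_pa, x$nu))
  invisible(x)
}

#' Principal stretches of an incompressible uniaxial deformation
#'
#' For a uniaxial stress state along the first axis with lateral symmetry
#' and incompressibility (I3 = 1), the principal stretches are
#' (lambda, lambda^-1/2, lambda^-1/2).
#'
#' @param stretch Axial principal stretch lambda (> 0); scalar.
#' @return Named numeric vector `c(l1, l2, l3)` with product 1.
#' @export
uniaxial_stretches <- function(stretch) {
  stopifnot(is.numeric(stretch), length(stretch) == 1L, is.finite(stretch))
  if (stretch <= 0) stop("uniaxial_stretches: stretch must be positive")
  lat <- stretch^(-0.5)
  c(l1 = stretch, l2 = lat, l3 = lat)
}

#' Principal strain invariants from principal stretches
#'
#' I1 = sum lambda_i^2, I2 = sum of pairwise products of lambda_i^2,
#' I3 = product of lambda_i^2.
#'
#' @param l1,l2,l3 Principal stretches (> 0).
#' @return Named numeric vector `c(i1, i2, i3)`.
#' @export
invariants_from_stretches <- function(l1, l2, l3) {
  stopifnot(is.numeric(l1), is.numeric(l2), is.numeric(l3))
  if (any(c(l1, l2, l3) <= 0))
    stop("invariants_from_stretches: stretches must be positive")
  s1 <- unname(l1)^2; s2 <- unname(l2)^2; s3 <- unname(l3)^2
  c(i1 = s1 + s2 + s3,
    i2 = s1 * s2 + s2 * s3 + s3 * s1,
    i3 = s1 * s2 * s3)
}

#' Mooney-Rivlin strain energy along the incompressible uniaxial path
#'
#' W(lambda) = C10 (I1 - 3) + C01 (I2 - 3) with
#' I1 = lambda^2 + 2/lambda and I2 = 2 lambda + 1/lambda^2.
#'
#' @param params An [mr_params()] object.
#' @param stretch Axial stretch(es), > 0.
#' @return Strain energy density, Pa (J/m^3).
#' @export
mr_strain_energy <- function(params, stretch) {
  stopifnot(inherits(params, "mr_params"), all(stretch > 0))
  i1 <- stretch^2 + 2 / stretch
  i2 <- 2 * stretch + stretch^-2
  params$c10 * (i1 - 3) + params$c01 * (i2 - 3)
}

#' Uniaxial Cauchy stress of an incompressible Mooney-Rivlin material
#'
#' sigma(lambda) = 2 (lambda^2 - 1/lambda) (C10 + C01 / lambda).  The
#' hydrostatic pressure has been eliminated by the traction-free lateral
#' boundary, so the expression is fully explicit.  Signed: tension
#' (lambda > 1) gives sigma > 0 when mu0 > 0, compression gives sigma < 0.
#'
#' @param params An [mr_params()] object.
#' @param stretch Axial stretch(es) lambda, > 0.  Vectorized.
#' @return Cauchy stress, Pa.
#' @export
cauchy_stress_uniaxial <- function(params, stretch) {
  stopifnot(inherits(params, "mr_params"), is.numeric(stretch))
  if (any(!is.finite(stretch)) || any(stretch <= 0))
    stop("cauchy_stress_uniaxial: stretch must be positive and finite")
  2 * (stretch^2 - 1 / stretch) * (params$c10 + params$c01 / stretch)
}

#' Uniaxial Cauchy stress as a function of engineering strain
#'
#' Identical to [cauchy_stress_uniaxial()] evaluated at lambda = 1 + strain.
#'
#' @param params An [mr_params()] object.
#' @param strain Engineering strain(s) epsilon = lambda - 1, > -1.
#' @return Cauchy stress, Pa.
#' @export
stress_from_strain <- function(params, strain) {
  stopifnot(is.numeric(strain))
  if (any(!is.finite(strain)) || any(strain <= -1))
    stop("stress_from_strain: strain must be finite and > -1")
  cauchy_stress_uniaxial(params, 1 + strain)
}

#' Small-strain Young's modulus implied by Mooney-Rivlin constants
#'
#' For an incompressible material the initial shear modulus is
#' mu0 = 2 (C10 + C01) and E = 3 mu0, hence E = 6 (C10 + C01).
#'
#' @param params An [mr_params()] object.
#' @return Young's modulus, Pa.
#' @export
youngs_from_mr <- function(params) {
  stopifnot(inherits(params, "mr_params"))
  mu0 <- 2 * (params$c10 + params$c01)
  if (mu0 <= 0) stop("youngs_from_mr: non-positive initial shear modulus")
  3 * mu0
}

#' Read or write a material table
#'
#' Material tables are CSV files with columns `name`, `c10_pa`, `c01_pa` and
#' optionally `e_pa`.  When `e_pa` is present it is validated against
#' 6 (C10 + C01); a relative discrepancy above 1% (more than table-rounding)
#' is an error.
#'
#' @param path CSV file path.
#' @return `read_material_table()`: a named list of [mr_params()] objects.
#' @examples
#' mats <- breast_materials()
#' sapply(mats, youngs_from_mr)
#' @export
read_material_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "c10_pa", "c01_pa")
  if (!all(need %in% names(tab)))
    stop("material table must have columns name, c10_pa, c01_pa")
  mats <- vector("list", nrow(tab))
  names(mats) <- tab$name
  for (i in seq_len(nrow(tab))) {
    p <- mr_params(tab$c10_pa[i], tab$c01_pa[i], name = tab$name[i])
    if ("e_pa" %in% names(tab) && !is.na(tab$e_pa[i])) {
      e_impl <- youngs_from_mr(p)
      if (abs(tab$e_pa[i] - e_impl) > 0.01 * abs(tab$e_pa[i]))
        stop(sprintf(
          "material '%s': e_pa %.6g inconsistent with 6(C10+C01) = %.6g",
          tab$name[i], tab$e_pa[i], e_impl))
    }
    mats[[i]] <- p
  }
  mats
}

#' @rdname read_material_table
#' @param materials Named list of [mr_params()] objects.
#' @export
write_material_table <- function(materials, path) {
  stopifnot(length(materials) > 0, !is.null(names(materials)))
  tab <- data.frame(
    name = names(materials),
    c10_pa = vapply(materials, function(m) m$c10, 0),
    c01_pa = vapply(materials, function(m) m$c01, 0),
    e_pa = vapply(materials, youngs_from_mr, 0),
    row.names = NULL)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reference breast-tissue material table
#'
#' The fat / fibroglandular / tumor Mooney-Rivlin constants widely used to
#' simulate breast tissue, shipped with the package as
#' `extdata/breast_materials.csv`.
#'
#' @return Named list of [mr_params()]: `fat`, `fibroglandular`, `tumor`.
#' @export
breast_materials <- function() {
  read_material_table(system.file("extdata", "breast_materials.csv",
                                  package = "elastinv", mustWork = TRUE))
}
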