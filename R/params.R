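#' Viscoelastic material parameters of the Kelvin-Voigt-Maxwell model
#'
#' Bundle and validate the four material parameters of the KVM model: a
#' Kelvin-Voigt arm (spring `E0` in parallel with dashpot `eta`) in parallel
#' with a Maxwell arm (spring `E1` in series with a dashpot of viscosity
#' `lambda * E1`, so `lambda` is the arm's stress-relaxation time).
#'
#' @param E0 Kelvin-Voigt elastic modulus \[Pa\], `>= 0`.
#' @param E1 Maxwell elastic modulus \[Pa\], `>= 0`. `E1 = 0` reduces the
#'   model to a Kelvin-Voigt solid.
#' @param lam Maxwell relaxation time \[s\], `>= 0`. Must be `> 0` whenever
#'   `E1 > 0` (the Maxwell arm is undefined otherwise).
#' @param eta Apparent viscosity \[Pa s\], `>= 0`.
#' @param nu Poisson ratio, in `[0, 0.5]`. Defaults to 0.5
#'   (incompressible), the standard assumption for cells and hydrogels.
#'
#' @return An object of class `"viscoelastic_params"`: a named list with
#'   fields `E0`, `E1`, `lam`, `eta`, `nu`.
#' @examples
#' viscoelastic_params(E0 = 1000, E1 = 800, lam = 0.1, eta = 2)
#' @export
viscoelastic_params <- function(E0, E1 = 0, lam = 0, eta = 0, nu = 0.5) {
  stopifnot(
    is.numeric(E0), length(E0) == 1L, is.finite(E0),
    is.numeric(E1), length(E1) == 1L, is.finite(E1),
    is.numeric(lam), length(lam) == 1L, is.finite(lam),
    is.numeric(eta), length(eta) == 1L, is.finite(eta),
    is.numeric(nu), length(nu) == 1L, is.finite(nu)
  )
  if (E0 < 0 || E1 < 0 || lam < 0 || eta < 0)
    stop("E0, E1, lam and eta must all be non-negative", call. = FALSE)
  if (nu < 0 || nu > 0.5 + 1e-12)
    stop("nu must lie in [0, 0.5]", call. = FALSE)
  if (E1 > 0 && lam <= 0)
    stop("lam must be positive when E1 > 0 (Maxwell arm undefined)",
         call. = FALSE)
  structure(list(E0 = E0, E1 = E1, lam = lam, eta = eta, nu = nu),
            class = "viscoelastic_params")
}

#' @export
print.viscoelastic_params <- function(x, ...) {
  cat(sprintf(
    "KVM material: E0 = %.4g Pa, E1 = %.4g Pa, lambda = %.4g s, eta = %.4g Pa s, nu = %.3g\n",
    x$E0, x$E1, x$lam, x$eta, x$nu))
  invisible(x)
}

#' Calibration constants of the explicit KVM force-indentation relation
#'
#' The explicit relation carries four dimensionless constants: `alpha1`
#' scales the elapsed contact time in the Maxwell arm's exponential decay,
#' and `alpha2 * delta^alpha3 * R^alpha4 * eta * v` is the viscous drag of
#' the probe segment in contact with the sample. The defaults are the
#' values calibrated against phase-field contact simulations over a wide
#' parameter range; with `alpha3 = alpha4 = 1/2` the viscous term is
#' `alpha2 * sqrt(R * delta) * eta * v`, which is dimensionally a force and
#' has the same functional form as the Kelvin-Voigt drag of a spherical
#' indenter.
#'
#' @param alpha1 Decay-rate constant (default 0.365).
#' @param alpha2 Viscous prefactor (default 7.25).
#' @param alpha3 Indentation exponent of the viscous term (default 1/2).
#' @param alpha4 Radius exponent of the viscous term (default 1/2).
#'
#' @return An object of class `"calibration_constants"`.
#' @examples
#' calibration_constants()
#' @export
calibration_constants <- function(alpha1 = 0.365, alpha2 = 7.25,
                                  alpha3 = 0.5, alpha4 = 0.5) {
  vals <- c(alpha1, alpha2, alpha3, alpha4)
  stopifnot(is.numeric(vals), length(vals) == 4L, all(is.finite(vals)))
  if (any(vals <= 0))
    stop("all calibration constants must be positive", call. = FALSE)
  structure(list(alpha1 = alpha1, alpha2 = alpha2,
                 alpha3 = alpha3, alpha4 = alpha4),
            class = "calibration_constants")
}

#' @export
print.calibration_constants <- function(x, ...) {
  cat(sprintf("calibration constants: alpha1 = %g, alpha2 = %g, alpha3 = %g, alpha4 = %g\n",
              x$alpha1, x$alpha2, x$alpha3, x$alpha4))
  invisible(x)
}

#' Probe and sample geometry
#'
#' Describes the spherical indenter and, optionally, a rounded (sphere-like)
#' sample. When the sample itself is a sphere of radius `Rcell` (a rounded
#' mitotic cell), the contact is sphere-on-sphere and an effective radius
#' `1/Reff = 1/Rcell + 1/R` replaces the probe radius in the contact model;
#' a confinement factor `K = Rcell^(1/3) / (Rcell^(1/3) + Reff^(1/3))`
#' additionally rescales the measured indentation to account for the
#' deformation of the sphere against the rigid support it rests on.
#'
#' @param R Indenter (bead) radius \[m\], `> 0`.
#' @param Rcell Optional radius of a rounded cell \[m\]; when given, `Reff`
#'   and `K` are computed and stored.
#' @param h Optional sample thickness \[m\] (used by the bottom-effect
#'   estimate).
#'
#' @return An object of class `"probe_geometry"` with fields `R`, `Rcell`,
#'   `Reff`, `K`, `h`. `Reff` and `K` are `NULL` unless `Rcell` is given.
#' @seealso [effective_radius()], [confinement_correction()]
#' @examples
#' probe_geometry(R = 2.5e-6, Rcell = 7.5e-6)
#' @export
probe_geometry <- function(R, Rcell = NULL, h = NULL) {
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R), R > 0)
  Reff <- NULL
  K <- NULL
  if (!is.null(Rcell)) {
    stopifnot(is.numeric(Rcell), length(Rcell) == 1L, is.finite(Rcell),
              Rcell > 0)
    Reff <- effective_radius(Rcell, R)
    K <- Rcell^(1 / 3) / (Rcell^(1 / 3) + Reff^(1 / 3))
    if (!(K > 0 && K < 1))
      stop("confinement factor K must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(h)) {
    stopifnot(is.numeric(h), length(h) == 1L, is.finite(h), h > 0)
  }
  structure(list(R = R, Rcell = Rcell, Reff = Reff, K = K, h = h),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("probe: R = %.3g um", x$R * 1e6))
  if (!is.null(x$Rcell))
    cat(sprintf("; rounded cell Rcell = %.3g um, Reff = %.4g um, K = %.3f",
                x$Rcell * 1e6, x$Reff * 1e6, x$K))
  if (!is.null(x$h)) cat(sprintf("; thickness h = %.3g um", x$h * 1e6))
  cat("\n")
  invisible(x)
}
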