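#' Hertz contact force of a sphere on an elastic half-space
#'
#' `F = (4/3) * E / (1 - nu^2) * sqrt(R) * delta^(3/2)`. Valid for small
#' elastic deformations (`delta << R`).
#'
#' @param E Young's modulus \[Pa\].
#' @param nu Poisson ratio (`< 1`).
#' @param R Indenter radius \[m\], `> 0`.
#' @param delta Indentation depth \[m\]; vectorised. Must be `>= 0` unless
#'   `clip = TRUE`.
#' @param clip If `TRUE`, negative indentations return zero force
#'   (piecewise-contact convention used by the fitting residual, which
#'   spans the pre-contact baseline); if `FALSE` (default) they raise an
#'   error.
#' @return Force \[N\], same length as `delta`.
#' @examples
#' hertz_force(1000, 0.5, 2.5e-6, 1e-6) # ~2.81 nN
#' @export
hertz_force <- function(E, nu, R, delta, clip = FALSE) {
  stopifnot(is.numeric(E), E >= 0, is.numeric(nu), nu < 1,
            is.numeric(R), R > 0, is.numeric(delta))
  if (clip) {
    delta <- pmax(delta, 0)
  } else if (any(delta < 0)) {
    stop("negative indentation; use clip = TRUE for the piecewise-contact convention",
         call. = FALSE)
  }
  (4 / 3) * E / (1 - nu^2) * sqrt(R) * delta^1.5
}

#' Hertz force with the large-indentation (hyperelastic) correction
#'
#' Multiplies the Hertz force by `(1 - 0.15 * delta / R)`, the correction
#' derived numerically for a neo-Hookean half-space, extending validity to
#' larger relative indentations.
#'
#' @inheritParams hertz_force
#' @return Force \[N\].
#' @examples
#' ding_force(1000, 0.5, 2.5e-6, 0.25e-6) / hertz_force(1000, 0.5, 2.5e-6, 0.25e-6)
#' @export
ding_force <- function(E, nu, R, delta, clip = FALSE) {
  f <- hertz_force(E, nu, R, delta, clip = clip)
  d <- if (clip) pmax(delta, 0) else delta
  corr <- 1 - 0.15 * d / R
  if (any(corr[d > 0] <= 0))
    stop("correction factor (1 - 0.15*delta/R) non-positive: indentation too large for the model",
         call. = FALSE)
  f * corr
}

#' Explicit Kelvin-Voigt-Maxwell force-indentation relation
#'
#' Closed-form contact force of a spherical probe indenting a KVM
#' half-space at constant velocity `v`:
#' \deqn{F(\delta) = F_{el}(E_0,\delta)
#'   + F_{el}(E_1,\delta)\,e^{-\alpha_1 \delta/(v\lambda)}
#'   + \alpha_2\,\delta^{\alpha_3} R^{\alpha_4}\,\eta\,v}
#' where \eqn{F_{el}} is the corrected Hertz force ([ding_force()]). The
#' elapsed contact time is inferred as `delta / v` (constant-velocity
#' approach), so the Maxwell arm decays with indentation. With the default
#' `alpha3 = alpha4 = 1/2` the viscous term is
#' `alpha2 * sqrt(R * delta) * eta * v`.
#'
#' @param p A [viscoelastic_params()] object.
#' @param consts A [calibration_constants()] object.
#' @param R Indenter radius \[m\] (use the effective radius for
#'   sphere-on-sphere contact).
#' @param v Indenter (piezo) approach velocity \[m/s\], `> 0`.
#' @param delta Indentation depth \[m\]; vectorised.
#' @param clip If `TRUE`, negative indentations give zero force.
#' @param terms If `TRUE`, return a 3-column matrix with the Kelvin-Voigt
#'   elastic, Maxwell, and viscous addends instead of their sum (fit
#'   diagnostics).
#' @return Force \[N\] (vector), or a `length(delta) x 3` matrix with
#'   columns `elastic`, `maxwell`, `viscous` when `terms = TRUE`.
#' @examples
#' p <- viscoelastic_params(E0 = 1000, E1 = 1000, lam = 0.1, eta = 1)
#' kvm_force(p, calibration_constants(), R = 2.5e-6, v = 5e-6, delta = 0.5e-6)
#' @export
kvm_force <- function(p, consts = calibration_constants(), R, v, delta,
                      clip = FALSE, terms = FALSE) {
  stopifnot(inherits(p, "viscoelastic_params"),
            inherits(consts, "calibration_constants"),
            is.numeric(v), length(v) == 1L, v > 0)
  if (p$E1 > 0 && p$lam <= 0)
    stop("lam must be positive when E1 > 0 (Maxwell arm undefined)",
         call. = FALSE)
  if (clip) {
    delta <- pmax(delta, 0)
  } else if (any(delta < 0)) {
    stop("negative indentation; use clip = TRUE for the piecewise-contact convention",
         call. = FALSE)
  }
  f_el0 <- ding_force(p$E0, p$nu, R, delta)
  if (p$E1 > 0) {
    decay <- exp(-consts$alpha1 * delta / (v * p$lam))
    f_mx <- ding_force(p$E1, p$nu, R, delta) * decay
  } else {
    f_mx <- numeric(length(delta))
  }
  f_vis <- consts$alpha2 * delta^consts$alpha3 * R^consts$alpha4 * p$eta * v
  if (terms) {
    cbind(elastic = f_el0, maxwell = f_mx, viscous = f_vis)
  } else {
    f_el0 + f_mx + f_vis
  }
}

#' Unrelaxed and apparent elastic moduli of a KVM material
#'
#' The unrelaxed modulus `Eu = E0 + E1` is the total elasticity before any
#' Maxwell relaxation; the apparent modulus
#' `Eapp = E0 + E1 * exp(-alpha1 * delta_max / (v * lam))` is the elasticity
#' experienced over the timescale of the indentation (`t_ind = delta_max/v`).
#' Both are more robust than `E1` and `lam` individually when the relaxation
#' time is far from `t_ind`.
#'
#' @param p A [viscoelastic_params()] object.
#' @param consts A [calibration_constants()] object.
#' @param delta_max Maximum indentation reached \[m\], `> 0`.
#' @param v Approach velocity \[m/s\], `> 0`.
#' @return A list of class `"derived_moduli"` with `Eu` \[Pa\], `Eapp` \[Pa\]
#'   and `t_ind` \[s\]; always `E0 <= Eapp <= Eu`.
#' @examples
#' p <- viscoelastic_params(1000, 1000, lam = 0.1, eta = 1)
#' derived_moduli(p, delta_max = 0.5e-6, v = 5e-6) # Eapp ~ 1694 Pa
#' @export
derived_moduli <- function(p, consts = calibration_constants(),
                           delta_max, v) {
  stopifnot(inherits(p, "viscoelastic_params"),
            is.numeric(delta_max), delta_max > 0,
            is.numeric(v), v > 0)
  Eu <- p$E0 + p$E1
  Eapp <- if (p$E1 > 0) {
    p$E0 + p$E1 * exp(-consts$alpha1 * delta_max / (v * p$lam))
  } else {
    p$E0
  }
  structure(list(Eu = Eu, Eapp = Eapp, t_ind = delta_max / v),
            class = "derived_moduli")
}

#' @export
print.derived_moduli <- function(x, ...) {
  cat(sprintf("Eu = %.4g Pa, Eapp = %.4g Pa, t_ind = %.4g s\n",
              x$Eu, x$Eapp, x$t_ind))
  invisible(x)
}

#' Stokes drag on the spherical probe
#'
#' `F = 6 * pi * mu * R * v`, the hydrodynamic drag of the bead moving
#' through the surrounding liquid. Reported alongside fits as a
#' negligibility diagnostic: for a 2.5 um bead at 5 um/s in water it is
#' about 2.4e-4 nN, four orders of magnitude below the measured contact
#' forces.
#'
#' @param mu Liquid viscosity \[Pa s\].
#' @param R Bead radius \[m\].
#' @param v Velocity \[m/s\].
#' @return Drag force \[N\].
#' @examples
#' stokes_drag(1e-3, 2.5e-6, 5e-6) * 1e9 # nN
#' @export
stokes_drag <- function(mu, R, v) {
  stopifnot(is.numeric(mu), mu >= 0, is.numeric(R), R > 0,
            is.numeric(v), v >= 0)
  6 * pi * mu * R * v
}

#' Remaining Maxwell-arm fraction over the indentation time
#'
#' `exp(-t_ind / lam)`: the fraction of the Maxwell modulus `E1` still
#' unrelaxed after one indentation time. This is the quantity behind the
#' relaxation-time fitting box `[t_ind/5, 10*t_ind]`: at the upper bound
#' 90% of `E1` remains (the material looks purely elastic with modulus
#' `E0 + E1`), at the lower bound 0.6% remains (the material looks like a
#' pure Kelvin-Voigt solid and `E1` becomes arbitrary).
#'
#' @param lam Relaxation time \[s\], `> 0`.
#' @param t_ind Indentation time \[s\], `> 0`.
#' @return Fraction in `(0, 1)`.
#' @examples
#' relaxation_remaining(lam = 10, t_ind = 1)  # 0.905
#' relaxation_remaining(lam = 0.2, t_ind = 1) # 0.0067
#' @export
relaxation_remaining <- function(lam, t_ind) {
  stopifnot(is.numeric(lam), all(lam > 0), is.numeric(t_ind), all(t_ind > 0))
  exp(-t_ind / lam)
}
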