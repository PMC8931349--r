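#' Configuration of the KVM curve fit
#'
#' @param nu Poisson ratio held fixed during fitting (default 0.5).
#' @param maxit Maximum Nelder-Mead iterations per start (default 4000).
#' @param reltol Relative convergence tolerance on the objective
#'   (default 1e-12).
#' @param cp_window_steps Half-width of the contact-point refit window, in
#'   multiples of the contact-point scan step (default 20). Prevents the
#'   refit from wandering into the baseline.
#' @param cp_window_frac Floor on the refit half-width as a fraction of the
#'   initial maximum indentation (default 0.15). The initial estimate sits
#'   systematically early on viscous materials (their force onset is
#'   steeper than the cubic-over-quadratic branch can follow), by an amount
#'   set by the physics, not by the sampling step — so the window must not
#'   shrink with denser sampling.
#' @param lam_lo_mult,lam_hi_mult The relaxation-time box as multiples of
#'   the indentation time `t_ind` (defaults 1/5 and 10). At the upper bound
#'   90% of `E1` is still unrelaxed after `t_ind`; at the lower bound 0.6%
#'   remains — beyond either, `E1` and `lam` are no longer identifiable.
#' @param restarts Number of additional deterministic restarts from
#'   perturbed starting points (default 1).
#' @param boundary_tol Fraction of the box width within which a fitted
#'   `lam` is flagged as bound-saturated (default 0.01).
#' @param trim_setpoint Drop samples whose force exceeds the metadata
#'   setpoint (instrument overshoot violates the constant-velocity
#'   assumption); default `TRUE`.
#' @param consts [calibration_constants()] used in the model.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(nu = 0.5, maxit = 4000L, reltol = 1e-12,
                       cp_window_steps = 20L, cp_window_frac = 0.15,
                       lam_lo_mult = 1 / 5, lam_hi_mult = 10,
                       restarts = 1L, boundary_tol = 0.01,
                       trim_setpoint = TRUE,
                       consts = calibration_constants()) {
  stopifnot(nu >= 0, nu <= 0.5 + 1e-12, maxit > 0, reltol > 0,
            cp_window_steps > 0, cp_window_frac > 0, lam_lo_mult > 0,
            lam_hi_mult > lam_lo_mult, restarts >= 0, boundary_tol > 0,
            inherits(consts, "calibration_constants"))
  structure(list(nu = nu, maxit = as.integer(maxit), reltol = reltol,
                 cp_window_steps = as.integer(cp_window_steps),
                 cp_window_frac = cp_window_frac,
                 lam_lo_mult = lam_lo_mult, lam_hi_mult = lam_hi_mult,
                 restarts = as.integer(restarts),
                 boundary_tol = boundary_tol,
                 trim_setpoint = trim_setpoint, consts = consts),
            class = "fit_config")
}

#' Effective contact radius for sphere-on-sphere contact
#'
#' Series combination of the probe and sample curvatures:
#' `1/Reff = 1/Rcell + 1/Rbead`. Used instead of the bead radius when a
#' rounded (mitotic-like) cell is probed.
#'
#' @param Rcell Cell radius \[m\].
#' @param Rbead Bead radius \[m\].
#' @return Effective radius \[m\].
#' @examples
#' effective_radius(7.5e-6, 2.5e-6) * 1e6 # 1.875 um
#' @export
effective_radius <- function(Rcell, Rbead) {
  stopifnot(is.numeric(Rcell), all(Rcell > 0),
            is.numeric(Rbead), all(Rbead > 0))
  1 / (1 / Rcell + 1 / Rbead)
}

#' Confinement correction of the indentation of a rounded cell
#'
#' A rounded cell resting on a rigid dish deforms both at the probe contact
#' and against the dish; the measured piezo indentation over-states the
#' probe-side indentation. The correction rescales the indentation signal
#' before fitting: `delta_corrected = K * delta_measured` with
#' `K = Rcell^(1/3) / (Rcell^(1/3) + Reff^(1/3))`.
#'
#' @param delta_measured Measured indentation \[m\]; vectorised.
#' @param Rcell Cell radius \[m\].
#' @param Reff Effective contact radius \[m\] (see [effective_radius()]).
#' @return Corrected indentation \[m\], with attribute `"K"`.
#' @examples
#' attr(confinement_correction(1e-6, 7.5e-6, 1.875e-6), "K") # 0.613
#' @export
confinement_correction <- function(delta_measured, Rcell, Reff) {
  stopifnot(is.numeric(Rcell), Rcell > 0, is.numeric(Reff), Reff > 0)
  K <- Rcell^(1 / 3) / (Rcell^(1 / 3) + Reff^(1 / 3))
  structure(K * delta_measured, K = K)
}

## Ding basis at unit modulus: F = E * .ding_basis(nu, R, delta)
.ding_basis <- function(nu, R, delta) {
  (4 / 3) / (1 - nu^2) * sqrt(R) * delta^1.5 * (1 - 0.15 * delta / R)
}

## piecewise model force on the separation axis (baseline already removed)
.model_force <- function(delta, p, consts, R, v) {
  out <- numeric(length(delta))
  pos <- delta > 0
  if (any(pos))
    out[pos] <- kvm_force(p, consts, R = R, v = v, delta = delta[pos])
  out
}

## unvalidated vectorised piecewise KVM force (zero before contact); must
## mirror kvm_force()/ding_force() exactly (asserted by test on random
## inputs)
.kvm_piecewise_fast <- function(E0, E1, lam, eta, nu, consts, R, v, delta) {
  pos <- delta > 0
  d <- delta[pos]
  el <- (4 / 3) / (1 - nu^2) * sqrt(R) * d^1.5 * (1 - 0.15 * d / R)
  f <- E0 * el +
    eta * v * consts$alpha2 * d^consts$alpha3 * R^consts$alpha4
  if (E1 > 0)
    f <- f + E1 * el * exp(-consts$alpha1 * d / (v * lam))
  out <- numeric(length(delta))
  out[pos] <- f
  out
}

#' Fit the explicit KVM relation to an approach curve
#'
#' Minimises the sum of squared force residuals over the full approach
#' segment — zero force before the contact point, the explicit KVM relation
#' beyond — over `(E0, E1, lam, eta, cp)`. `nu` is fixed (default 0.5).
#' Because the model is linear in `E0`, `E1` and `eta`, those three are
#' profiled out exactly at every step by non-negative least squares
#' (active-set over the sign patterns), and only `(lam, cp)` are searched
#' by Nelder-Mead: `lam` through a logistic transform onto
#' `[t_ind/5, 10*t_ind]` (outside that box the Maxwell arm is not
#' identifiable), `cp` through a tanh transform onto a window around the
#' initial estimate from [estimate_contact_point()]. Profiling removes the
#' `E0`/`E1` compensation ridge on which a full five-parameter simplex
#' stalls. When a box edge fits the data as well as the interior optimum,
#' the edge is adopted and the corresponding bound flag raised.
#'
#' A corrected-Hertz-only fit (contact point by golden-section search,
#' modulus profiled) always runs first; its solution seeds one simplex
#' start, so the KVM residual can never exceed the elastic residual. The
#' fit uses no random numbers — restarts are deterministic.
#'
#' For a rounded cell (geometry with `Rcell`), the effective radius
#' replaces the bead radius and the indentation is rescaled by the
#' confinement factor `K` before the model is evaluated.
#'
#' @param approach A [force_curve()] (approach segment; a mixed curve is
#'   split automatically).
#' @param geom A [probe_geometry()]; defaults to the curve metadata's.
#' @param cfg A [fit_config()].
#' @param cpfit Optional precomputed [estimate_contact_point()] result.
#' @return An object of class `"kvm_fit"`: `params`
#'   ([viscoelastic_params()]), `cp` (refit, separation axis, \[m\]),
#'   `cp_init`, `delta_max` \[m\], `t_ind` \[s\], `derived`
#'   ([derived_moduli()]), `sse` \[N^2\], `rms` \[N\], `flags` (logical:
#'   `lam_at_upper_bound`, `lam_at_lower_bound`, `E1_at_zero`,
#'   `converged`), `lam_bounds`, `K`, `R_contact`, `v`, `n`,
#'   `sse_ding`, `stokes_drag_N`.
#' @export
fit_kvm_curve <- function(approach, geom = NULL, cfg = fit_config(),
                          cpfit = NULL) {
  stopifnot(inherits(approach, "force_curve"), inherits(cfg, "fit_config"))
  if (any(approach$segment == "retract"))
    approach <- split_segments(approach)$approach
  if (is.null(geom)) geom <- approach$meta$geom
  if (is.null(geom))
    stop("probe geometry missing (pass geom= or set it in curve metadata)",
         call. = FALSE)
  stopifnot(inherits(geom, "probe_geometry"))

  if (is.null(cpfit)) cpfit <- estimate_contact_point(approach)
  curve <- remove_baseline(approach, cpfit)
  sep <- tip_sample_separation(curve)
  F <- curve$F

  v <- curve$meta$v
  if (is.null(v)) v <- stats::median(diff(curve$z) / diff(curve$t))
  stopifnot(v > 0)

  if (cfg$trim_setpoint && !is.null(curve$meta$setpoint)) {
    keep <- F <= curve$meta$setpoint * (1 + 1e-9)
    sep <- sep[keep]; F <- F[keep]
  }

  rounded <- !is.null(geom$Rcell)
  R_contact <- if (rounded) geom$Reff else geom$R
  Kfac <- if (rounded) geom$K else 1

  cp0 <- cpfit$cp
  consts <- cfg$consts
  nu <- cfg$nu
  F_scale <- max(abs(F))

  dmax0 <- max(sep - cp0) * Kfac
  if (dmax0 <= 0) stop("no indentation beyond the contact point", call. = FALSE)
  w <- max(cfg$cp_window_steps * cpfit$step,
           cfg$cp_window_frac * max(sep - cp0))
  t_ind0 <- dmax0 / v
  lam_lo <- cfg$lam_lo_mult * t_ind0
  lam_hi <- cfg$lam_hi_mult * t_ind0

  ## The moduli and viscosity enter the model linearly, so for any (lam, cp)
  ## the best (E0, E1, eta) >= 0 follow from non-negative least squares in
  ## closed form (active-set over the 2^3 sign patterns). Only (lam, cp) are
  ## searched by the simplex; this removes the E0/E1 compensation ridge that
  ## stalls a full five-parameter simplex.
  inner_fit <- function(lam, cp, what = c("E1", "eta")) {
    delta <- (sep - cp) * Kfac
    pos <- delta > 0
    if (!any(pos)) return(list(sse = sum((F / F_scale)^2),
                               theta = c(0, 0, 0)))
    d <- delta[pos]
    cols <- list(E0 = .ding_basis(nu, R_contact, d))
    if ("E1" %in% what)
      cols$E1 <- cols$E0 * exp(-consts$alpha1 * d / (v * lam))
    if ("eta" %in% what)
      cols$eta <- consts$alpha2 * d^consts$alpha3 * R_contact^consts$alpha4 * v
    X <- do.call(cbind, cols)
    y <- F[pos]
    sse_rest <- sum(F[!pos]^2)
    XtX <- crossprod(X); Xty <- crossprod(X, y)
    best_s <- NULL
    subsets <- lapply(rev(seq_len(2^ncol(X))) - 1L,
                      function(m) which(bitwAnd(m, 2^(seq_len(ncol(X)) - 1L)) > 0))
    for (sub in subsets) {
      if (length(sub) == 0L) {
        th <- numeric(ncol(X)); sse <- sum(y^2) + sse_rest
      } else {
        th_s <- tryCatch(solve(XtX[sub, sub, drop = FALSE], Xty[sub]),
                         error = function(e) NULL)
        if (is.null(th_s) || any(th_s < 0)) next
        th <- numeric(ncol(X)); th[sub] <- th_s
        sse <- sum((y - X %*% th)^2) + sse_rest
      }
      if (is.null(best_s) || sse < best_s$sse) best_s <- list(sse = sse, th = th)
      if (length(sub) == ncol(X) && !is.null(best_s)) break  # unconstrained feasible
    }
    theta <- c(0, 0, 0); names(theta) <- c("E0", "E1", "eta")
    theta[names(cols)] <- best_s$th
    list(sse = best_s$sse / F_scale^2, theta = theta)
  }

  ## --- Ding-only pre-fit: cp by golden-section, E0 profiled out
  obj_ding <- function(u) inner_fit(lam = 1, cp = cp0 + w * tanh(u),
                                    what = character(0))$sse
  od <- stats::optimize(obj_ding, c(-3, 3), tol = 1e-10)
  cp_ding_u <- od$minimum
  ding_sol <- inner_fit(1, cp0 + w * tanh(cp_ding_u), character(0))
  E0_ding <- unname(ding_sol$theta["E0"])
  sse_ding <- ding_sol$sse * F_scale^2

  obj <- function(u) {
    lam <- lam_lo + (lam_hi - lam_lo) * stats::plogis(u[1])
    inner_fit(lam, cp0 + w * tanh(u[2]))$sse
  }
  mid_u <- stats::qlogis(pmin(pmax((t_ind0 - lam_lo) / (lam_hi - lam_lo),
                                   0.05), 0.95))
  starts <- list(c(mid_u, 0), c(stats::qlogis(0.95), cp_ding_u))
  if (cfg$restarts >= 1L)
    starts <- c(starts, list(c(stats::qlogis(0.05), 0)))
  if (cfg$restarts >= 2L)
    starts <- c(starts, list(c(stats::qlogis(0.5), cp_ding_u)))

  nm <- function(x0) {
    stats::optim(x0, obj, method = "Nelder-Mead",
                 control = list(maxit = cfg$maxit, reltol = cfg$reltol))
  }
  best <- NULL
  for (s in starts) {
    fit <- nm(s)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  for (pass in seq_len(6L)) {
    fit <- nm(best$par)
    done <- fit$value >= best$value * (1 - 1e-10)
    if (fit$value < best$value) best <- fit
    if (done || best$value < 1e-22) break
  }

  lam <- lam_lo + (lam_hi - lam_lo) * stats::plogis(best$par[1])
  cp <- cp0 + w * tanh(best$par[2])
  sol <- inner_fit(lam, cp)
  sse_scaled <- sol$sse

  ## data that do not pin lam inside the box are resolved AT the box edge:
  ## if an edge fits as well or better, adopt it (and flag it below)
  for (lam_edge in c(lam_lo, lam_hi)) {
    sol_e <- inner_fit(lam_edge, cp)
    if (sol_e$sse < sse_scaled * (1 + 1e-9)) {
      lam <- lam_edge; sol <- sol_e; sse_scaled <- sol_e$sse
    }
  }

  E0 <- unname(sol$theta["E0"]); E1 <- unname(sol$theta["E1"])
  eta <- unname(sol$theta["eta"])
  params <- viscoelastic_params(E0 = E0, E1 = E1,
                                lam = if (E1 > 0) lam else 0,
                                eta = eta, nu = nu)

  delta_max <- max(sep - cp) * Kfac
  t_ind <- delta_max / v
  band <- cfg$boundary_tol * (lam_hi - lam_lo)
  e1_zero <- E1 <= max(0.01 * E0, 1)
  flags <- list(
    # bound proximity is only meaningful while the Maxwell arm carries load
    lam_at_upper_bound = !e1_zero && lam >= lam_hi - band,
    lam_at_lower_bound = !e1_zero && lam <= lam_lo + band,
    E1_at_zero = e1_zero,
    no_contact = FALSE,
    converged = best$convergence == 0L
  )
  if (!flags$converged)
    warning("Nelder-Mead iteration limit reached; result flagged, not rejected")

  sse <- sse_scaled * F_scale^2
  structure(list(
    params = params,
    cp = cp, cp_init = cp0,
    delta_max = delta_max, t_ind = t_ind,
    derived = derived_moduli(params, consts, delta_max, v),
    sse = sse, rms = sqrt(sse / length(F)),
    sse_ding = sse_ding, E0_ding = E0_ding,
    flags = flags, lam_bounds = c(lam_lo, lam_hi),
    K = Kfac, R_contact = R_contact, v = v, n = length(F),
    consts = consts,
    stokes_drag_N = stokes_drag(1e-3, geom$R, v),
    baseline = list(m = cpfit$m, d = cpfit$d)
  ), class = "kvm_fit")
}

#' @export
print.kvm_fit <- function(x, ...) {
  cat("KVM fit:\n")
  cat(sprintf("  E0 = %.4g Pa, E1 = %.4g Pa, lambda = %.4g s, eta = %.4g Pa s\n",
              x$params$E0, x$params$E1, x$params$lam, x$params$eta))
  cat(sprintf("  Eu = %.4g Pa, Eapp = %.4g Pa (delta_max = %.3g um, t_ind = %.3g s)\n",
              x$derived$Eu, x$derived$Eapp, x$delta_max * 1e6, x$t_ind))
  cat(sprintf("  cp = %.4g um (init %.4g um), rms residual = %.3g nN, n = %d\n",
              x$cp * 1e6, x$cp_init * 1e6, x$rms * 1e9, x$n))
  on <- names(Filter(isTRUE, x$flags[setdiff(names(x$flags), "converged")]))
  if (length(on)) cat("  flags:", paste(on, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a purely elastic (corrected-Hertz) model to an approach curve
#'
#' Same pipeline as [fit_kvm_curve()] but with the Maxwell arm and the
#' viscous term fixed at zero: only `(E0, cp)` are optimised. Useful as
#' the nested reference model.
#'
#' @inheritParams fit_kvm_curve
#' @return A list with `E0` \[Pa\], `sse` \[N^2\] and `n`.
#' @export
fit_ding_curve <- function(approach, geom = NULL, cfg = fit_config(),
                           cpfit = NULL) {
  res <- fit_kvm_curve(approach, geom = geom, cfg = cfg, cpfit = cpfit)
  list(E0 = res$E0_ding, sse = res$sse_ding, n = res$n)
}

#' Bottom-effect (finite sample thickness) force over-estimation
#'
#' A thin viscoelastic layer on a rigid support resists indentation more
#' than a half-space; fitting half-space models therefore over-estimates
#' the moduli. Using the simplified relaxation function
#' `phi(t) = Eapp + eta*dirac(t)`, the first two terms of the thin-layer
#' force series for a spherical probe are
#' \deqn{F_0 = \frac{16}{9}\sqrt{R I}\left[\frac{9}{2}\eta v + E_{app} I\right]}
#' \deqn{F_1 = 1.133\,\frac{16}{9}\,\frac{R I}{h}\left[6 \eta v + E_{app} I\right]}
#' and the relative over-estimation incurred by neglecting the finite
#' thickness is `F1/F0`. Higher-order terms, `O(I^(3/2)/h^2)`, are
#' truncated.
#'
#' @param Eapp Apparent elastic modulus \[Pa\].
#' @param eta Apparent viscosity \[Pa s\].
#' @param R Probe radius \[m\].
#' @param h Sample thickness \[m\], `> 0`.
#' @param v Indentation rate \[m/s\].
#' @param I Indentation depth \[m\].
#' @return A list with `F0` \[N\] (semi-infinite term), `F1` \[N\]
#'   (first-order thickness term) and `overestimate` (= `F1/F0`).
#' @examples
#' I <- indentation_at_force(2.5e-9, Eapp = 2700, eta = 1.71, R = 2.5e-6, v = 2e-6)
#' bottom_effect_estimate(2700, 1.71, 2.5e-6, h = 15e-6, v = 2e-6, I = I)
#' @export
bottom_effect_estimate <- function(Eapp, eta, R, h, v, I) {
  stopifnot(is.numeric(h), length(h) == 1L)
  if (h <= 0) stop("sample thickness h must be positive", call. = FALSE)
  stopifnot(Eapp >= 0, eta >= 0, R > 0, v >= 0, all(I >= 0))
  F0 <- (16 / 9) * sqrt(R * I) * ((9 / 2) * eta * v + Eapp * I)
  F1 <- 1.133 * (16 / 9) * (R * I / h) * (6 * eta * v + Eapp * I)
  list(F0 = F0, F1 = F1, overestimate = F1 / F0)
}

#' Indentation at which the semi-infinite contact force reaches a target
#'
#' Inverts the `F0` term of [bottom_effect_estimate()] for the indentation
#' `I`, e.g. to evaluate the bottom-effect at a given force setpoint.
#'
#' @inheritParams bottom_effect_estimate
#' @param F_target Target force \[N\], `> 0`.
#' @return Indentation \[m\].
#' @export
indentation_at_force <- function(F_target, Eapp, eta, R, v) {
  stopifnot(F_target > 0, Eapp > 0 || eta * v > 0, R > 0)
  f <- function(I) (16 / 9) * sqrt(R * I) * ((9 / 2) * eta * v + Eapp * I) -
    F_target
  hi <- 1e-7
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(0, hi), tol = 1e-18)$root
}

#' Collect KVM fit results into a data frame
#'
#' One row per curve with the standard reporting columns (SI units in the
#' column names). `flags` is a semicolon-joined list of raised flags.
#'
#' @param fits A list of `"kvm_fit"` objects.
#' @param curve_ids,groups,cells Optional character vectors recycled along
#'   `fits`; taken from each curve's metadata by [cmd_fit()].
#' @return A `data.frame` with columns `curve_id`, `group`, `cell`,
#'   `E0_Pa`, `E1_Pa`, `lambda_s`, `eta_Pa_s`, `Eu_Pa`, `Eapp_Pa`, `cp_m`,
#'   `delta_max_m`, `t_ind_s`, `sse`, `flags`.
#' @export
fit_results_df <- function(fits, curve_ids = NULL, groups = NULL,
                           cells = NULL) {
  stopifnot(is.list(fits), all(vapply(fits, inherits, TRUE, "kvm_fit")))
  n <- length(fits)
  pick <- function(x, default) if (is.null(x)) rep(default, n) else rep_len(as.character(x), n)
  flag_str <- function(f) {
    on <- names(Filter(isTRUE, f$flags[c("lam_at_upper_bound",
                                         "lam_at_lower_bound",
                                         "E1_at_zero", "no_contact")]))
    if (length(on)) paste(on, collapse = ";") else ""
  }
  data.frame(
    curve_id = pick(curve_ids, NA_character_),
    group = pick(groups, NA_character_),
    cell = pick(cells, NA_character_),
    E0_Pa = vapply(fits, function(f) f$params$E0, 0),
    E1_Pa = vapply(fits, function(f) f$params$E1, 0),
    lambda_s = vapply(fits, function(f) f$params$lam, 0),
    eta_Pa_s = vapply(fits, function(f) f$params$eta, 0),
    Eu_Pa = vapply(fits, function(f) f$derived$Eu, 0),
    Eapp_Pa = vapply(fits, function(f) f$derived$Eapp, 0),
    cp_m = vapply(fits, function(f) f$cp, 0),
    delta_max_m = vapply(fits, function(f) f$delta_max, 0),
    t_ind_s = vapply(fits, function(f) f$t_ind, 0),
    sse = vapply(fits, function(f) f$sse, 0),
    flags = vapply(fits, flag_str, ""),
    stringsAsFactors = FALSE
  )
}

#' Write fit results to CSV with a JSON provenance sidecar
#'
#' The CSV is deterministic (no timestamp); run provenance — calibration
#' constants, Poisson ratio, package version, configuration echo and
#' timestamp — goes to `<basename>_provenance.json`.
#'
#' @param df A data frame from [fit_results_df()].
#' @param path Output CSV path.
#' @param cfg The [fit_config()] used.
#' @param extra Optional named list merged into the provenance record.
#' @return `path`, invisibly.
#' @export
write_fit_results <- function(df, path, cfg = fit_config(), extra = list()) {
  utils::write.csv(df, path, row.names = FALSE)
  prov <- c(list(
    software = "afmkvm",
    version = as.character(utils::packageVersion("afmkvm")),
    constants = unclass(cfg$consts),
    nu = cfg$nu,
    lam_bounds_mult = c(cfg$lam_lo_mult, cfg$lam_hi_mult),
    n_curves = nrow(df),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(prov,
                       paste0(tools::file_path_sans_ext(path), "_provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
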