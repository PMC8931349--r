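#' Recipe for a synthetic KVM approach curve
#'
#' Describes everything needed to generate a ground-truth force curve:
#' material, geometry, kinematics, acquisition and noise. Defaults emulate
#' a typical live-cell measurement with a 2.5 um bead at 5 um/s, a 0.05 N/m
#' cantilever, and an indentation of 0.8 um (within the 0.5-1 um range a
#' 2-4 nN setpoint produces on such samples).
#'
#' @param params [viscoelastic_params()] of the half-space.
#' @param geom [probe_geometry()]. If it carries `Rcell`, the curve is
#'   generated with the sphere-on-sphere convention: effective radius in
#'   the contact model and confinement factor `K` applied to the
#'   indentation (the same convention the fit applies).
#' @param v Piezo approach velocity \[m/s\].
#' @param delta_max Target maximum indentation \[m\].
#' @param rate Sampling rate \[Hz\]; the 5 kHz default matches typical
#'   force-spectroscopy acquisition (a ~0.3 s approach recorded as a
#'   1000-2000 sample segment). Must give at least 200 approach samples.
#' @param k Cantilever spring constant \[N/m\].
#' @param baseline_m Baseline slope \[N/m\] (on the separation axis).
#' @param baseline_d Baseline force offset \[N\].
#' @param cp_offset Contact position on the piezo axis, measured from the
#'   ramp start \[m\] — i.e. the pre-contact travel.
#' @param noise_sd Standard deviation of additive i.i.d. Gaussian force
#'   noise \[N\].
#' @param with_retract Append a mirrored retract ramp carrying baseline
#'   force only (for segment-splitting tests; the KVM relation is
#'   approach-only).
#' @param seed Integer seed; the same spec and seed give a bit-identical
#'   curve.
#' @return A list of class `"synthetic_curve_spec"`.
#' @export
synthetic_curve_spec <- function(params = viscoelastic_params(E0 = 1000,
                                                              E1 = 800,
                                                              lam = 0.1,
                                                              eta = 2),
                                 geom = probe_geometry(R = 2.5e-6),
                                 v = 5e-6, delta_max = 0.8e-6,
                                 rate = 5000, k = 0.05,
                                 baseline_m = 0, baseline_d = 0,
                                 cp_offset = 0.5e-6, noise_sd = 0,
                                 with_retract = FALSE, seed = 1L) {
  stopifnot(inherits(params, "viscoelastic_params"),
            inherits(geom, "probe_geometry"),
            v > 0, delta_max > 0, rate > 0, k > 0, cp_offset > 0,
            noise_sd >= 0)
  spec <- structure(list(params = params, geom = geom, v = v,
                         delta_max = delta_max, rate = rate, k = k,
                         baseline_m = baseline_m, baseline_d = baseline_d,
                         cp_offset = cp_offset, noise_sd = noise_sd,
                         with_retract = isTRUE(with_retract),
                         seed = as.integer(seed)),
                    class = "synthetic_curve_spec")
  if (.spec_n_approach(spec) < 200L)
    stop("spec must yield at least 200 approach samples; raise rate or lengthen the ramp",
         call. = FALSE)
  spec
}

.spec_n_approach <- function(spec) {
  Kfac <- if (!is.null(spec$geom$Rcell)) spec$geom$K else 1
  ## piezo travel: pre-contact + indentation (in measured units) + maximal
  ## cantilever deflection headroom
  z_turn <- spec$cp_offset + spec$delta_max / Kfac + 2 * .spec_peak_force(spec) / spec$k
  floor(z_turn / spec$v * spec$rate) + 1L
}

.spec_peak_force <- function(spec) {
  Kfac <- if (!is.null(spec$geom$Rcell)) spec$geom$K else 1
  R <- if (!is.null(spec$geom$Rcell)) spec$geom$Reff else spec$geom$R
  kvm_force(spec$params, calibration_constants(), R = R, v = spec$v,
            delta = spec$delta_max * 1)
}

#' Generate a synthetic KVM approach curve with embedded ground truth
#'
#' Simulates what the instrument records during a constant-velocity
#' approach: the piezo advances at `v`; beyond the contact point the sample
#' pushes back with the explicit KVM force at the true tip-sample
#' separation, which itself depends on the cantilever deflection `F/k`.
#' The implicit per-sample equation `F = baseline + F_KVM(z - F/k - cp)`
#' is solved by damped fixed-point iteration (the contraction factor is
#' `dF/ddelta / k`, far below 1 for the cantilevers and materials
#' emulated). Gaussian force noise is added afterwards, under the spec
#' seed. The generator's ground truth (true parameters, contact point on
#' both axes, turn index) is embedded in the curve metadata for test
#' harnesses.
#'
#' The generator and the fit share conventions but not code paths for the
#' inverse problem; an independent forward model is
#' [hereditary_integral_force()].
#'
#' @param spec A [synthetic_curve_spec()].
#' @return A [force_curve()] with `meta$ground_truth`.
#' @export
generate_kvm_curve <- function(spec) {
  stopifnot(inherits(spec, "synthetic_curve_spec"))
  rounded <- !is.null(spec$geom$Rcell)
  Kfac <- if (rounded) spec$geom$K else 1
  R <- if (rounded) spec$geom$Reff else spec$geom$R
  consts <- calibration_constants()

  n <- .spec_n_approach(spec)
  t <- seq(0, by = 1 / spec$rate, length.out = n)
  z <- spec$v * t
  cp <- spec$cp_offset

  ## solve F = m*(zeta-cp) + d + KVM(K*(zeta-cp)) with zeta = z - F/k
  F <- numeric(n)
  for (it in 1:60) {
    zeta <- z - F / spec$k
    delta <- pmax((zeta - cp) * Kfac, 0)
    Fnew <- spec$baseline_m * (zeta - cp) + spec$baseline_d +
      kvm_force(spec$params, consts, R = R, v = spec$v, delta = delta)
    if (max(abs(Fnew - F)) < 1e-18) { F <- Fnew; break }
    F <- Fnew
  }
  zeta <- z - F / spec$k
  segment <- rep("approach", n)

  if (spec$with_retract) {
    t_r <- t[n] + seq_len(n - 1L) / spec$rate
    z_r <- z[n] - spec$v * seq_len(n - 1L) / spec$rate
    F_r <- spec$baseline_m * (z_r - cp) + spec$baseline_d
    t <- c(t, t_r); z <- c(z, z_r); F <- c(F, F_r)
    segment <- c(segment, rep("retract", n - 1L))
  }

  if (spec$noise_sd > 0) {
    F <- F + .with_seed(spec$seed, stats::rnorm(length(F), 0, spec$noise_sd))
  }

  truth <- list(
    E0 = spec$params$E0, E1 = spec$params$E1, lam = spec$params$lam,
    eta = spec$params$eta, nu = spec$params$nu,
    cp = cp, separation = zeta, turn_index = n,
    delta_max = max((zeta - cp)[seq_len(n)]) * Kfac,
    K = Kfac, R_contact = R
  )
  force_curve(t, z, F, segment = segment,
              meta = list(k = spec$k, v = spec$v, geom = spec$geom,
                          ground_truth = truth))
}

## evaluate expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Hereditary-integral (Lee-Radok type) viscoelastic contact force
#'
#' Independent forward oracle for the approach segment: evaluates
#' \deqn{F(t) = \frac{4\sqrt{R}}{3(1-\nu^2)}\left[
#'   \int_0^t \left(E_0 + E_1 e^{-(t-\tau)/\lambda}\right)
#'   \frac{d}{d\tau}\delta^{3/2}(\tau)\,d\tau
#'   + \eta\,\frac{3}{2}\sqrt{\delta(t)}\,\dot\delta(t)\right]}
#' i.e. the convolution of the KVM relaxation function
#' `phi(t) = E0 + E1*exp(-t/lam) + eta*dirac(t)` with the rate of the
#' Hertzian indentation kernel, the Dirac term evaluated in closed form.
#' Quadrature is trapezoidal on the uniform time grid with the kernel rate
#' from central differences; halving the step changes the standard
#' constant-velocity result by well under 0.1%.
#'
#' This code path shares nothing with [kvm_force()] — no calibration
#' constants, no large-indentation correction — so agreement between the
#' two is a meaningful cross-check, not a tautology.
#'
#' @param params [viscoelastic_params()] (the `eta` field is the Dirac
#'   weight of the relaxation function).
#' @param R Probe radius \[m\].
#' @param delta Sampled indentation history \[m\], non-decreasing
#'   (approach only), `delta[1] = 0` expected.
#' @param t Uniform time grid \[s\], same length as `delta`.
#' @return Force history \[N\], same length as `delta`.
#' @examples
#' t <- seq(0, 0.16, length.out = 401)
#' d <- 5e-6 * t
#' p <- viscoelastic_params(E0 = 1000)
#' max(abs(hereditary_integral_force(p, 2.5e-6, d, t) -
#'         hertz_force(1000, 0.5, 2.5e-6, d)))
#' @export
hereditary_integral_force <- function(params, R, delta, t) {
  stopifnot(inherits(params, "viscoelastic_params"), R > 0,
            is.numeric(delta), is.numeric(t),
            length(delta) == length(t), length(t) >= 3L)
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1]))
    stop("time grid must be uniform", call. = FALSE)
  if (any(diff(delta) < -1e-15 * max(delta)))
    stop("decreasing indentation: retraction is not supported by the approach-only oracle",
         call. = FALSE)
  if (params$E1 > 0 && params$lam <= 0)
    stop("lam must be positive when E1 > 0", call. = FALSE)
  n <- length(t)
  h <- dt[1]
  C <- (4 / 3) * sqrt(R) / (1 - params$nu^2)

  g <- delta^1.5
  dg <- numeric(n)
  dg[2:(n - 1)] <- (g[3:n] - g[1:(n - 2)]) / (2 * h)
  dg[1] <- (g[2] - g[1]) / h
  dg[n] <- (g[n] - g[n - 1]) / h

  ddelta <- numeric(n)
  ddelta[2:(n - 1)] <- (delta[3:n] - delta[1:(n - 2)]) / (2 * h)
  ddelta[1] <- (delta[2] - delta[1]) / h
  ddelta[n] <- (delta[n] - delta[n - 1]) / h

  F <- numeric(n)
  for (i in 2:n) {
    j <- seq_len(i)
    kern <- params$E0 + if (params$E1 > 0)
      params$E1 * exp(-(t[i] - t[j]) / params$lam) else 0
    integrand <- kern * dg[j]
    F[i] <- h * (sum(integrand) - 0.5 * (integrand[1] + integrand[i]))
  }
  F <- F + params$eta * 1.5 * sqrt(delta) * ddelta
  C * F
}

#' Generate a batch of synthetic curves and a ground-truth manifest
#'
#' Writes `n` curves (TSV + JSON sidecar, the format [read_force_curve()]
#' consumes) into `dir`, one per-curve seed derived as `seed + i`, plus a
#' `manifest_<group>.csv` listing each file's true parameters — emulating a
#' per-condition acquisition batch.
#'
#' @param dir Output directory (created if needed).
#' @param n Number of curves.
#' @param spec Base [synthetic_curve_spec()]; each curve reuses it with its
#'   own seed.
#' @param group Condition label stored in each curve's metadata.
#' @param cells Optional number of cells the curves are split across
#'   (curve `i` belongs to cell `((i-1) %% cells) + 1`), emulating
#'   per-cell replicate triplets.
#' @param seed Base integer seed.
#' @return The manifest `data.frame`, invisibly.
#' @export
simulate_dataset <- function(dir, n, spec = synthetic_curve_spec(),
                             group = "sim", cells = NULL, seed = 1L) {
  stopifnot(n >= 1L, inherits(spec, "synthetic_curve_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec_i <- spec
    spec_i$seed <- as.integer(seed + i)
    curve <- generate_kvm_curve(spec_i)
    id <- sprintf("%s_%03d", group, i)
    curve$meta$curve_id <- id
    curve$meta$group <- group
    if (!is.null(cells))
      curve$meta$cell <- sprintf("%s_cell%02d", group, ((i - 1L) %% cells) + 1L)
    file <- file.path(dir, paste0(id, ".tsv"))
    write_force_curve(curve, file)
    rows[[i]] <- data.frame(
      file = basename(file), curve_id = id, group = group,
      cell = if (!is.null(cells)) curve$meta$cell else NA_character_,
      E0_Pa = spec$params$E0, E1_Pa = spec$params$E1,
      lambda_s = spec$params$lam, eta_Pa_s = spec$params$eta,
      cp_m = spec$cp_offset, seed = spec_i$seed,
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, paste0("manifest_", group, ".csv")),
                   row.names = FALSE)
  invisible(manifest)
}
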