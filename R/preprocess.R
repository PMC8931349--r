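#' Tip-sample separation
#'
#' Corrects the piezo height for the cantilever deflection: the probe apex
#' sits at `z - F/k` because a compressive force `F` bends the cantilever
#' back by `F/k`. With the package convention (`z` increasing into the
#' sample, compression positive) the separation also increases into the
#' sample; indentation is `separation - cp` once the contact point is known.
#'
#' @param curve A [force_curve()] whose metadata carries the spring
#'   constant `k` \[N/m\].
#' @return Numeric vector of separations \[m\], one per sample.
#' @export
tip_sample_separation <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  k <- curve$meta$k
  if (is.null(k) || !is.numeric(k) || k <= 0)
    stop("spring constant k [N/m] missing from curve metadata", call. = FALSE)
  curve$z - curve$F / k
}

#' Split a curve into approach and retract segments
#'
#' Uses per-sample segment labels when present; otherwise splits at the
#' extremum (maximum) of the piezo height, the turning point of a
#' triangular ramp. Only the approach segment is fitted.
#'
#' @param curve A [force_curve()].
#' @return A list with elements `approach` and `retract` (each a
#'   [force_curve()], or `NULL` for an empty retract).
#' @export
split_segments <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  if (length(unique(curve$segment)) > 1L) {
    app <- which(curve$segment == "approach")
    ret <- which(curve$segment == "retract")
  } else if (all(curve$segment == "retract")) {
    stop("curve has no approach segment", call. = FALSE)
  } else {
    i_turn <- which.max(curve$z)
    if (i_turn == length(curve$z)) {
      app <- seq_along(curve$z)
      ret <- integer(0)
    } else {
      dz <- diff(curve$z)
      if (any(dz[seq_len(i_turn - 1L)] <= 0) || any(dz[i_turn:length(dz)] >= 0))
        warning("piezo height not monotone within segments; splitting at the global extremum")
      app <- seq_len(i_turn)
      ret <- seq.int(i_turn + 1L, length(curve$z))
    }
  }
  list(
    approach = .subset_curve(curve, app),
    retract = if (length(ret) >= 16L) .subset_curve(curve, ret) else NULL
  )
}

## Linearized least squares for the indentation branch
## F_branch = d^3 / (a d^2 + b d + c): multiply through by the denominator,
## F*(a d^2 + b d + c) = d^3, linear in (a, b, c). Cheap enough to run at
## every candidate contact point; refined by true-SSE nlminb at the winner.
.branch_lin_fit <- function(dpos, y) {
  X <- cbind(y * dpos^2, y * dpos, y)
  cf <- tryCatch(qr.coef(qr(X), dpos^3), error = function(e) rep(NA_real_, 3))
  if (anyNA(cf)) return(NULL)
  list(a = cf[[1]], b = cf[[2]], c = cf[[3]])
}

.branch_pred <- function(dpos, a, b, c) {
  dpos^3 / (a * dpos^2 + b * dpos + c)
}

#' Estimate the contact point of an approach curve
#'
#' Scans candidate contact points over the sample separations in the
#' central 80% of the approach segment. For each candidate `cp` the force
#' is modelled piecewise in `delta = separation - cp`: a linear baseline
#' `F = m*delta + d` before contact and
#' `F = delta^3 / (a*delta^2 + b*delta + c) + m*delta + d` beyond. The
#' rational branch behaves like `delta^3/c` at small indentation and like
#' `(1/a + m)*delta` at large indentation. The candidate minimising the
#' total sum of squared residuals wins (ties broken towards the smallest
#' `cp`); the branch coefficients of the winner are refined by bounded
#' nonlinear least squares keeping the denominator positive.
#'
#' The returned `cp` is an initial estimate on the separation axis; the
#' KVM fit ([fit_kvm_curve()]) re-optimises it jointly with the material
#' parameters.
#'
#' @param approach A [force_curve()] holding only the approach segment.
#' @param min_side Minimum number of samples required on each side of a
#'   candidate (default 8).
#' @return A list of class `"contact_point_fit"`: `cp` \[m\], baseline
#'   slope `m` \[N/m\] and offset `d` \[N\], branch coefficients `a`, `b`,
#'   `c` (`c > 0`), residual sum of squares `sse` \[N^2\], the separation
#'   vector `sep` \[m\] and the scan step `step` \[m\].
#' @export
estimate_contact_point <- function(approach, min_side = 8L) {
  stopifnot(inherits(approach, "force_curve"))
  sep <- tip_sample_separation(approach)
  F <- approach$F
  n <- length(F)
  if (n < 4L * min_side)
    stop("approach segment too short for contact-point estimation",
         call. = FALSE)
  ord <- order(sep)
  sep_o <- sep[ord]
  F_o <- F[ord]

  ## no-contact guard: force rise above the early baseline must exceed the
  ## baseline noise by a clear margin
  i_base <- seq_len(floor(n / 3))
  bl <- stats::lm.fit(cbind(1, sep_o[i_base]), F_o[i_base])
  sd_b <- stats::sd(bl$residuals)
  pred_end <- bl$coefficients[[1]] + bl$coefficients[[2]] * sep_o
  rise <- max(F_o - pred_end)
  if (rise < max(10 * sd_b, 1e-4 * max(abs(F_o)), 1e-15))
    stop("no contact detected: force never rises above the baseline",
         call. = FALSE)

  lo <- max(ceiling(0.1 * n), min_side + 1L)
  hi <- min(floor(0.9 * n), n - min_side)
  best <- NULL
  for (i in lo:hi) {
    cp <- sep_o[i]
    d_all <- sep_o - cp
    neg <- d_all < 0
    pos <- d_all > 0
    if (sum(neg) < min_side || sum(pos) < min_side) next
    ## baseline from the pre-contact region (profiled)
    Xb <- cbind(1, d_all[neg])
    cf <- stats::lm.fit(Xb, F_o[neg])$coefficients
    d0 <- cf[[1]]; m0 <- cf[[2]]
    y <- F_o[pos] - (m0 * d_all[pos] + d0)
    br <- .branch_lin_fit(d_all[pos], y)
    if (is.null(br) || br$c <= 0) next
    den <- br$a * d_all[pos]^2 + br$b * d_all[pos] + br$c
    if (any(den <= 0)) next
    res_neg <- F_o[neg] - (m0 * d_all[neg] + d0)
    res_pos <- y - .branch_pred(d_all[pos], br$a, br$b, br$c)
    sse <- sum(res_neg^2) + sum(res_pos^2)
    if (is.null(best) || sse < best$sse - 1e-30 ||
        (abs(sse - best$sse) <= 1e-30 && cp < best$cp)) {
      best <- list(cp = cp, m = m0, d = d0, a = br$a, b = br$b, c = br$c,
                   sse = sse)
    }
  }
  if (is.null(best))
    stop("no contact detected: no valid contact-point candidate", call. = FALSE)

  ## refine branch coefficients at the winning candidate on the true SSE
  d_all <- sep_o - best$cp
  pos <- d_all > 0
  y <- F_o[pos] - (best$m * d_all[pos] + best$d)
  dpos <- d_all[pos]
  obj <- function(th) {
    den <- th[1] * dpos^2 + th[2] * dpos + th[3]
    if (any(den <= 0)) return(1e30)
    sum((y - dpos^3 / den)^2)
  }
  opt <- stats::nlminb(c(best$a, best$b, best$c), obj,
                       lower = c(-Inf, -Inf, .Machine$double.xmin))
  if (opt$objective < obj(c(best$a, best$b, best$c))) {
    best$a <- opt$par[1]; best$b <- opt$par[2]; best$c <- opt$par[3]
    neg <- d_all < 0
    res_neg <- F_o[neg] - (best$m * d_all[neg] + best$d)
    best$sse <- sum(res_neg^2) + obj(opt$par)
  }
  best$sep <- sep
  best$step <- stats::median(diff(sep_o))
  class(best) <- "contact_point_fit"
  best
}

#' @export
print.contact_point_fit <- function(x, ...) {
  cat(sprintf("contact point: cp = %.4g um, baseline m = %.3g N/m, d = %.3g nN, sse = %.3g N^2\n",
              x$cp * 1e6, x$m, x$d * 1e9, x$sse))
  invisible(x)
}

#' Subtract the fitted linear baseline from a curve
#'
#' Removes `m*(separation - cp) + d` from the force channel so the
#' pre-contact force is zero-mean. Idempotent: re-estimating the baseline
#' on the corrected curve yields slope and offset at noise level.
#'
#' @param curve A [force_curve()].
#' @param cpfit A `"contact_point_fit"` from [estimate_contact_point()]
#'   (estimated from `curve` if missing).
#' @return The baseline-corrected [force_curve()].
#' @export
remove_baseline <- function(curve, cpfit = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(cpfit)) cpfit <- estimate_contact_point(curve)
  sep <- tip_sample_separation(curve)
  Fc <- curve$F - (cpfit$m * (sep - cpfit$cp) + cpfit$d)
  force_curve(curve$t, curve$z, Fc, segment = curve$segment,
              meta = curve$meta)
}
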