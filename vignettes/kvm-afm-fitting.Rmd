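---
title: "Viscoelastic KVM analysis of AFM force-indentation curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viscoelastic KVM analysis of AFM force-indentation curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmkvm)
```

## The model

An AFM force-indentation experiment lowers a cantilever-mounted spherical
bead onto a soft sample at constant piezo velocity $v$ and records force
$F$ against indentation $\delta$. The classical analysis fits the Hertz
contact law

$$F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$

optionally with the hyperelastic large-indentation correction factor
$(1 - 0.15\,\delta/R)$, and reports a single apparent Young's modulus.
Cells and physically crosslinked gels, however, are viscoelastic: the
force they oppose depends on how fast they are probed.

`afmkvm` models the sample as a **Kelvin-Voigt-Maxwell (KVM)** solid: a
Kelvin-Voigt pair (spring $E_0$ in parallel with dashpot $\eta$) in
parallel with a Maxwell arm (spring $E_1$ in series with a dashpot of
viscosity $\lambda E_1$, so $\lambda$ is the arm's stress-relaxation
time). For a constant-velocity spherical indentation the contact force has
the explicit closed form

$$F(\delta) \;=\; F_{el}(E_0,\delta)
   \;+\; F_{el}(E_1,\delta)\,
         e^{-\alpha_1\,\delta/(v\lambda)}
   \;+\; \alpha_2\,\delta^{\alpha_3} R^{\alpha_4}\,\eta\,v ,$$

where $F_{el}(E,\delta)$ is the corrected Hertz force above and elapsed
contact time is $\delta/v$. The four calibration constants, fixed by
matching against continuum contact simulations over a wide parameter
range, are $\alpha_1 = 0.365$, $\alpha_2 = 7.25$,
$\alpha_3 = \alpha_4 = 1/2$. With the half-power exponents the viscous
term is $\alpha_2\sqrt{R\delta}\,\eta v$ — dimensionally a force, and of
the same functional form as the Kelvin-Voigt drag term of the Lee-Radok
solution (the calibrated prefactor is a numerical observation, not derived
from that solution).

Because $E_1$ and $\lambda$ trade off whenever the relaxation time is far
from the indentation time $t_{ind} = \delta_{max}/v$, two derived moduli
are the robust summary of the elastic content:

* the **unrelaxed modulus** $E_u = E_0 + E_1$, and
* the **apparent modulus**
  $E_{app} = E_0 + E_1 e^{-\alpha_1 \delta_{max}/(v\lambda)}$,
  the elasticity experienced over the measurement timescale.

## Parameters and defaults

| parameter | meaning | unit | default / bounds |
|---|---|---|---|
| $E_0$ | Kelvin-Voigt modulus | Pa | $\ge 0$ |
| $E_1$ | Maxwell modulus | Pa | $\ge 0$ |
| $\lambda$ | Maxwell relaxation time | s | box $[t_{ind}/5,\,10\,t_{ind}]$ |
| $\eta$ | apparent viscosity | Pa s | $\ge 0$ |
| $\nu$ | Poisson ratio | — | fixed, 0.5 |
| $R$ | bead radius | m | from metadata |
| $k$ | spring constant | N/m | from metadata |

The $\lambda$ box is not cosmetic. At $\lambda = 10\,t_{ind}$ the Maxwell
arm still carries $e^{-1/10} \approx 0.9$ of $E_1$ after a full
indentation — the material is indistinguishable from a purely elastic one
with modulus $E_0 + E_1$. At $\lambda = t_{ind}/5$ only
$e^{-5} \approx 0.006$ of $E_1$ survives — the material looks like a plain
Kelvin-Voigt solid and $E_1$ is arbitrary. Outside the box only $E_u$
(upper side) or $E_{app} = E_0$ (lower side) are physically recoverable,
and `fit_kvm_curve()` flags such fits (`lam_at_upper_bound`,
`lam_at_lower_bound`, `E1_at_zero`).

## The pipeline

1. **Tip-sample separation** (`tip_sample_separation`): the probe apex
   sits at $z - F/k$; indentation is measured from the contact point on
   this corrected axis.
2. **Segment split** (`split_segments`): by per-sample labels, else at
   the piezo extremum. Only the approach is fitted — retraction carries
   adhesion artifacts the model does not describe.
3. **Contact point** (`estimate_contact_point`): for every candidate on
   the sample grid in the central 80% of the approach, the force is fitted
   piecewise — a line $m\delta + d$ before contact, the rational branch
   $\delta^3/(a\delta^2 + b\delta + c) + m\delta + d$ beyond — and the
   candidate with the least total squared residual wins (ties to the
   smallest). The baseline pair $(m, d)$ is profiled from the pre-contact
   region alone, which keeps its recovery exact on clean data; the branch
   coefficients come from a linearised solve per candidate and a bounded
   (`c > 0`, positive denominator) refinement at the winner.
4. **KVM fit** (`fit_kvm_curve`): plain (unweighted) least squares over
   the full approach — zero force before the contact point, the explicit
   relation beyond. The three amplitudes $(E_0, E_1, \eta)$ enter the
   model linearly, so they are profiled out by exact non-negative least
   squares at every step (active-set over the $2^3$ sign patterns) and the
   Nelder-Mead simplex searches only $(\lambda, cp)$ — a variable
   projection scheme. Samples above the force setpoint (instrument
   overshoot) are trimmed first.

### Numerical choices

* **Why profile the amplitudes?** A five-parameter simplex stalls on the
  $E_0$/$E_1$ compensation ridge: at large $\lambda/t_{ind}$ the two
  elastic bases are nearly collinear and the simplex collapses long before
  it reaches the ridge floor. With the amplitudes solved exactly, the
  remaining two-dimensional landscape is clean; noiseless curves are
  recovered to machine precision. When a $\lambda$-box edge fits at least
  as well as the interior optimum the edge is adopted, which is what makes
  the bound flags deterministic on saturated curves.
* **Contact-point refit window.** The line+polynomial estimate is
  systematically *early* on viscous materials — their force onset rises
  like $\sqrt{\delta}$, which the cubic-over-quadratic branch (zero slope
  at onset) can only follow by placing the contact sooner. The offset is
  tens of nanometres, set by the physics rather than the sampling step, so
  the refit window is `max(20 scan steps, 15% of the initial maximum
  indentation)`. A window tied to the grid alone starves the refit at
  multi-kHz sampling.
* **Degenerate inputs.** Curves whose force never rises above the
  baseline noise raise a *no contact* error rather than returning junk;
  corrupt files in a batch are logged and counted by `cmd_fit`, never
  silently dropped. Candidate contact points whose branch denominator is
  not positive over the data are discarded.
* **Determinism.** The fit uses no random numbers (deterministic restart
  points); all stochasticity in the package flows through generator seeds.

### Geometric corrections

For a rounded (mitotic-like) cell of radius $R_{cell}$, contact is
sphere-on-sphere: the effective radius $1/R_{eff} = 1/R_{cell} + 1/R$
replaces the bead radius, and the measured indentation is rescaled by the
confinement factor
$K = R_{cell}^{1/3}/(R_{cell}^{1/3} + R_{eff}^{1/3})$ before fitting,
accounting for the additional deformation of the cell against the rigid
dish. For the standard geometry ($R_{cell} = 7.5\,\mu m$,
$R = 2.5\,\mu m$): $R_{eff} = 1.875\,\mu m$, $K = 0.613$.

### Bottom effect

A thin sample on glass resists indentation more than a half-space, so
half-space fits over-estimate the force. With the simplified relaxation
function $\varphi = E_{app} + \eta\,\delta_D(t)$, the first two terms of
the thin-layer series for a sphere are

$$F_0 = \tfrac{16}{9}\sqrt{RI}\left[\tfrac92\eta v + E_{app} I\right],
\qquad
F_1 = 1.133\,\tfrac{16}{9}\,\tfrac{RI}{h}\left[6\eta v + E_{app} I\right],$$

and `bottom_effect_estimate()` reports the over-estimation $F_1/F_0$
(terms of order $I^{3/2}/h^2$ are truncated). This is a *diagnostic*: the
fitted model itself deliberately neglects the substrate, as the derivation
of the explicit relation assumes a half-space.

## The synthetic generator and the independent oracle

`generate_kvm_curve()` emulates what the instrument records: a constant-
velocity piezo ramp, a linear baseline (slope and offset) before contact,
the explicit KVM force beyond it, and i.i.d. Gaussian force noise under a
fixed seed. The per-sample implicit equation
$F = \text{baseline} + F_{KVM}(z - F/k - cp)$ is solved by fixed-point
iteration, so the cantilever-deflection coupling between force and
separation is reproduced, and the exact ground truth (parameters, contact
point, noiseless separation) travels in the curve metadata. Defaults
emulate a live-cell measurement: 2.5 µm bead, 0.05 N/m cantilever, 5 µm/s,
0.8 µm indentation, 5 kHz sampling.

What the generator does **not** emulate: pre-contact hydrodynamic force
onset and negative detachment forces (diffuse-interface effects seen in
full continuum simulations), adhesion, instrument drift other than a
linear baseline, and retraction mechanics (an optional mirrored retract
ramp carries baseline force only, for segment-splitting tests). Passing
the recovery suite therefore demonstrates correctness of the estimator
under the stated noise model, not robustness to every instrumental
artifact.

`hereditary_integral_force()` is the independent check on the model
itself: it evaluates the Lee-Radok-type hereditary integral
$$F(t) = \frac{4\sqrt{R}}{3(1-\nu^2)}\int_0^t
 \left(E_0 + E_1 e^{-(t-\tau)/\lambda}\right)
 \frac{d}{d\tau}\,\delta^{3/2}(\tau)\, d\tau
 \;+\; \frac{4\sqrt{R}}{3(1-\nu^2)}\,\eta\,\tfrac32\sqrt{\delta}\,\dot\delta$$
by trapezoidal quadrature (the Dirac term of the relaxation function in
closed form). It shares no code or constants with `kvm_force()`: it uses
the plain Hertz kernel and real elapsed time. Halving the time step on the
standard ramp changes the result by under 0.1%; with a constant kernel it
reproduces the Hertz force, and its slow/fast relaxation limits bracket
the explicit relation's $E_{app}$ limits.

## The recovery study and what is identifiable

The acceptance suite fits 100 seeded synthetic curves at the default
acquisition settings, material $E_0 = 1$ kPa, $E_1 = 0.8$ kPa,
$\eta = 2$ Pa s (HeLa-like), $\lambda$ spread evenly over
$[t_{ind}/2,\, 2\,t_{ind}]$, and per-sample force noise of 1% of each
curve's peak force. Under these conditions the derived moduli are robust —
median relative errors on $E_u$ and $E_{app}$ are a few percent — while
the individual parameters $E_0$, $E_1$, $\lambda$, $\eta$ are **not**
reliably recovered once $\lambda$ approaches $2\,t_{ind}$: the Maxwell
term becomes nearly collinear with the elastic one, and materially
different parameter combinations fit a noisy curve equally well (the
suite's median errors on $E_0$ and $\eta$ sit well above 10%). This is a
property of the data, not of the optimizer — profiling the likelihood
shows equally good fits with wildly different splits — and it is exactly
why the unrelaxed and apparent moduli are the recommended reporting
quantities. Individual-parameter interpretation is safest when
$\lambda \lesssim t_{ind}/2$ and the viscous term is well above the noise
floor (slow relaxation relative to the probe, or faster probing).

## Statistics

Batch studies acquire about three curves per cell; `aggregate_per_cell()`
takes per-cell medians so that cells, not curves, are the statistical
unit. `compare_groups()` runs a Kruskal-Wallis rank test across groups
with pairwise post-hoc Welch t-tests, labelled `***` at $p < 0.001$ and
`n.s.` at $p > 0.05$. The pairwise tests are uncorrected by default (a
`p_adjust = "holm"` switch is available); all-tied degenerate input
reports $H = 0$, $p = 1$.

## Known limitations

* Spherical probes only; no conical/pyramidal geometry, no JKR/DMT
  adhesion, no power-law rheology.
* The approach segment only; retraction (Ting-type) analysis is out of
  scope.
* The bottom effect is estimated, not folded into the fitted model.
* $E_1$ and $\lambda$ individually are meaningful only when
  $\lambda/t_{ind}$ is of order one or less; report $E_u$ and $E_{app}$
  otherwise.
* The constant-velocity assumption enters through $t = \delta/v$; strongly
  non-triangular drive waveforms are not supported.
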