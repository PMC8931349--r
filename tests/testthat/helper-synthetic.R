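# shared fixtures: cheap synthetic curves for unit tests (the acceptance
# recovery suite uses the generator defaults instead)

cheap_spec <- function(params = viscoelastic_params(1000, 800, 0.08, 2),
                       rate = 1000, noise_sd = 0, seed = 1, ...) {
  synthetic_curve_spec(params = params, rate = rate, noise_sd = noise_sd,
                       seed = seed, ...)
}

# noise level used throughout: 1% of the curve's peak force
noise_1pct <- function(spec) {
  spec$noise_sd <- 0
  0.01 * max(generate_kvm_curve(spec)$F)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
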