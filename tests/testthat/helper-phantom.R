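# Shared pipeline fixtures. The condyle model is cached inside the package
# by seed, so repeated calls across test files cost nothing.

sk_cfg <- run_config()

sk_model <- function() default_condyle_model(params = sk_cfg)

sk_pair <- function(shift = 10, noise = 0, seed = 7, ...) {
  render_phantom_pair(phantom_spec(tibial_translation_mm = shift,
                                   noise_sd = noise, seed = seed, ...))
}
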