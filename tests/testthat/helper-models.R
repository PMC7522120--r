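## Shared small fixtures for the test suite.

## one-component model with fast, well-conditioned kinetics for cheap tests
simple_model <- function(sites = 2e5) {
  binding_model(list(binding_component(3e5, 2e-3, sites)))
}

## near-zero-affinity model: free diffusion limit for the penetration PDE
inert_model <- function() {
  binding_model(list(binding_component(1e-10, 1e-3, 1)))
}
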