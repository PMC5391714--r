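# Random but reproducible gene-flow scenarios for property-style tests.

random_models <- function(n, seed = 20160101) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    pmgf(pollen_diameter  = runif(1, 15, 200),
         release_height   = runif(1, 0.2, 5),
         outcrossing_rate = runif(1, 0.1, 60),
         crossability     = runif(1, 30, 100),
         wind_speed       = runif(1, 0.5, 10))
  })
}

# grid of (mean, shape) pairs covering mu in [0.1, 1e4] and shape over at
# least six orders of magnitude
wald_param_grid <- function() {
  expand.grid(mean  = c(0.1, 1, 10, 1e2, 1e4),
              shape = c(1e-3, 1e-1, 1, 1e1, 1e3))
}
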