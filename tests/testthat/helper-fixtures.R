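# Shared fixture builders for the test suite.

# Noise-free Gaussian peak on a regular grid, as a depth_curve.
gauss_curve <- function(center, sigma = 2, step = 0.1, half_span = 20,
                        baseline = 0) {
  d <- seq(center - half_span, center + half_span, by = step)
  depth_curve(d, baseline + exp(-(d - center)^2 / (2 * sigma^2)))
}

# Random layer stack for property tests.
random_stack <- function(n, materials = c("PMMA", "graphite", "lacquer", "water")) {
  lapply(seq_len(n), function(i) {
    material_layer(sample(materials, 1), stats::runif(1, 0, 5))
  })
}

# The ten published barrier-table columns in a fixed order.
table3_fixture <- function() barrier_reference_table()
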