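# mode shorthands used across the suite
params_published <- conversion_params()
params_derivation <- conversion_params(numerator_mode = "derivation_consistent")
params_exact_piecewise <- conversion_params(
  numerator_mode = "derivation_consistent",
  moisture_model = "piecewise_fiber_saturation")

# literal closed-form conversion as commonly printed, written out
# independently of the package internals (test-side oracle)
eq1_literal <- function(Dw, w, numerator = 29466) {
  numerator * Dw / (30000 + 7950 * Dw + 300 * w - 265 * Dw * w)
}

# random per-species summaries for aggregation tests
random_summaries <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    species = sprintf("sp%03d", seq_len(n)),
    n_samples = sample(1:10, n, replace = TRUE),
    median_density = stats::runif(n, 0.05, 0.95)
  ))
}
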