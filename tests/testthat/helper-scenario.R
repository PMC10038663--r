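# Scenario fixtures are generated once per test run and cached (generation
# plus a full pipeline run costs a few seconds each).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

zero_noise_scenario <- function() {
  cached("zero_noise", generate_scenario(
    scenario_config(noise_sd = 0, seed = 101), tempfile("scn0_")))
}

zero_noise_result <- function() {
  cached("zero_noise_result",
         suppressMessages(run_pipeline(zero_noise_scenario()$dir)))
}

# A small NanoString table with identical underlying lanes (no lane effects,
# no counting noise), used for the normalization properties.
flat_nanostring <- function() {
  cached("flat_nano", {
    sc <- generate_scenario(
      scenario_config(noise_sd = 0, lane_scale_range = c(1, 1), seed = 77,
                      n_genes = 6, n_decoy_genes = 0),
      tempfile("scnflat_"))
    sc$nanostring
  })
}
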