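# shared fixtures: the standard simulation is expensive enough to cache
# once per test session
.test_cache <- new.env(parent = emptyenv())

std_sim <- function() {
  if (is.null(.test_cache$sim)) .test_cache$sim <- simulate_aorta()
  .test_cache$sim
}

std_features <- function() {
  if (is.null(.test_cache$ft)) {
    .test_cache$ft <- extract_features(std_sim()$waveforms$aa)
  }
  .test_cache$ft
}

# matched-load simulation (reflection coefficient forced to zero)
matched_sim <- function() {
  if (is.null(.test_cache$matched)) {
    sim0 <- std_sim()
    load <- peripheral_load()
    # terminal resistance equal to Zc gives Gamma = 0 exactly
    load$terminal_resistance <- sim0$zc
    .test_cache$matched <- simulate_aorta(load = load)
  }
  .test_cache$matched
}
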