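# Lazily cached full-scale simulations shared by the acceptance tests
# (the same preset + seed is reused by several criteria).

.sim_cache <- new.env(parent = emptyenv())

cached_analysis <- function(preset, seed) {
  key <- paste(preset, seed, sep = "#")
  if (!exists(key, envir = .sim_cache)) {
    sim <- simulate_tracks(sim_preset(preset, seed = seed))
    metrics <- tracklet_metrics(decompose_tracklets(sim$tracks))
    assign(key, list(sim = sim, metrics = metrics), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}
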