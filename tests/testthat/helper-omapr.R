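# shared fixtures: everything is generated in code, sized for speed

# small mouse-like scenario for unit tests (same physics, smaller field)
small_scenario <- function(name = "mouse_control", shape = c(48, 48),
                           duration_ms = 650, pcl = 150, seed = 101L, ...) {
  scenario(name, pcl = pcl, shape = shape, duration_ms = duration_ms,
           seed = seed, ...)
}

# deterministic integer movie with a known per-sample formula
formula_recording <- function(h = 4L, w = 5L, nf = 6L, frame_rate = 500) {
  frames <- array(0L, c(h, w, nf))
  for (f in seq_len(nf)) {
    for (r in seq_len(h)) {
      frames[r, , f] <- 100L * (f - 1L) + 10L * (r - 1L) + (seq_len(w) - 1L)
    }
  }
  recording(frames, frame_rate = frame_rate, bits_per_sample = 10L)
}

# full-size acceptance runs are expensive; compute once per test session
acceptance_env <- new.env(parent = emptyenv())

acceptance_run <- function(key, fn) {
  if (!exists(key, envir = acceptance_env)) {
    assign(key, fn(), envir = acceptance_env)
    gc(FALSE)
  }
  get(key, envir = acceptance_env)
}

mouse_replicate_summary <- function(k) {
  acceptance_run(paste0("mouse_", k), function() {
    run <- run_pipeline(pipeline_config("mouse_control", seed = k))
    s <- run$summary
    rm(run)
    s
  })
}
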