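# Small in-code fixtures shared across test files.

# A compact generator configuration: fewer channels and a short session so
# preprocessing-level tests run in seconds.
tiny_generator <- function(seed = 1, n_channels = 8, ...) {
  generator_config(n_channels = n_channels,
                   mixing = default_mixing(n_channels, seed = seed),
                   seed = seed, ...)
}

tiny_session <- function(speed = "fast", n_trials = 1, seed = 1, rest_s = 1) {
  generate_session(speed, n_trials, rest_s = rest_s, seed = seed)
}

# One preprocessed dataset at reduced scale (shared across tests via lazy
# memoisation in the testthat environment).
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_generator(seed = 42)
      kin <- tiny_session("fast", n_trials = 2, seed = 42)
      raw <- emg_forward_model(kin, cfg)
      ds <- preprocess_recording(raw, filter_spec(cfg$fs_emg))
      ds$trial_table <- attr(kin, "trial_table")
      cache <<- ds
    }
    cache
  }
})
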