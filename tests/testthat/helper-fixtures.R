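# Shared simulated datasets, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# A single-variant let-7a run through the full detection/calling chain,
# reused by several acceptance blocks.
shared_run <- function() {
  if (is.null(.fixtures$run)) {
    trace <- simulate_mixture(let7_sequences()["let7a"], n_events = 2000, seed = 101)
    det <- detect_pipeline(trace)
    fit <- fit_conductance_model(det$segments)
    frags <- call_fragments(det$segments, fit)
    profiles <- lapply(frags, find_transition_points,
                       reference = let7_sequences()[["let7a"]])
    .fixtures$run <- list(trace = trace, det = det, fit = fit,
                          frags = frags, profiles = profiles)
  }
  .fixtures$run
}

# Ground-truth path-level fragments for a two-variant mixture: the letters
# actually dwelled on, without trace rendering or calling noise.
path_fragments <- function(fractions, n_events, seed,
                           variants = let7_sequences()[c("let7a", "let7f")],
                           tmodel = translocation_model()) {
  tunnelcall:::with_local_seed(seed, {
    labs <- sample(names(variants), n_events, replace = TRUE, prob = fractions)
    lapply(labs, function(v) {
      p <- tunnelcall:::sim_path_impl(variants[[v]], tmodel, sequence_id = v)
      lets <- tunnelcall:::path_letters(p)
      tunnelcall:::new_fragment(lets, (seq_along(lets) - 0.5) / 1.5,
                                rep(NA_real_, length(lets)),
                                rep(1, length(lets)))
    })
  })
}
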