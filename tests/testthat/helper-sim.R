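# Shared fixtures: small, seed-fixed simulations memoized per test run so
# several test files can reuse them without regenerating.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- maker()
  .fixture_env[[name]]
}

small_sim <- function() fixture("small_sim", function() {
  simulate_recording(sim_config(n_channels = 4, fs = 512, duration = 600,
                                seed = 3))
})

# deterministic sinusoid helper
tone <- function(freq, dur_s, fs, amp = 1, phase = 0)
  amp * sin(2 * pi * freq * (0:(dur_s * fs - 1)) / fs + phase)
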