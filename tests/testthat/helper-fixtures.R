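# Shared fixtures, built in code and cached for the duration of a test run.

.fixture_env <- new.env(parent = emptyenv())

with_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# A small four-choice session with a clear ERP (80 events).
small_session <- function() {
  with_fixture("small_session", function() {
    generate_session(session_spec("four_choice", n_repetitions = 2,
                                  n_selections = 10, snr = 2,
                                  artifact_rate = 0, seed = 42))
  })
}

# Symbolized trials + labels from the small session.
small_symbols <- function() {
  with_fixture("small_symbols", function() {
    ses <- small_session()
    preprocess_pipeline(ses$recording, ses$schedule)
  })
}

# A single-channel recording holding an arbitrary vector.
vec_recording <- function(x, fs = 240) {
  eeg_recording(matrix(x, nrow = 1), fs)
}

# Random symbolized trial set of given size (valid symbols 0..8).
random_symbols <- function(n, L_s = 54, C = 6, seed = 1) {
  with_seed(seed, {
    arr <- array(sample(0:8, n * L_s * C, replace = TRUE),
                 dim = c(n, L_s, C))
    structure(arr, class = "symbolized_trial_set")
  })
}

with_seed <- p300lbp:::with_seed
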