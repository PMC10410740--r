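# Miniature configurations for fast, hand-checkable tests.

make_config <- function(defaults, overrides) {
  args <- utils::modifyList(defaults, overrides)
  do.call(sim_config, args)
}

tiny_config <- function(...) {
  make_config(list(n_thal = 5, n_ctx = 8, n_dspn = 4, n_ispn = 4, d = 2,
                   n_trials = 2, seed = 1, n_record_trials = 1), list(...))
}

# A small but non-trivial config for behavioural tests (a few seconds).
small_config <- function(...) {
  make_config(list(n_thal = 15, n_ctx = 30, n_dspn = 20, n_ispn = 20,
                   n_trials = 50, seed = 1), list(...))
}
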