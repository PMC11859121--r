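# Shared helpers for the test suite.

# population-level mean of a per-group outcome column, weighted by group size
popmean <- function(summary_rows, col) {
  sum(summary_rows[[col]] * summary_rows$group_size) /
    sum(summary_rows$group_size)
}

# population-level final value of `col` for each run in a replicate list
final_popmeans <- function(reps, col) {
  vapply(reps, function(r) popmean(r$final, col), numeric(1))
}

# small fast parameter set for structural tests
tiny_params <- function(...) {
  defaults <- list(N = 40, generations = 10, sigma = 0.3, n_targets = 3,
                   seed = 42L)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(model_params, defaults)
}
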