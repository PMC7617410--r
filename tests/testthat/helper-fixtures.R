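# Hand-built stimulus with a prescribed per-frame signed difference, for
# deterministic checks.  Counts are split around a halfway of 1000.
fixed_stimulus <- function(diffs, condition = "free_response",
                           halfway = 1000, frame_duration = 0.05,
                           correct_side = 1) {
  structure(list(condition = condition, correct_side = correct_side,
                 frames_left = as.integer(round(halfway + diffs / 2)),
                 frames_right = as.integer(round(halfway - diffs / 2)),
                 halfway_point = halfway,
                 mean_left = halfway + 45, mean_right = halfway - 45,
                 planned_duration = if (condition == "interrogation")
                   length(diffs) * frame_duration,
                 frame_duration = frame_duration),
            class = "ddm_stimulus")
}

# small block structure for fast dataset tests
small_config <- function(n_blocks = 4, trials_per_block = 8)
  task_config(n_blocks = n_blocks, trials_per_block = trials_per_block)

# desk-scale fitting profile for structural tests (not recovery quality)
tiny_fit_config <- function()
  fit_config("fast", n_random_starts = 8, n_repeats = 1, iter_max = 25)

params_for <- function(name, d = c(60, 110, 170)) {
  default_params(model_spec(name), d = d)
}
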