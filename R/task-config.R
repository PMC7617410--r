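#' Task configuration
#'
#' Generative design of the two-array dot-comparison task: every 50 ms the
#' number of dots in each array is resampled from a truncated normal whose
#' means are separated by `mean_separation` dots, around a per-trial halfway
#' point.  Free-response blocks alternate with interrogation blocks in pairs;
#' interrogation stimulus durations are drawn from a truncated normal matched
#' to the response times of the most recent free-response block.
#'
#' @param frame_duration Frame length in seconds.
#' @param mean_separation Mean dot-count difference between the two arrays
#'   per frame (the signal), dots.
#' @param array_sd Per-array, per-frame dot-count SD before truncation, dots.
#' @param halfway_mean,halfway_sd,halfway_bounds Distribution of the
#'   per-trial halfway point between the two array means, dots.
#' @param dot_count_bounds Admissible range of a displayed dot count
#'   (half-open: counts are integers in `(lower, upper]`).
#' @param interrogation_duration_mean,interrogation_duration_sd Fallback
#'   moments (seconds) for interrogation stimulus durations when no
#'   free-response block has yet been observed.
#' @param interrogation_duration_bounds Truncation bounds for interrogation
#'   durations, seconds.
#' @param trials_per_block,n_blocks Block structure of a session.
#' @param cue_response_delay_mean,cue_response_delay_sd Simulated motor delay
#'   (seconds) between the response cue and the response on interrogation
#'   trials; truncated to `[0.1, 1]` (responses must land within the 1 s
#'   response window).
#' @return An object of class `ddm_task_config`.
#' @export
task_config <- function(frame_duration = 0.05,
                        mean_separation = 90,
                        array_sd = 220,
                        halfway_mean = 1000,
                        halfway_sd = 100,
                        halfway_bounds = c(500, 1500),
                        dot_count_bounds = c(0, 3096),
                        interrogation_duration_mean = 0.75,
                        interrogation_duration_sd = 0.40,
                        interrogation_duration_bounds = c(0.2, 4.0),
                        trials_per_block = 40,
                        n_blocks = 16,
                        cue_response_delay_mean = 0.35,
                        cue_response_delay_sd = 0.10) {
  cfg <- list(frame_duration = frame_duration,
              mean_separation = mean_separation,
              array_sd = array_sd,
              halfway_mean = halfway_mean,
              halfway_sd = halfway_sd,
              halfway_bounds = halfway_bounds,
              dot_count_bounds = dot_count_bounds,
              interrogation_duration_mean = interrogation_duration_mean,
              interrogation_duration_sd = interrogation_duration_sd,
              interrogation_duration_bounds = interrogation_duration_bounds,
              trials_per_block = trials_per_block,
              n_blocks = n_blocks,
              cue_response_delay_mean = cue_response_delay_mean,
              cue_response_delay_sd = cue_response_delay_sd)
  validate_task_config(cfg)
  structure(cfg, class = "ddm_task_config")
}

validate_task_config <- function(cfg) {
  with(cfg, {
    if (frame_duration <= 0) stop("frame_duration must be > 0")
    if (mean_separation <= 0) stop("mean_separation must be > 0")
    if (array_sd < 0) stop("array_sd must be >= 0")
    if (diff(halfway_bounds) <= 0 || diff(dot_count_bounds) <= 0 ||
        diff(interrogation_duration_bounds) <= 0)
      stop("bounds intervals must be nonempty")
    if (halfway_bounds[1] <= dot_count_bounds[1] ||
        halfway_bounds[2] > dot_count_bounds[2])
      stop("halfway_bounds must lie within the dot-count range")
    if (any(interrogation_duration_bounds <= 0))
      stop("durations must be positive")
    if (trials_per_block < 2 || trials_per_block %% 2 != 0)
      stop("trials_per_block must be even (equal left/right counts)")
    if (n_blocks < 2 || n_blocks %% 2 != 0)
      stop("n_blocks must be even (free/interrogation pairs)")
  })
  invisible(cfg)
}

#' Stimulus statistics entering the calibrated Bayesian readout
#'
#' Summaries of the task's evidence stream, as represented by an observer who
#' treats the within-frame-constant stimulus noise as white: the expected
#' signed evidence rate for the correct option (`mean_rate`, dots) and the
#' white-noise-equivalent stimulus variance per second
#' (`stim_var = 2 * array_sd^2 * frame_duration`).
#'
#' @param config A [task_config()].
#' @return An object of class `ddm_task_stats` with fields `mean_rate`,
#'   `stim_var` and `frame_duration`.
#' @export
task_stats <- function(config = task_config()) {
  structure(list(mean_rate = config$mean_separation,
                 stim_var = 2 * config$array_sd^2 * config$frame_duration,
                 frame_duration = config$frame_duration),
            class = "ddm_task_stats")
}
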