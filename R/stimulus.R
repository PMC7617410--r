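# truncated-normal integer dot counts: sample, round to nearest integer,
# rejection-resample anything outside (lower, upper]
sample_dot_counts <- function(n, mean, sd, bounds) {
  x <- round(rnorm(n, mean, sd))
  bad <- which(x <= bounds[1] | x > bounds[2])
  while (length(bad)) {
    x[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[x[bad] <= bounds[1] | x[bad] > bounds[2]]
  }
  x
}

# scalar truncated-normal draw by rejection (continuous)
rtrunc_norm1 <- function(mean, sd, bounds) {
  if (sd <= 0) return(min(max(mean, bounds[1]), bounds[2]))
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= bounds[1] && x <= bounds[2]) return(x)
  }
}

#' Sample a stimulus for one trial
#'
#' Draws the per-trial halfway point, then per 50 ms frame the integer dot
#' counts of the two arrays from truncated normals centred `mean_separation/2`
#' above (correct side) and below (incorrect side) the halfway point.
#'
#' @param config A [task_config()].
#' @param condition `"free_response"` or `"interrogation"`.
#' @param correct_side `+1` (left) or `-1` (right).
#' @param max_duration Stimulus duration to cover, seconds; the returned
#'   frame sequences span at least this long.  For interrogation trials this
#'   is the planned stimulus duration.
#' @return An object of class `ddm_stimulus` with integer vectors
#'   `frames_left` and `frames_right`, the `halfway_point`, the generating
#'   array means, and metadata.
#' @export
sample_stimulus <- function(config, condition = c("free_response", "interrogation"),
                            correct_side = 1, max_duration = 1) {
  condition <- match.arg(condition)
  if (!correct_side %in% c(-1, 1)) stop("correct_side must be +1 or -1")
  if (max_duration < config$frame_duration)
    stop("max_duration must cover at least one frame")
  n_frames <- ceiling(max_duration / config$frame_duration - 1e-9)
  halfway <- rtrunc_norm1(config$halfway_mean, config$halfway_sd,
                          config$halfway_bounds)
  mean_left <- halfway + correct_side * config$mean_separation / 2
  mean_right <- halfway - correct_side * config$mean_separation / 2
  structure(list(condition = condition,
                 correct_side = correct_side,
                 frames_left = sample_dot_counts(n_frames, mean_left,
                                                 config$array_sd,
                                                 config$dot_count_bounds),
                 frames_right = sample_dot_counts(n_frames, mean_right,
                                                  config$array_sd,
                                                  config$dot_count_bounds),
                 halfway_point = halfway,
                 mean_left = mean_left, mean_right = mean_right,
                 planned_duration = if (condition == "interrogation") max_duration,
                 frame_duration = config$frame_duration),
            class = "ddm_stimulus")
}

#' Signed evidence stream of a stimulus
#'
#' Per-frame dot difference `left - right` (dots), the model's evidence
#' input; positive values favour "left" (+1).
#'
#' @param stimulus A `ddm_stimulus`.
#' @return Numeric vector, one element per frame.
#' @export
stimulus_evidence <- function(stimulus) {
  as.numeric(stimulus$frames_left - stimulus$frames_right)
}

#' Sample an interrogation stimulus duration
#'
#' Drawn from a normal with mean and SD matched to the response times of the
#' most recent free-response block (the config's fallback moments when none
#' is available), truncated to the configured bounds and rounded down to a
#' whole number of frames.
#'
#' @param reference_rts Response times (seconds) of the most recent
#'   free-response block; may be empty.
#' @param config A [task_config()].
#' @return Duration in seconds (a whole number of frames).
#' @export
sample_interrogation_duration <- function(reference_rts, config) {
  if (length(reference_rts) >= 2) {
    m <- mean(reference_rts); s <- sd(reference_rts)
  } else {
    m <- config$interrogation_duration_mean
    s <- config$interrogation_duration_sd
  }
  x <- rtrunc_norm1(m, s, config$interrogation_duration_bounds)
  d <- floor(x / config$frame_duration) * config$frame_duration
  max(d, config$interrogation_duration_bounds[1])
}
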