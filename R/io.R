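#' Write a dataset as linked plain-text tables
#'
#' Writes `trials.tsv` (one row per trial), `frames.tsv` (one row per frame)
#' and `metadata.json` (config, variant, seeds, and true parameters when
#' simulated) into a directory.
#'
#' @param dataset A `ddm_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(dataset$trials, file.path(dir, "trials.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$frames, file.path(dir, "frames.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(spec = dataset$spec$name,
               seed = dataset$seed,
               config = unclass(dataset$config),
               participants = lapply(dataset$participants, function(p)
                 list(seed = p$seed, spec = p$spec$name,
                      params = as.list(params_to_vector(p$params)))))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' Validates the schema: required columns, and agreement between the trials
#' table's `n_frames` and the frame counts actually present in the frames
#' table.
#'
#' @param dir Directory containing `trials.tsv`, `frames.tsv`,
#'   `metadata.json`.
#' @return A `ddm_dataset`.
#' @export
read_dataset <- function(dir) {
  trials <- utils::read.delim(file.path(dir, "trials.tsv"))
  frames <- utils::read.delim(file.path(dir, "frames.tsv"))
  need_t <- c("participant", "trial", "condition", "correct_side",
              "response", "rt", "stimulus_duration", "n_frames",
              "confidence_bin")
  need_f <- c("participant", "trial", "frame", "dots_left", "dots_right")
  miss <- setdiff(need_t, names(trials))
  if (length(miss)) stop("trials table is missing columns: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(need_f, names(frames))
  if (length(miss)) stop("frames table is missing columns: ",
                         paste(miss, collapse = ", "))
  cnt <- aggregate(frame ~ participant + trial, frames, length)
  key <- paste(trials$participant, trials$trial)
  got <- cnt$frame[match(key, paste(cnt$participant, cnt$trial))]
  if (any(is.na(got)) || any(got != trials$n_frames))
    stop("per-trial frame counts disagree between the trials and frames tables")
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  spec <- model_spec(meta$spec)
  cfg <- do.call(task_config, meta$config[names(meta$config) %in%
                                            names(formals(task_config))])
  participants <- NULL
  if (!is.null(meta$participants) && length(meta$participants))
    participants <- lapply(seq_along(meta$participants), function(i) {
      m <- meta$participants[[i]]
      sp <- model_spec(m$spec)
      list(seed = m$seed, spec = sp,
           params = params_from_vector(unlist(m$params), sp))
    })
  structure(list(trials = trials, frames = frames,
                 participants = participants, config = cfg, spec = spec,
                 seed = meta$seed),
            class = "ddm_dataset")
}

#' Run configuration: serialization round trip
#'
#' A run configuration bundles the task config, model variant(s), fitting
#' profile, master seed and output directory; it round-trips losslessly
#' through JSON so that every output is reproducible from its recorded
#' configuration.
#'
#' @param task A [task_config()].
#' @param models Character vector of variant names.
#' @param fit A [fit_config()].
#' @param seed Master seed.
#' @param n_participants Participants to simulate.
#' @param out_dir Output directory.
#' @return An object of class `ddm_run_config`.
#' @export
run_config <- function(task = task_config(), models = "M",
                       fit = fit_config("fast"), seed = 1,
                       n_participants = 1, out_dir = ".") {
  bad <- setdiff(models, ddm_model_names(include_duplicates = TRUE))
  if (length(bad)) stop("unknown model name in config: ",
                        paste(bad, collapse = ", "))
  structure(list(task = task, models = models, fit = fit, seed = seed,
                 n_participants = n_participants, out_dir = out_dir),
            class = "ddm_run_config")
}

#' @rdname run_config
#' @param config A `ddm_run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(list(task = unclass(config$task),
                            models = config$models,
                            fit = unclass(config$fit),
                            seed = config$seed,
                            n_participants = config$n_participants,
                            out_dir = config$out_dir),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("task", "models", "seed")) if (is.null(x[[f]]))
    stop("config is missing required field: ", f)
  fit_args <- x$fit[names(x$fit) %in% names(formals(fit_config))]
  run_config(task = do.call(task_config,
                            x$task[names(x$task) %in% names(formals(task_config))]),
             models = x$models,
             fit = do.call(fit_config, fit_args),
             seed = x$seed,
             n_participants = if (is.null(x$n_participants)) 1 else x$n_participants,
             out_dir = if (is.null(x$out_dir)) "." else x$out_dir)
}

#' Derive recorded sub-seeds from a master seed
#'
#' Every stochastic stage receives its own derived seed so that each output
#' is independently reproducible.
#'
#' @param master Master seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}
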