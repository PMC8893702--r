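#' Checkpoint input/output
#'
#' Checkpoints store the full parameter set (raw recurrent weights, sign
#' vector, input and output weights) plus the scalar constants (`tau`,
#' `sigma`, training `dt`, rate bound, noise mode) and optional metadata
#' (`taskName`, `seed`) in R's native binary serialization, giving a
#' bit-exact round trip.
#'
#' @param params A [NetworkParams-class].
#' @param path File path (conventionally `.rds`).
#' @param taskName,seed Optional metadata recorded alongside the weights.
#' @return `writeCheckpoint` returns `path` invisibly; `readCheckpoint`
#'   returns the [NetworkParams-class] with metadata in
#'   `attr(, "taskName")` / `attr(, "seed")`.
#' @export
writeCheckpoint <- function(params, path, taskName = NA_character_,
                            seed = NA_integer_) {
  stopifnot(is(params, "NetworkParams"))
  obj <- list(wRec = params@wRec, signVector = params@signVector,
              wIn = params@wIn, wOut = params@wOut, tau = params@tau,
              sigma = params@sigma, dtTrain = params@dt,
              rateBound = params@rateBound, noiseMode = params@noiseMode,
              taskName = taskName, seed = seed)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  if (!file.exists(path))
    stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  params <- new("NetworkParams", wRec = obj$wRec,
                signVector = obj$signVector, wIn = obj$wIn,
                wOut = obj$wOut, tau = obj$tau, sigma = obj$sigma,
                dt = obj$dtTrain, rateBound = obj$rateBound,
                noiseMode = obj$noiseMode)
  attr(params, "taskName") <- obj$taskName
  attr(params, "seed") <- obj$seed
  params
}

#' Read a task configuration from a YAML file
#'
#' Every [taskConfig()] argument is a key; missing keys take the defaults.
#'
#' @param path YAML file path.
#' @return A [TaskConfig-class].
#' @export
readTaskConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(taskConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown task config keys: ", paste(unknown, collapse = ", "))
  do.call(taskConfig, vals)
}

#' @rdname readTaskConfig
#' @param config A [TaskConfig-class] to write.
#' @export
writeTaskConfig <- function(config, path) {
  stopifnot(is(config, "TaskConfig"))
  vals <- lapply(slotNames(config), function(s) slot(config, s))
  names(vals) <- slotNames(config)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Serialize a trial
#'
#' Stores the trial's arrays (inputs, target, mask) and its scalar
#' landmarks (stimulus onset, condition, trial length) in R's native
#' binary serialization.
#'
#' @param trial A [TrialBatch-class].
#' @param path File path (`.rds`).
#' @return The written path invisibly; `readTrial` returns the
#'   [TrialBatch-class].
#' @export
writeTrial <- function(trial, path) {
  stopifnot(is(trial, "TrialBatch"))
  saveRDS(trial, path)
  invisible(path)
}

#' @rdname writeTrial
#' @export
readTrial <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  obj <- readRDS(path)
  stopifnot(is(obj, "TrialBatch"))
  obj
}

#' Serialize a rate trajectory
#'
#' @param traj A [RateTrajectory-class] (or [PrototypePair-class]).
#' @param path File path (`.rds`).
#' @return The written path, invisibly; `readTrajectory` returns the
#'   object.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "RateTrajectory") || is(traj, "PrototypePair"))
  saveRDS(traj, path)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  readRDS(path)
}
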