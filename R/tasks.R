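#' Construct a task configuration
#'
#' Builds the configuration of one of the two interval-production tasks.
#' In the 2-Context task a transient Go cue marks trial onset and a
#' sustained analog context level (0.75 for short, 0.25 for long) specifies
#' which interval to produce. In the 2-Stimulus task two distinct transient
#' input channels cue the short versus long interval; the required output is
#' identical. Defaults are the study conditions: 3 s and 6 s intervals,
#' 0.5 s stimuli, baseline jittered in \[0.2, 0.6\] s, 0.2 s target hold.
#'
#' @param taskName `"2context"` or `"2stimulus"`.
#' @param shortInterval,longInterval Target intervals in seconds.
#' @param contextLevels Context levels for short and long trials (2-Context).
#' @param inputOverlap Fraction of channel-2 input-weight rows copied from
#'   channel 1 (2-Stimulus weight-overlap variant).
#' @param goEnabled Include the transient Go input (set `FALSE` for the
#'   no-Go variant of the 2-Context task).
#' @param contextMode `"persistent"` or `"transient"` context input.
#' @param stimDuration,baselineRange,postInterval,dt Timing parameters in
#'   seconds; see [TaskConfig-class].
#' @param maskBaseline Exclude the baseline period from the loss mask.
#' @return A [TaskConfig-class].
#' @examples
#' cfg <- taskConfig("2context")
#' trial <- makeTrial(cfg, "short", seed = 1)
#' @export
taskConfig <- function(taskName = c("2context", "2stimulus"),
                       shortInterval = 3, longInterval = 6,
                       contextLevels = c(0.75, 0.25), inputOverlap = 0,
                       goEnabled = TRUE,
                       contextMode = c("persistent", "transient"),
                       stimDuration = 0.5, baselineRange = c(0.2, 0.6),
                       postInterval = 0.2, dt = 0.02,
                       maskBaseline = FALSE) {
  new("TaskConfig",
      taskName = match.arg(taskName),
      shortInterval = shortInterval, longInterval = longInterval,
      contextLevels = contextLevels, inputOverlap = inputOverlap,
      goEnabled = goEnabled, contextMode = match.arg(contextMode),
      stimDuration = stimDuration, baselineRange = baselineRange,
      postInterval = postInterval, dt = dt, maskBaseline = maskBaseline)
}

#' Generate a single task trial
#'
#' Draws the stimulus onset uniformly on the dt-grid within the baseline
#' range and lays out inputs, target and mask on the trial's time grid
#' `t = dt, 2*dt, ..., T` with `T = stimOnset + interval + postInterval`.
#' The target is 0 up to the interval midpoint, ramps linearly from 0 to 1
#' over the second half of the interval, and holds at 1 for
#' `postInterval` seconds.
#'
#' @param config A [TaskConfig-class].
#' @param condition `"short"`, `"long"`, or a numeric generalization
#'   condition: for 2-Context a context level in \[0, 1\]; for 2-Stimulus
#'   either the mixing weight of the long channel or a length-2 vector of
#'   channel weights summing to 1. Numeric conditions use the long-interval
#'   trial length so late crossings remain observable.
#' @param seed Optional RNG seed for the stimulus-onset draw.
#' @return A [TrialBatch-class].
#' @export
makeTrial <- function(config, condition, seed = NULL) {
  stopifnot(is(config, "TaskConfig"))
  dt <- config@dt

  if (is.character(condition)) {
    condition <- match.arg(condition, c("short", "long"))
    interval <- if (condition == "short") config@shortInterval else config@longInterval
    label <- condition
    if (config@taskName == "2context") {
      level <- config@contextLevels[if (condition == "short") 1L else 2L]
      mix <- NULL
    } else {
      mix <- if (condition == "short") c(1, 0) else c(0, 1)
      level <- mix[2L]
    }
  } else {
    if (config@taskName == "2context") {
      if (length(condition) != 1L || condition < 0 || condition > 1)
        stop("2-Context generalization level must be a scalar in [0, 1]")
      level <- condition
      mix <- NULL
    } else {
      if (length(condition) == 1L) condition <- c(1 - condition, condition)
      if (length(condition) != 2L || any(condition < 0) ||
          abs(sum(condition) - 1) > 1e-8)
        stop("2-Stimulus mixing weights must be non-negative and sum to 1")
      mix <- condition
      level <- mix[2L]
    }
    interval <- config@longInterval
    label <- "generalization"
  }

  onsetGrid <- seq(config@baselineRange[1], config@baselineRange[2], by = dt)
  stimOnset <- withSeed(seed, onsetGrid[sample.int(length(onsetGrid), 1L)])

  trialLength <- stimOnset + interval + config@postInterval
  n <- round(trialLength / dt)
  t <- seq_len(n) * dt
  eps <- dt * 1e-6

  stimWindow <- t > stimOnset + eps & t <= stimOnset + config@stimDuration + eps
  inputs <- matrix(0, n, 2L)
  if (config@taskName == "2context") {
    if (config@goEnabled) inputs[stimWindow, 1L] <- 1
    ctxWindow <- if (config@contextMode == "persistent") t > stimOnset + eps else stimWindow
    inputs[ctxWindow, 2L] <- level
  } else {
    inputs[stimWindow, 1L] <- mix[1L]
    inputs[stimWindow, 2L] <- mix[2L]
  }

  rampStart <- stimOnset + 0.5 * interval
  rampEnd <- stimOnset + interval
  target <- numeric(n)
  ramp <- t > rampStart + eps & t <= rampEnd + eps
  target[ramp] <- (t[ramp] - rampStart) / (0.5 * interval)
  target[t > rampEnd + eps] <- 1
  target <- pmin(target, 1)

  mask <- rep(1, n)
  if (config@maskBaseline) mask[t <= stimOnset + eps] <- 0

  new("TrialBatch", inputs = inputs, target = target, mask = mask,
      stimOnset = stimOnset, intervalLabel = label,
      conditionValue = level, interval = interval,
      trialLength = trialLength, dt = dt)
}

#' Draw the (frozen) input weight matrix
#'
#' Input weights are standard-normal and never trained. For the 2-Stimulus
#' weight-overlap variant, a fraction `config@inputOverlap` of the rows of
#' channel 2 is copied from channel 1, interpolating between independent
#' input subspaces (overlap 0) and identical ones (overlap 1).
#'
#' @param config A [TaskConfig-class].
#' @param N Number of network units.
#' @param seed Optional RNG seed.
#' @return N-by-2 numeric matrix.
#' @export
makeInputWeights <- function(config, N, seed = NULL) {
  stopifnot(is(config, "TaskConfig"))
  withSeed(seed, {
    W <- matrix(stats::rnorm(2L * N), N, 2L)
    if (config@taskName == "2stimulus" && config@inputOverlap > 0) {
      k <- round(config@inputOverlap * N)
      if (k > 0) {
        shared <- sample.int(N, k)
        W[shared, 2L] <- W[shared, 1L]
      }
    }
    W
  })
}
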