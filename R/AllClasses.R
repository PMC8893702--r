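#' @import methods
NULL

#' Task configuration for the two-interval timing tasks
#'
#' Holds every tunable of the 2-Context and 2-Stimulus interval-production
#' tasks: the two target intervals, the analog context levels, the stimulus
#' window, the baseline jitter range, and the discretization step. Variant
#' switches cover the no-Go task, transient context input, and partially
#' overlapping input weights for the 2-Stimulus task.
#'
#' @slot taskName `"2context"` or `"2stimulus"`.
#' @slot shortInterval,longInterval Target intervals in seconds (3 and 6).
#' @slot contextLevels Analog context levels for short and long trials
#'   (2-Context task), in (0, 1).
#' @slot inputOverlap Fraction of input-weight rows shared between the two
#'   input channels (2-Stimulus variant), in \[0, 1\].
#' @slot goEnabled Whether the transient Go input is present (2-Context).
#' @slot contextMode `"persistent"` (context on until trial end) or
#'   `"transient"` (context only during the stimulus window).
#' @slot stimDuration Transient stimulus duration in seconds (0.5).
#' @slot baselineRange Range of the random pre-stimulus baseline, seconds.
#' @slot postInterval Duration of the target hold at 1 after the interval
#'   elapses, seconds (0.2).
#' @slot dt Discretization step in seconds.
#' @slot maskBaseline If `TRUE`, the loss mask zeroes the baseline period;
#'   default `FALSE` (mask is 1 everywhere).
#' @export
setClass("TaskConfig",
  slots = c(
    taskName = "character",
    shortInterval = "numeric",
    longInterval = "numeric",
    contextLevels = "numeric",
    inputOverlap = "numeric",
    goEnabled = "logical",
    contextMode = "character",
    stimDuration = "numeric",
    baselineRange = "numeric",
    postInterval = "numeric",
    dt = "numeric",
    maskBaseline = "logical"
  )
)

setValidity("TaskConfig", function(object) {
  msg <- character()
  if (!object@taskName %in% c("2context", "2stimulus"))
    msg <- c(msg, "taskName must be '2context' or '2stimulus'")
  if (object@shortInterval >= object@longInterval)
    msg <- c(msg, "shortInterval must be < longInterval")
  if (any(object@contextLevels <= 0) || any(object@contextLevels >= 1))
    msg <- c(msg, "contextLevels must lie in (0, 1)")
  if (object@inputOverlap < 0 || object@inputOverlap > 1)
    msg <- c(msg, "inputOverlap must lie in [0, 1]")
  if (object@stimDuration <= 0)
    msg <- c(msg, "stimDuration must be positive")
  if (!object@contextMode %in% c("persistent", "transient"))
    msg <- c(msg, "contextMode must be 'persistent' or 'transient'")
  if (object@dt <= 0)
    msg <- c(msg, "dt must be positive")
  durs <- c(object@shortInterval, object@longInterval, object@stimDuration,
            object@baselineRange, object@postInterval)
  if (any(abs(durs / object@dt - round(durs / object@dt)) > 1e-6))
    msg <- c(msg, "dt must divide all task durations to within one step")
  if (length(msg)) msg else TRUE
})

#' A single task trial: inputs, target, mask and timing landmarks
#'
#' @slot inputs Time-by-2 matrix of external inputs (Go/context channels for
#'   2-Context; short/long channels for 2-Stimulus).
#' @slot target Target output time series in \[0, 1\].
#' @slot mask Loss weights per time step.
#' @slot stimOnset Stimulus onset in seconds (end of baseline).
#' @slot intervalLabel `"short"`, `"long"`, or `"generalization"`.
#' @slot conditionValue Analog condition value: context level (2-Context) or
#'   mixing weight of the long channel (2-Stimulus).
#' @slot interval Target interval in seconds used to build the target.
#' @slot trialLength Trial length in seconds.
#' @slot dt Discretization step in seconds.
#' @export
setClass("TrialBatch",
  slots = c(
    inputs = "matrix",
    target = "numeric",
    mask = "numeric",
    stimOnset = "numeric",
    intervalLabel = "character",
    conditionValue = "numeric",
    interval = "numeric",
    trialLength = "numeric",
    dt = "numeric"
  )
)

setValidity("TrialBatch", function(object) {
  msg <- character()
  n <- nrow(object@inputs)
  if (ncol(object@inputs) != 2L)
    msg <- c(msg, "inputs must have two channels")
  if (length(object@target) != n || length(object@mask) != n)
    msg <- c(msg, "target and mask must match the input length")
  if (any(object@target < -1e-9) || any(object@target > 1 + 1e-9))
    msg <- c(msg, "target must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Parameters of the excitatory/inhibitory firing-rate network
#'
#' Stores the raw (trainable) recurrent weights together with the Dale's-law
#' sign vector. The weights used by the dynamics are
#' `relu(wRec) %*% diag(signVector)` with a zero diagonal; see
#' [effectiveWeights()].
#'
#' @slot wRec N-by-N raw recurrent weights (clipped at zero in the forward
#'   pass; negative entries are silent).
#' @slot signVector Length-N vector of +1 (excitatory) / -1 (inhibitory).
#' @slot wIn N-by-2 input weights (frozen during training).
#' @slot wOut Length-N output weights.
#' @slot tau Membrane time constant in seconds (0.1).
#' @slot sigma Noise scale of the stochastic dynamics (0.45).
#' @slot dt Discretization step in seconds the parameters were trained at.
#' @slot rateBound Upper bound of the Softplus firing rate (20).
#' @slot noiseMode `"em"` for the Euler--Maruyama per-step scaling
#'   `sqrt(2 dt / tau) * sigma`, or `"euler"` for the plain-Euler reading
#'   `(dt / tau) * sigma * sqrt(2 tau)`.
#' @export
setClass("NetworkParams",
  slots = c(
    wRec = "matrix",
    signVector = "numeric",
    wIn = "matrix",
    wOut = "numeric",
    tau = "numeric",
    sigma = "numeric",
    dt = "numeric",
    rateBound = "numeric",
    noiseMode = "character"
  )
)

setValidity("NetworkParams", function(object) {
  msg <- character()
  N <- nrow(object@wRec)
  if (ncol(object@wRec) != N)
    msg <- c(msg, "wRec must be square")
  if (any(abs(diag(object@wRec)) > 0))
    msg <- c(msg, "wRec must have a zero diagonal (no self-connections)")
  if (length(object@signVector) != N ||
      !all(object@signVector %in% c(-1, 1)))
    msg <- c(msg, "signVector must be length N with entries +1/-1")
  if (nrow(object@wIn) != N || ncol(object@wIn) != 2L)
    msg <- c(msg, "wIn must be N x 2")
  if (length(object@wOut) != N)
    msg <- c(msg, "wOut must have length N")
  if (!object@noiseMode %in% c("em", "euler"))
    msg <- c(msg, "noiseMode must be 'em' or 'euler'")
  if (length(msg)) msg else TRUE
})

#' Units-by-time firing-rate trajectory
#'
#' @slot rates N-by-T matrix of firing rates.
#' @slot dt Sampling step in seconds.
#' @slot nTrials Number of trials averaged (1 for a single simulation).
#' @slot condition Condition label the trajectory belongs to.
#' @export
setClass("RateTrajectory",
  slots = c(
    rates = "matrix",
    dt = "numeric",
    nTrials = "integer",
    condition = "character"
  )
)

#' Prototypical short/long population dynamics
#'
#' An analytic pair of Gaussian-tuned neural sequences (100 units spanning
#' 6 s) whose short-interval counterpart follows one of the three coding
#' regimes: temporal scaling, absolute timing, or a stimulus-specific
#' (row-shuffled) sequence.
#'
#' @slot short Units-by-T_short rate matrix.
#' @slot long Units-by-T_long rate matrix (identical across regimes).
#' @slot regime `"scaling"`, `"absolute"`, or `"stimulus-specific"`.
#' @slot permutation Row permutation used (stimulus-specific regime;
#'   identity otherwise).
#' @slot dt Sampling step in seconds (0.001).
#' @export
setClass("PrototypePair",
  slots = c(
    short = "matrix",
    long = "matrix",
    regime = "character",
    permutation = "integer",
    dt = "numeric"
  )
)

#' Population-level stimulus-specific index result
#'
#' @slot iMin Minimal-distance index vector (length T_short): for each
#'   short-interval time point, the long-interval time point of minimal
#'   population Euclidean distance.
#' @slot tauMin Breakpoint of the best-matching absolute-scaling reference
#'   vector (1-based).
#' @slot cTauMin Pearson correlation between `iMin` and the best reference
#'   vector.
#' @slot ssiPop `1 - cTauMin`; 0 for pure scaling or pure absolute coding.
#' @slot D Optional T_short-by-T_long distance matrix (empty unless
#'   requested).
#' @export
setClass("PopulationSSI",
  slots = c(
    iMin = "numeric",
    tauMin = "integer",
    cTauMin = "numeric",
    ssiPop = "numeric",
    D = "matrix"
  )
)

#' Per-unit timing classification
#'
#' @slot ssiUnit Per-unit stimulus-specific index (`NA` when undefined).
#' @slot asi Per-unit absolute-scaling index (`NA` when `ssiUnit > 0.5` or
#'   undefined).
#' @slot tauMin Per-unit best warp breakpoint (samples).
#' @slot classLabel `"stimulus-specific"`, `"scaling"`, `"absolute"`, or
#'   `"unclassifiable"`.
#' @slot active Whether the unit passed the activity floor.
#' @export
setClass("TimingClassification",
  slots = c(
    ssiUnit = "numeric",
    asi = "numeric",
    tauMin = "numeric",
    classLabel = "character",
    active = "logical"
  )
)

#' Training state of a network
#'
#' @slot params Current [NetworkParams-class].
#' @slot history Data frame with one row per evaluation point:
#'   `trials`, `performance`, `meanError`.
#' @slot converged Whether the stopping rule (performance > 0.97 and mean
#'   error < 2) fired.
#' @slot trialsUsed Number of training trials consumed.
#' @slot optim Adam moment estimates (internal).
#' @export
setClass("TrainState",
  slots = c(
    params = "NetworkParams",
    history = "data.frame",
    converged = "logical",
    trialsUsed = "integer",
    optim = "list"
  )
)

#' Principal-component subspace of the mean dynamics
#'
#' @slot basis Units-by-k orthonormal matrix of principal directions fitted
#'   on the time-concatenated short and long mean dynamics.
#' @slot varExplained Fraction of variance explained per component (all
#'   components, non-increasing).
#' @slot projections Named list of k-by-T projected (centered) trajectories,
#'   one per condition.
#' @slot projectedWeights k-by-m matrix of projected input/output weight
#'   vectors (named columns).
#' @slot center Per-unit mean removed before projection.
#' @slot dt Sampling step of the projected trajectories, seconds.
#' @export
setClass("SubspaceProjection",
  slots = c(
    basis = "matrix",
    varExplained = "numeric",
    projections = "list",
    projectedWeights = "matrix",
    center = "numeric",
    dt = "numeric"
  )
)
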