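#' Effective recurrent weight matrix
#'
#' The weights entering the dynamics: raw weights rectified at zero, zero
#' diagonal, and each presynaptic column multiplied by the Dale's-law sign
#' of its source unit, so every column is uniformly excitatory or
#' inhibitory.
#'
#' @param object A [NetworkParams-class].
#' @return N-by-N numeric matrix.
#' @export
setGeneric("effectiveWeights", function(object) standardGeneric("effectiveWeights"))

#' @rdname effectiveWeights
#' @export
setMethod("effectiveWeights", "NetworkParams", function(object) {
  W <- pmax(object@wRec, 0)
  diag(W) <- 0
  sweep(W, 2L, object@signVector, "*")
})

#' Logical mask of excitatory units
#' @param object A [NetworkParams-class].
#' @return Logical vector, `TRUE` for excitatory units.
#' @export
setGeneric("isExcitatory", function(object) standardGeneric("isExcitatory"))

#' @rdname isExcitatory
#' @export
setMethod("isExcitatory", "NetworkParams", function(object) object@signVector > 0)

#' Extract the rate matrix of a trajectory
#' @param object A [RateTrajectory-class] or [PrototypePair-class].
#' @param ... Unused.
#' @return Units-by-time numeric matrix (for `PrototypePair`, pass
#'   `which = "short"` or `"long"`).
#' @export
setGeneric("rateMatrix", function(object, ...) standardGeneric("rateMatrix"))

#' @rdname rateMatrix
#' @export
setMethod("rateMatrix", "RateTrajectory", function(object, ...) object@rates)

#' @rdname rateMatrix
#' @param which `"short"` or `"long"`.
#' @export
setMethod("rateMatrix", "PrototypePair", function(object, which = c("short", "long"), ...) {
  slot(object, match.arg(which))
})

#' Class labels of a unit classification
#' @param object A [TimingClassification-class].
#' @return Character vector of per-unit class labels.
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname classLabels
#' @export
setMethod("classLabels", "TimingClassification", function(object) object@classLabel)

#' Trained parameters of a training run
#' @param object A [TrainState-class].
#' @return The [NetworkParams-class] at the end of training.
#' @export
setGeneric("networkParams", function(object) standardGeneric("networkParams"))

#' @rdname networkParams
#' @export
setMethod("networkParams", "TrainState", function(object) object@params)

#' @describeIn TimingClassification Coerce to a per-unit data frame.
#' @param x A `TimingClassification`.
#' @param ... Unused.
#' @export
as.data.frame.TimingClassification <- function(x, ...) {
  data.frame(
    unit = seq_along(x@classLabel),
    ssiUnit = x@ssiUnit,
    asi = x@asi,
    tauMin = x@tauMin,
    class = x@classLabel,
    active = x@active
  )
}

setMethod("show", "TaskConfig", function(object) {
  cat(sprintf("TaskConfig: %s task, intervals %g/%g s, dt %g s\n",
              object@taskName, object@shortInterval, object@longInterval,
              object@dt))
  if (object@taskName == "2context") {
    cat(sprintf("  context levels %g (short) / %g (long), %s, Go %s\n",
                object@contextLevels[1], object@contextLevels[2],
                object@contextMode,
                if (object@goEnabled) "on" else "off"))
  } else {
    cat(sprintf("  input overlap %g\n", object@inputOverlap))
  }
})

setMethod("show", "NetworkParams", function(object) {
  N <- nrow(object@wRec)
  nE <- sum(object@signVector > 0)
  cat(sprintf("NetworkParams: %d units (%d E / %d I), tau %g s, sigma %g, dt %g s\n",
              N, nE, N - nE, object@tau, object@sigma, object@dt))
})

setMethod("show", "TrialBatch", function(object) {
  cat(sprintf("TrialBatch: %s trial, %d steps of %g s, stim onset %g s\n",
              object@intervalLabel, nrow(object@inputs), object@dt,
              object@stimOnset))
})

setMethod("show", "PrototypePair", function(object) {
  cat(sprintf("PrototypePair (%s): %d units, short %d / long %d samples at %g s\n",
              object@regime, nrow(object@long), ncol(object@short),
              ncol(object@long), object@dt))
})

setMethod("show", "PopulationSSI", function(object) {
  cat(sprintf("PopulationSSI: SSI_pop = %.4g (tau_min = %d, c = %.4g)\n",
              object@ssiPop, object@tauMin, object@cTauMin))
})

setMethod("show", "TimingClassification", function(object) {
  tab <- table(factor(object@classLabel,
                      levels = c("stimulus-specific", "scaling", "absolute",
                                 "unclassifiable")))
  cat("TimingClassification:", paste(names(tab), tab, sep = " = ",
                                     collapse = ", "), "\n")
})

setMethod("show", "TrainState", function(object) {
  n <- nrow(object@history)
  cat(sprintf("TrainState: %d trials, converged = %s", object@trialsUsed,
              object@converged))
  if (n > 0) {
    cat(sprintf(", last performance %.3f, last mean error %.3f",
                object@history$performance[n], object@history$meanError[n]))
  }
  cat("\n")
})

setMethod("show", "SubspaceProjection", function(object) {
  k <- ncol(object@basis)
  cat(sprintf("SubspaceProjection: %d components, top-%d variance %.1f%%\n",
              k, k, 100 * sum(object@varExplained[seq_len(k)])))
})
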