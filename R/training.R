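#' Masked squared-error loss of one trial
#'
#' Sum over time of `mask * (o - z)^2`, the error the networks are trained
#' to minimize.
#'
#' @param output Network output time series.
#' @param target Target time series of equal length.
#' @param mask Loss weights (defaults to 1 everywhere).
#' @return Scalar error.
#' @export
trialError <- function(output, target, mask = rep(1, length(target))) {
  if (length(output) != length(target) || length(mask) != length(target))
    stop("output, target and mask must have equal length")
  sum(mask * (output - target)^2)
}

# one Adam step; st holds m, v and the step counter
adamStep <- function(w, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g * g
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(w = w - lr * mhat / (sqrt(vhat) + eps), st = st)
}

#' Evaluate task performance of a network
#'
#' Runs noise-on test trials (half short, half long), scores each with
#' [scoreTrial()] and returns the fraction of correct trials and the mean
#' masked squared error.
#'
#' @param params A [NetworkParams-class].
#' @param config A [TaskConfig-class] at the same `dt`.
#' @param nTrials Number of test trials (100).
#' @param noiseSigma Optional noise override.
#' @param seed Optional RNG seed.
#' @return List with `performance`, `meanError`, and the per-trial
#'   data frame `trials` (`condition`, `crossing`, `correct`, `error`).
#' @export
evaluateNetwork <- function(params, config, nTrials = 100, noiseSigma = NULL,
                            seed = NULL) {
  withSeed(seed, {
    conds <- rep(c("short", "long"), length.out = nTrials)
    trials <- runScoredTrials(params, config, conds,
                              noiseSigma = noiseSigma)
    list(performance = mean(trials$correct),
         meanError = mean(trials$error),
         trials = trials)
  })
}

#' Train a network on an interval task
#'
#' Backpropagation-through-time with Adam (learning rate 0.01, default
#' moments), one parameter update per trial, conditions drawn uniformly
#' from short/long. Only the recurrent and output weights are trained;
#' input weights are frozen. Dale's law is enforced by the rectified
#' reparameterization of the recurrent weights (the forward pass clips at
#' zero, gradients carry subgradient 0 below zero) and the diagonal is
#' forced to zero after every update. Every `evalEvery` trials the network
#' is tested on `evalTrials` noise-on trials; training stops once
#' performance exceeds `perfCriterion` and mean error falls below
#' `errCriterion`.
#'
#' @param config A [TaskConfig-class] (training uses its `dt`, 20 ms).
#' @param net Optional starting [NetworkParams-class]; defaults to
#'   [initNetwork()] with the task's input weights.
#' @param lr Adam learning rate (0.01).
#' @param maxTrials Trial budget before giving up (non-convergence returns
#'   `converged = FALSE`, it is not an error).
#' @param evalEvery,evalTrials Evaluation cadence and size (100 / 100).
#' @param perfCriterion,errCriterion Stopping thresholds (0.97 / 2).
#' @param seed Optional RNG seed covering initialization, trial draws,
#'   noise, and evaluations.
#' @param verbose Print one line per evaluation.
#' @return A [TrainState-class].
#' @export
trainNetwork <- function(config, net = NULL, lr = 0.01, maxTrials = 50000,
                         evalEvery = 100, evalTrials = 100,
                         perfCriterion = 0.97, errCriterion = 2,
                         seed = NULL, verbose = FALSE) {
  stopifnot(is(config, "TaskConfig"))
  withSeed(seed, {
    if (is.null(net)) {
      wIn <- makeInputWeights(config, 200)
      net <- initNetwork(N = 200, dt = config@dt, wIn = wIn)
    }
    if (abs(net@dt - config@dt) > 1e-12)
      stop("network and task dt must agree for training")
    N <- nrow(net@wRec)
    alpha <- config@dt / net@tau
    noiseSd <- stepNoiseSd(net, net@sigma, config@dt)

    stW <- list(m = matrix(0, N, N), v = matrix(0, N, N), t = 0)
    stO <- list(m = numeric(N), v = numeric(N), t = 0)
    history <- data.frame(trials = integer(), performance = numeric(),
                          meanError = numeric())
    converged <- FALSE
    trialCount <- 0L

    while (trialCount < maxTrials) {
      trialCount <- trialCount + 1L
      cond <- if (stats::runif(1) < 0.5) "short" else "long"
      trial <- makeTrial(config, cond)
      bp <- cpp_bptt(net@wRec, net@signVector, net@wIn, net@wOut,
                     trial@inputs, trial@target, trial@mask,
                     alpha, noiseSd, net@rateBound)
      stW$t <- stW$t + 1
      up <- adamStep(net@wRec, bp$gWrec, stW, lr)
      net@wRec <- up$w; stW <- up$st
      diag(net@wRec) <- 0
      stO$t <- stO$t + 1
      up <- adamStep(net@wOut, as.numeric(bp$gWout), stO, lr)
      net@wOut <- up$w; stO <- up$st

      if (trialCount %% evalEvery == 0L) {
        ev <- evaluateNetwork(net, config, nTrials = evalTrials)
        history <- rbind(history,
                         data.frame(trials = trialCount,
                                    performance = ev$performance,
                                    meanError = ev$meanError))
        if (verbose)
          message(sprintf("trial %d: performance %.2f, mean error %.2f",
                          trialCount, ev$performance, ev$meanError))
        if (ev$performance > perfCriterion && ev$meanError < errCriterion) {
          converged <- TRUE
          break
        }
      }
    }
    new("TrainState", params = net, history = history,
        converged = converged, trialsUsed = trialCount,
        optim = list(wRec = stW, wOut = stO))
  })
}
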