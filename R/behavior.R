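#' Score one trial's output
#'
#' The crossing (response) time is the first time the output reaches the
#' threshold of 0.6, detected on the simulation grid. A trial is correct
#' when the crossing falls inside the acceptance window
#' `(stimOnset + 0.5 * interval, stimOnset + interval]`; trials that never
#' cross, or cross outside the window (including during the baseline), are
#' incorrect.
#'
#' @param output Network output time series on the trial's grid.
#' @param trial The [TrialBatch-class] that produced it.
#' @param threshold Crossing threshold (0.6).
#' @return List with `crossing` (seconds, `NA` if the output never crosses)
#'   and `correct` (logical; `NA` for generalization conditions, which have
#'   no defined acceptance window).
#' @export
scoreTrial <- function(output, trial, threshold = 0.6) {
  stopifnot(is(trial, "TrialBatch"))
  idx <- firstCrossing(output, threshold)
  crossing <- if (is.na(idx)) NA_real_ else idx * trial@dt
  if (trial@intervalLabel %in% c("short", "long")) {
    lo <- trial@stimOnset + 0.5 * trial@interval
    hi <- trial@stimOnset + trial@interval
    correct <- !is.na(crossing) && crossing > lo + 1e-9 &&
      crossing <= hi + 1e-9
  } else {
    correct <- NA
  }
  list(crossing = crossing, correct = correct)
}

# Run scored trials over a vector of conditions with one precomputed
# effective weight matrix and no rate storage (uses the current RNG
# stream). Workhorse of evaluation and all behavioral sweeps.
runScoredTrials <- function(params, config, conds, noiseSigma = NULL) {
  sigma <- if (is.null(noiseSigma)) params@sigma else noiseSigma
  Weff <- effectiveWeights(params)
  n <- length(conds)
  crossing <- relCrossing <- err <- rep(NA_real_, n)
  correct <- logical(n)
  for (k in seq_len(n)) {
    cond <- if (is.list(conds)) conds[[k]] else conds[k]
    trial <- makeTrial(config, cond)
    sd <- stepNoiseSd(params, sigma, trial@dt)
    o <- as.numeric(cpp_simulate_output(Weff, params@wIn, params@wOut,
                                        trial@inputs,
                                        trial@dt / params@tau, sd,
                                        params@rateBound))
    sc <- scoreTrial(o, trial)
    crossing[k] <- sc$crossing
    relCrossing[k] <- if (is.na(sc$crossing)) NA_real_ else
      sc$crossing - trial@stimOnset
    correct[k] <- isTRUE(sc$correct)
    err[k] <- trialError(o, trial@target, trial@mask)
  }
  data.frame(condition = if (is.list(conds))
               vapply(conds, function(x) x[length(x)], numeric(1))
             else conds,
             crossing = crossing, relCrossing = relCrossing,
             correct = correct, error = err,
             stringsAsFactors = FALSE)
}

# trials of one repeated condition
conditionTrials <- function(params, config, condition, trialsPerCondition,
                            noiseSigma = NULL) {
  conds <- if (is.character(condition)) rep(condition, trialsPerCondition)
    else rep(list(condition), trialsPerCondition)
  tr <- runScoredTrials(params, config, conds, noiseSigma = noiseSigma)
  tr$correct <- as.numeric(tr$correct)
  tr
}

#' Fit a sigmoid to mean crossing times across conditions
#'
#' Nonlinear least squares fit of `y = b + (a - b) / (1 + exp(g * (m - x)))`
#' with `a`, `b` initialized from the extreme-condition means, `m` at the
#' mid-level, and `g` from the central finite difference; `g` is bounded to
#' \[0, 1000\] (the curve's direction is carried by the sign of `a - b`).
#' Higher `g` means more categorical (step-like) generalization.
#'
#' @param x Condition levels.
#' @param y Mean crossing times per condition (`NA` entries are dropped).
#' @return Named list with coefficients `a`, `b`, `g`, `m` and `fitted`.
#' @export
fitSigmoid <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 4)
    stop("sigmoid fit needs at least 4 conditions with crossings")
  x <- x[keep]; y <- y[keep]
  ord <- order(x); x <- x[ord]; y <- y[ord]
  n <- length(x)
  a0 <- y[n]; b0 <- y[1]
  m0 <- x[ceiling(n / 2)]
  mid <- max(2, min(n - 1, ceiling(n / 2)))
  slope <- (y[mid + 1] - y[mid - 1]) / (x[mid + 1] - x[mid - 1])
  g0 <- abs(4 * slope / (a0 - b0 + 1e-12))
  g0 <- min(max(g0, 1e-3), 500)
  fit <- minpack.lm::nlsLM(
    y ~ b + (a - b) / (1 + exp(g * (m - x))),
    start = list(a = a0, b = b0, g = g0, m = m0),
    lower = c(a = -Inf, b = -Inf, g = 0, m = -Inf),
    upper = c(a = Inf, b = Inf, g = 1000, m = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  co <- as.list(stats::coef(fit))
  c(co, list(fitted = stats::fitted(fit), x = x, y = y))
}

#' Generalization sweep over novel input conditions
#'
#' Tests a trained network on a grid of input conditions: context levels
#' 0.75 down to 0.25 in steps of 0.05 for the 2-Context task, or mixing
#' weights of the long channel 0 to 1 in steps of 0.1 for the 2-Stimulus
#' task (channel weights always sum to 1), with 50 trials per condition.
#' Crossing times are measured relative to stimulus onset. The mean
#' crossing times are fitted with a sigmoid ([fitSigmoid()]) and correlated
#' with the condition levels (Pearson; the absolute value is informative
#' for the 2-Context task, whose correlation is negative).
#'
#' @param params A trained [NetworkParams-class].
#' @param config The task's [TaskConfig-class].
#' @param levels Condition grid; defaults as above.
#' @param trialsPerCondition Trials per condition (50).
#' @param noiseSigma Optional noise override.
#' @param seed Optional RNG seed.
#' @return List with `summary` (per-condition data frame), `fit` (sigmoid
#'   coefficients or `NULL` with a warning when the fit fails), `r`,
#'   `absR`, and Fisher-transformed `fisherZ`.
#' @export
generalizationSweep <- function(params, config, levels = NULL,
                                trialsPerCondition = 50, noiseSigma = NULL,
                                seed = NULL) {
  stopifnot(is(config, "TaskConfig"))
  if (is.null(levels)) {
    levels <- if (config@taskName == "2context")
      seq(config@contextLevels[1], config@contextLevels[2], by = -0.05)
    else seq(0, 1, by = 0.1)
  }
  withSeed(seed, {
    rows <- lapply(levels, function(lev) {
      tr <- conditionTrials(params, config, lev, trialsPerCondition,
                            noiseSigma = noiseSigma)
      cr <- tr$relCrossing[!is.na(tr$relCrossing)]
      data.frame(condition = lev, nTrials = trialsPerCondition,
                 nCrossed = length(cr),
                 meanCrossing = if (length(cr)) mean(cr) else NA_real_,
                 sdCrossing = if (length(cr) > 1) stats::sd(cr) else NA_real_)
    })
    summary <- do.call(rbind, rows)
    dropped <- summary$condition[summary$nCrossed == 0]
    if (length(dropped))
      message("conditions without crossings dropped from the fit: ",
              paste(dropped, collapse = ", "))
    fit <- tryCatch(fitSigmoid(summary$condition, summary$meanCrossing),
                    error = function(e) {
                      warning("sigmoid fit failed: ", conditionMessage(e))
                      NULL
                    })
    keep <- is.finite(summary$meanCrossing)
    r <- stats::cor(summary$condition[keep], summary$meanCrossing[keep])
    list(summary = summary, fit = fit, r = r, absR = abs(r),
         fisherZ = atanh(abs(r)))
  })
}

#' Noise-robustness sweep
#'
#' Tests a trained network at noise levels sigma = 0.1 to 0.8 with 50
#' trials per interval per level, reporting the mean masked squared error
#' over all trials, the standard deviation of crossing times over correct
#' trials, and the incorrect-trial fraction.
#'
#' @param params A trained [NetworkParams-class].
#' @param config The task's [TaskConfig-class].
#' @param sigmas Noise levels to test.
#' @param trialsPerInterval Trials per interval per level (50).
#' @param seed Optional RNG seed.
#' @return Data frame with one row per sigma:
#'   `sigma`, `meanError`, `sdCrossing` (mean of the per-interval SDs),
#'   `incorrectFrac`.
#' @export
noiseSweep <- function(params, config, sigmas = seq(0.1, 0.8, by = 0.1),
                       trialsPerInterval = 50, seed = NULL) {
  stopifnot(is(config, "TaskConfig"))
  withSeed(seed, {
    rows <- lapply(sigmas, function(s) {
      perInt <- lapply(c("short", "long"), function(cond) {
        tr <- conditionTrials(params, config, cond, trialsPerInterval,
                              noiseSigma = s)
        ok <- tr$correct == 1
        list(sd = if (sum(ok) > 1) stats::sd(tr$crossing[ok]) else NA_real_,
             err = tr$error, incorrect = mean(!ok))
      })
      data.frame(sigma = s,
                 meanError = mean(c(perInt[[1]]$err, perInt[[2]]$err)),
                 sdCrossing = mean(c(perInt[[1]]$sd, perInt[[2]]$sd),
                                   na.rm = TRUE),
                 incorrectFrac = mean(c(perInt[[1]]$incorrect,
                                        perInt[[2]]$incorrect)))
    })
    do.call(rbind, rows)
  })
}
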