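#' Initialize an excitatory/inhibitory firing-rate network
#'
#' The recurrent matrix starts as a random sparse matrix: each off-diagonal
#' entry is present with probability `connectionProb`, present entries are
#' absolute values of zero-mean normal draws with standard deviation
#' `gain / sqrt(connectionProb * N)` (the conventional normalization under
#' which `gain` sets the dynamic regime independently of size and
#' sparsity), and the outgoing weights of inhibitory units are multiplied
#' by `inhibitoryBoost` (initialization only) so the network begins in an
#' approximately balanced regime. Input weights are standard normal and
#' frozen; output weights are normal scaled by `gain / sqrt(N)`.
#'
#' @param N Number of units (200).
#' @param fracExcitatory Fraction of excitatory units (0.8).
#' @param connectionProb Initial connection probability (0.2; 1 for the
#'   fully connected variant).
#' @param gain Standard deviation of the initial weight draws (1).
#' @param inhibitoryBoost Multiplier on initial inhibitory columns (4).
#' @param tau Time constant in seconds (0.1).
#' @param sigma Noise scale of the dynamics (0.45).
#' @param dt Discretization step in seconds (0.02 for training).
#' @param rateBound Softplus rate cap (20).
#' @param noiseMode Per-step noise scaling, see [NetworkParams-class].
#' @param wIn Optional pre-drawn N-by-2 input weight matrix (e.g. from
#'   [makeInputWeights()] for the overlap variant).
#' @param seed Optional RNG seed.
#' @return A [NetworkParams-class].
#' @examples
#' net <- initNetwork(N = 50, seed = 1)
#' mean(effectiveWeights(net)[upper.tri(diag(50))] != 0)
#' @export
initNetwork <- function(N = 200, fracExcitatory = 0.8, connectionProb = 0.2,
                        gain = 1, inhibitoryBoost = 4, tau = 0.1,
                        sigma = 0.45, dt = 0.02, rateBound = 20,
                        noiseMode = c("em", "euler"), wIn = NULL,
                        seed = NULL) {
  stopifnot(connectionProb > 0, connectionProb <= 1, gain > 0)
  noiseMode <- match.arg(noiseMode)
  nE <- round(N * fracExcitatory)
  sgn <- c(rep(1, nE), rep(-1, N - nE))
  withSeed(seed, {
    present <- matrix(stats::runif(N * N) < connectionProb, N, N)
    sdW <- gain / sqrt(connectionProb * N)
    W <- abs(matrix(stats::rnorm(N * N, sd = sdW), N, N)) * present
    diag(W) <- 0
    W[, sgn < 0] <- W[, sgn < 0] * inhibitoryBoost
    if (is.null(wIn)) wIn <- matrix(stats::rnorm(2L * N), N, 2L)
    wOut <- stats::rnorm(N, sd = gain / sqrt(N))
    new("NetworkParams", wRec = W, signVector = sgn, wIn = wIn,
        wOut = wOut, tau = tau, sigma = sigma, dt = dt,
        rateBound = rateBound, noiseMode = noiseMode)
  })
}

# per-step noise s.d. for the chosen discretization of the noise term
stepNoiseSd <- function(params, sigma, dt) {
  alpha <- dt / params@tau
  switch(params@noiseMode,
         em = sqrt(2 * alpha) * sigma,
         euler = alpha * sigma * sqrt(2 * params@tau))
}

#' Simulate one trial of the network dynamics
#'
#' Euler integration of
#' `tau dx/dt = -x + W r + W_in I + noise`, with
#' `r = min(log(1 + exp(x)), rateBound)` and linear readout
#' `o = w_out' r`, starting from `x = 0`. The per-step update is
#' `x <- (1 - alpha) x + alpha (W r + W_in I) + sqrt(2 alpha) sigma xi`
#' with `alpha = dt / tau` and unit-variance Gaussian `xi` (Euler--Maruyama
#' scaling; see [NetworkParams-class] for the alternative).
#'
#' @param params A [NetworkParams-class].
#' @param trial A [TrialBatch-class]; its grid defines the simulation step,
#'   so build the trial at the desired `dt` (e.g. 1 ms for analysis-time
#'   dynamics of a network trained at 20 ms).
#' @param noiseSigma Override of the noise scale (e.g. 0 for deterministic
#'   dynamics, or the sweep values of a robustness test).
#' @param seed Optional RNG seed for the noise stream.
#' @return A list with `trajectory` (a [RateTrajectory-class]) and
#'   `output` (numeric vector).
#' @export
simulateTrial <- function(params, trial, noiseSigma = NULL, seed = NULL) {
  stopifnot(is(params, "NetworkParams"), is(trial, "TrialBatch"))
  # the trial's grid sets the integration step; params@dt only records the
  # step the weights were trained at
  sigma <- if (is.null(noiseSigma)) params@sigma else noiseSigma
  sd <- stepNoiseSd(params, sigma, trial@dt)
  res <- withSeed(seed,
    cpp_simulate(effectiveWeights(params), params@wIn, params@wOut,
                 trial@inputs, trial@dt / params@tau, sd, params@rateBound))
  traj <- new("RateTrajectory", rates = res$rates, dt = trial@dt,
              nTrials = 1L, condition = trial@intervalLabel)
  list(trajectory = traj, output = as.numeric(res$output))
}

#' Trial-averaged delay-epoch dynamics
#'
#' Simulates `nTrials` noise-on trials per condition at the analysis step
#' (1 ms), extracts the delay epoch (stimulus onset to onset + interval,
#' which has a fixed number of samples regardless of the jittered baseline)
#' and averages rates across trials.
#'
#' @param params A [NetworkParams-class].
#' @param config A [TaskConfig-class] (its `dt` is replaced by `dt`).
#' @param condition `"short"` or `"long"`.
#' @param nTrials Trials to average (25).
#' @param dt Analysis discretization step in seconds (0.001).
#' @param noiseSigma Optional noise override.
#' @param seed Optional RNG seed.
#' @return A [RateTrajectory-class] of the units-by-interval mean rates.
#' @export
averageDynamics <- function(params, config, condition, nTrials = 25,
                            dt = 0.001, noiseSigma = NULL, seed = NULL) {
  stopifnot(is(config, "TaskConfig"))
  cfg <- config
  cfg@dt <- dt
  withSeed(seed, {
    acc <- NULL
    for (k in seq_len(nTrials)) {
      trial <- makeTrial(cfg, condition)
      sim <- simulateTrial(params, trial, noiseSigma = noiseSigma)
      i0 <- round(trial@stimOnset / dt)
      nInt <- round(trial@interval / dt)
      win <- sim$trajectory@rates[, (i0 + 1L):(i0 + nInt), drop = FALSE]
      acc <- if (is.null(acc)) win else acc + win
    }
    new("RateTrajectory", rates = acc / nTrials, dt = dt,
        nTrials = as.integer(nTrials), condition = condition)
  })
}
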