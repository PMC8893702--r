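# shared fixtures: small, fast objects built in code

# a config whose baseline is pinned so the stimulus onset is deterministic
fixedOnsetConfig <- function(taskName = "2context", dt = 0.01,
                             onset = 0.5, ...) {
  taskConfig(taskName, dt = dt, baselineRange = c(onset, onset), ...)
}

# tiny 2-unit network with a printed weight matrix, for hand-checked steps
twoUnitNetwork <- function(w12 = 0.5, w21 = 0.3, dt = 0.02) {
  net <- initNetwork(N = 2, fracExcitatory = 0.5, connectionProb = 1,
                     dt = dt, seed = 1)
  net@wRec <- matrix(c(0, w21, w12, 0), 2, 2)  # column-major
  net
}

# downsampled prototypes (10 ms) keep oracle comparisons fast
smallPrototype <- function(regime, ...) {
  makePrototype(regime, dt = 0.01, ...)
}

# naive O(Ts*Tl*N) population SSI oracle: explicit loops, no shortcuts
oracleSSIPop <- function(Xs, Xl) {
  Ts <- ncol(Xs); Tl <- ncol(Xl)
  D <- matrix(0, Ts, Tl)
  for (s in seq_len(Ts)) {
    for (l in seq_len(Tl)) {
      D[s, l] <- sqrt(sum((Xs[, s] - Xl[, l])^2))
    }
  }
  iMin <- integer(Ts)
  for (s in seq_len(Ts)) iMin[s] <- which.min(D[s, ])
  best <- Inf; tauMin <- 1L
  for (tau in seq_len(Ts)) {
    ref <- if (tau == Ts) seq_len(Ts) else
      c(seq_len(tau), tau + seq_len(Ts - tau) * (Tl - tau) / (Ts - tau))
    d <- sum((iMin - ref)^2)
    if (d < best) { best <- d; tauMin <- tau }
  }
  ref <- if (tauMin == Ts) seq_len(Ts) else
    c(seq_len(tauMin), tauMin + seq_len(Ts - tauMin) * (Tl - tauMin) / (Ts - tauMin))
  cT <- cor(iMin, ref)
  list(iMin = iMin, tauMin = tauMin, cTauMin = cT, ssiPop = 1 - cT)
}

# naive unit-level warp oracle: builds each warped trace with stats::approx
oracleUnitIndices <- function(x, y) {
  Ts <- length(x); Tl <- length(y)
  warp <- function(tau) {
    out <- numeric(Ts)
    if (tau > 0) out[seq_len(tau)] <- y[seq_len(tau)]
    if (tau < Ts) {
      a <- (Tl - tau) / (Ts - tau)
      tt <- (tau + 1):Ts
      out[tt] <- approx(seq_len(Tl), y, xout = pmin(tau + a * (tt - tau), Tl))$y
    }
    out
  }
  dist <- vapply(0:Ts, function(tau) sum((x - warp(tau))^2), numeric(1))
  tauMin <- (0:Ts)[max(which(dist == min(dist)))]  # ties -> largest tau
  w <- warp(tauMin)
  ssi <- 1 - cor(x, w)
  list(tauMin = tauMin, dist = min(dist), ssiUnit = ssi, warped = w)
}
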