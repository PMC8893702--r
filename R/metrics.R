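#' Absolute-scaling reference index vector
#'
#' Column `tau` of the reference matrix: identity indices `1..tau` followed
#' by `tau + k * alpha` with `alpha = (Tlong - tau) / (Tshort - tau)`, so
#' every vector has `Tshort` entries ending at `Tlong`. `tau = 1` is the
#' pure-scaling profile, `tau = Tshort` the pure-absolute identity profile
#' (the degenerate `alpha` is bypassed by construction).
#'
#' @param tau Breakpoint, integer in `1..Tshort`.
#' @param Tshort,Tlong Sample counts of the short and long dynamics.
#' @param partialScaling Fix the post-breakpoint scaling factor at
#'   `Tlong / Tshort` instead of stretching to reach `Tlong`, so the last
#'   entry varies from `Tlong` (tau = 1) down to `Tshort` (tau = Tshort).
#'   Exposed for completeness; not validated against reference values.
#' @return Numeric vector of length `Tshort`.
#' @examples
#' referenceVector(3000, 3000, 6000)[1:3]  # identity
#' @export
referenceVector <- function(tau, Tshort, Tlong, partialScaling = FALSE) {
  stopifnot(tau >= 1, tau <= Tshort)
  if (tau == Tshort) return(as.numeric(seq_len(Tshort)))
  alpha <- if (partialScaling) Tlong / Tshort else
    (Tlong - tau) / (Tshort - tau)
  c(seq_len(tau), tau + seq_len(Tshort - tau) * alpha)
}

#' Population-level stimulus-specific index
#'
#' Quantifies how far the relationship between the short- and long-interval
#' population trajectories is from any absolute-scaling combination.
#' The pairwise Euclidean distance between the two units-by-time matrices
#' gives the distance matrix `D`; the per-row argmin gives the minimal
#' index vector `I_min`; `I_min` is matched (Euclidean) against the family
#' of reference vectors ([referenceVector()]) over all breakpoints, and
#' `SSI_pop = 1 - cor(I_min, reference(tau_min))`. Pure scaling yields a
#' linear `I_min` matched at `tau_min = 1`; pure absolute timing yields the
#' identity, matched at `tau_min = Tshort`; both give `SSI_pop = 0`.
#'
#' @param short,long Units-by-time rate matrices (or
#'   [RateTrajectory-class] / numeric matrices) at the same unit count and
#'   sampling step, trial-averaged.
#' @param normalize Divide each unit's rates by its peak across both
#'   intervals before computing distances (off by default; raw
#'   trial-averaged rates are used).
#' @param returnD Keep the full distance matrix in the result.
#' @param partialScaling Use the fixed-factor reference family; see
#'   [referenceVector()].
#' @return A [PopulationSSI-class]. When `I_min` is constant the
#'   correlation is undefined and `ssiPop` is `NA` with a warning.
#' @export
computeSSIPop <- function(short, long, normalize = FALSE, returnD = FALSE,
                          partialScaling = FALSE) {
  Xs <- if (is(short, "RateTrajectory")) short@rates else short
  Xl <- if (is(long, "RateTrajectory")) long@rates else long
  stopifnot(nrow(Xs) == nrow(Xl))
  if (normalize) {
    peak <- pmax(apply(Xs, 1, max), apply(Xl, 1, max))
    peak[peak == 0] <- 1
    Xs <- Xs / peak
    Xl <- Xl / peak
  }
  Ts <- ncol(Xs); Tl <- ncol(Xl)
  # squared distances via the Gram expansion (BLAS)
  D2 <- outer(colSums(Xs^2), colSums(Xl^2), "+") - 2 * crossprod(Xs, Xl)
  iMin <- max.col(-D2, ties.method = "first")
  res <- matchReference(iMin, Ts, Tl, partialScaling)
  cTau <- if (stats::sd(iMin) == 0) {
    warning("constant minimal index vector: correlation undefined")
    NA_real_
  } else stats::cor(iMin, referenceVector(res$tauMin, Ts, Tl, partialScaling))
  new("PopulationSSI", iMin = as.numeric(iMin),
      tauMin = as.integer(res$tauMin), cTauMin = cTau,
      ssiPop = 1 - cTau,
      D = if (returnD) sqrt(pmax(D2, 0)) else matrix(numeric(), 0, 0))
}

# best-matching reference breakpoint for an index vector (first argmin)
matchReference <- function(iMin, Ts, Tl, partialScaling = FALSE) {
  best <- Inf; bestTau <- 1L
  for (tau in seq_len(Ts)) {
    d <- sum((iMin - referenceVector(tau, Ts, Tl, partialScaling))^2)
    if (d < best) { best <- d; bestTau <- tau }
  }
  list(tauMin = bestTau, dist = best)
}

#' Unit-level warp indices: SSI_unit, ASI
#'
#' Searches over breakpoints `tau` for the best two-segment transformation
#' of a unit's long-interval trace `y` onto its short-interval trace `x`:
#' identity (absolute timing) before `tau`, temporal compression by
#' `alpha = (Tlong - tau) / (Tshort - tau)` after (scaling), with linear
#' interpolation at fractional indices. `tau_min` minimizes the squared
#' distance; `SSI_unit = 1 - cor(x, warped y at tau_min)`. When
#' `SSI_unit <= 0.5` the absolute and scaling weights
#' `W_abs = mean over t <= tau_min of |(x(t) - x(1)) (y(t) - y(1))|`,
#' `W_scale = mean over t >= tau_min of |(x(t) - x(tau_min)) (ytilde(t) - y(tau_min))|`
#' give `AbsR = W_abs / (W_abs + W_scale)` and
#' `ASI = (tau_min / Tshort + AbsR) / 2`; otherwise ASI is undefined.
#'
#' @param x Short-interval trace (length `Tshort`).
#' @param y Long-interval trace (length `Tlong`).
#' @param tauStep Breakpoint grid step in samples; steps > 1 scan a coarse
#'   grid and refine the best breakpoint locally at step 1.
#' @return List with `ssiUnit`, `asi`, `tauMin`, `dist` (the minimal
#'   squared distance). Zero-variance traces give `ssiUnit = NA`;
#'   `tau_min = 0` (pure scaling) sets `AbsR = 0`; `W_abs = W_scale = 0`
#'   gives `asi = NA`.
#' @export
computeUnitIndices <- function(x, y, tauStep = 1) {
  Ts <- length(x); Tl <- length(y)
  taus <- unique(c(seq.int(0L, Ts, by = as.integer(tauStep)), Ts))
  dist <- cpp_dist_profile(x, y, as.integer(taus))
  # exact ties resolve to the largest breakpoint: a trace that admits both
  # readings (e.g. flat after its field) is absolute, not scaled
  argminLast <- function(v) max(which(v == min(v)))
  tauMin <- taus[argminLast(dist)]
  if (tauStep > 1) {
    lo <- max(0L, tauMin - as.integer(tauStep))
    hi <- min(Ts, tauMin + as.integer(tauStep))
    fine <- seq.int(lo, hi)
    dfine <- cpp_dist_profile(x, y, as.integer(fine))
    tauMin <- fine[argminLast(dfine)]
    dmin <- min(dfine)
  } else {
    dmin <- min(dist)
  }
  warped <- as.numeric(cpp_warp_long(y, as.integer(tauMin), Ts))
  if (stats::sd(x) == 0 || stats::sd(warped) == 0)
    return(list(ssiUnit = NA_real_, asi = NA_real_, tauMin = tauMin,
                dist = dmin))
  ssi <- 1 - stats::cor(x, warped)
  asi <- NA_real_
  if (ssi <= 0.5) {
    if (tauMin == 0) {
      absR <- 0
    } else {
      wAbs <- mean(abs((x[seq_len(tauMin)] - x[1]) *
                       (y[seq_len(tauMin)] - y[1])))
      seg <- tauMin:Ts
      wScale <- mean(abs((x[seg] - x[tauMin]) * (warped[seg] - y[tauMin])))
      if (wAbs + wScale == 0)
        return(list(ssiUnit = ssi, asi = NA_real_, tauMin = tauMin,
                    dist = dmin))
      absR <- wAbs / (wAbs + wScale)
    }
    asi <- (tauMin / Ts + absR) / 2
  }
  list(ssiUnit = ssi, asi = asi, tauMin = tauMin, dist = dmin)
}

#' Classify units into timing-code classes
#'
#' Applies [computeUnitIndices()] to every unit of a short/long pair of
#' trial-averaged rate matrices and the threshold rule: stimulus-specific
#' if `SSI_unit > 0.5`; otherwise absolute if `ASI > 0.5`, else scaling.
#' Units whose peak rate across both intervals falls below `activityFloor`
#' are unclassifiable (flat traces carry no timing information) and should
#' be excluded from class fractions.
#'
#' @param short,long Units-by-time rate matrices, [RateTrajectory-class],
#'   or a [PrototypePair-class] passed as `short` (then `long` is ignored).
#' @param activityFloor Minimal peak rate for a unit to be classified
#'   (default 0.2, i.e. 1 percent of the rate bound of 20).
#' @param tauStep Breakpoint grid step passed to [computeUnitIndices()].
#' @return A [TimingClassification-class].
#' @examples
#' cls <- classifyUnits(makePrototype("scaling"), tauStep = 10)
#' table(classLabels(cls))
#' @export
classifyUnits <- function(short, long = NULL, activityFloor = 0.2,
                          tauStep = 1) {
  if (is(short, "PrototypePair")) {
    long <- short@long
    short <- short@short
  }
  Xs <- if (is(short, "RateTrajectory")) short@rates else short
  Xl <- if (is(long, "RateTrajectory")) long@rates else long
  stopifnot(nrow(Xs) == nrow(Xl))
  n <- nrow(Xs)
  ssi <- asi <- tauMin <- rep(NA_real_, n)
  cls <- rep("unclassifiable", n)
  active <- rep(FALSE, n)
  for (i in seq_len(n)) {
    active[i] <- max(Xs[i, ], Xl[i, ]) >= activityFloor
    if (!active[i]) next
    ui <- computeUnitIndices(Xs[i, ], Xl[i, ], tauStep = tauStep)
    ssi[i] <- ui$ssiUnit; asi[i] <- ui$asi; tauMin[i] <- ui$tauMin
    if (is.na(ui$ssiUnit)) next
    cls[i] <- if (ui$ssiUnit > 0.5) "stimulus-specific"
      else if (is.na(ui$asi)) "unclassifiable"
      else if (ui$asi > 0.5) "absolute" else "scaling"
  }
  new("TimingClassification", ssiUnit = ssi, asi = asi, tauMin = tauMin,
      classLabel = cls, active = active)
}
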