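#' Principal-component subspace of the mean dynamics
#'
#' PCA of the time-concatenated short and long mean dynamics (units as
#' variables, time points as observations, per-unit mean over concatenated
#' time removed), keeping the top `nComponents` directions. The centered
#' trajectories and the input/output weight vectors are projected onto the
#' basis, giving the low-dimensional state-space picture in which segment
#' angles to the input and output subspaces are measured.
#'
#' @param short,long Units-by-time mean rate matrices or
#'   [RateTrajectory-class] objects.
#' @param params Optional [NetworkParams-class] whose input/output weight
#'   vectors are projected (columns named `input1`, `input2`, `output`).
#' @param nComponents Number of principal directions to keep (3; fewer with
#'   a warning when the dynamics have lower rank).
#' @param dt Sampling step recorded for segment binning (taken from
#'   `short` when it is a trajectory).
#' @return A [SubspaceProjection-class].
#' @export
fitSubspace <- function(short, long, params = NULL, nComponents = 3,
                        dt = NULL) {
  if (is(short, "RateTrajectory")) { if (is.null(dt)) dt <- short@dt }
  Xs <- if (is(short, "RateTrajectory")) short@rates else short
  Xl <- if (is(long, "RateTrajectory")) long@rates else long
  stopifnot(nrow(Xs) == nrow(Xl))
  if (is.null(dt)) dt <- 1
  X <- cbind(Xs, Xl)
  ctr <- rowMeans(X)
  Xc <- X - ctr
  pc <- stats::prcomp(t(Xc), center = FALSE)
  varFrac <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  k <- min(nComponents, rank)
  if (k < nComponents)
    warning(sprintf("dynamics have rank %d; keeping %d components", rank, k))
  basis <- pc$rotation[, seq_len(k), drop = FALSE]
  projections <- list(short = crossprod(basis, Xs - ctr),
                      long = crossprod(basis, Xl - ctr))
  wmat <- if (is.null(params)) matrix(numeric(), nrow(Xs), 0)
    else cbind(input1 = params@wIn[, 1], input2 = params@wIn[, 2],
               output = params@wOut)
  projW <- crossprod(basis, wmat)
  new("SubspaceProjection", basis = basis, varExplained = varFrac,
      projections = projections, projectedWeights = projW,
      center = as.numeric(ctr), dt = dt)
}

# angle between two vectors in degrees, in [0, 180]
vectorAngle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  acos(min(1, max(-1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Angles between trajectory segments and projected weight vectors
#'
#' Bins each projected trajectory into consecutive segments (250 ms by
#' default), represents each segment by its end-minus-start vector in the
#' component space, and reports the angle in degrees (\[0, 180\]) between
#' every segment and every projected input/output weight vector.
#'
#' @param projection A [SubspaceProjection-class] with projected weights.
#' @param binSeconds Segment length in seconds (0.25).
#' @return Data frame `{condition, binStart, weight, angle}`; zero-length
#'   segments give `NA` angles.
#' @export
segmentAngles <- function(projection, binSeconds = 0.25) {
  stopifnot(is(projection, "SubspaceProjection"))
  W <- projection@projectedWeights
  if (ncol(W) == 0)
    stop("projection carries no weight vectors; pass params to fitSubspace")
  bsteps <- round(binSeconds / projection@dt)
  rows <- list()
  for (cond in names(projection@projections)) {
    P <- projection@projections[[cond]]
    nbin <- floor(ncol(P) / bsteps)
    for (b in seq_len(nbin)) {
      seg <- P[, b * bsteps] - P[, (b - 1) * bsteps + 1]
      for (w in colnames(W)) {
        rows[[length(rows) + 1L]] <-
          data.frame(condition = cond,
                     binStart = (b - 1) * bsteps * projection@dt,
                     weight = w, angle = vectorAngle(seg, W[, w]))
      }
    }
  }
  do.call(rbind, rows)
}
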