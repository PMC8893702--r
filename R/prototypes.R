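#' Prototypical population dynamics for timing two intervals
#'
#' Generates the analytic fixture used to validate the timing-code metrics:
#' 100 units whose long-interval (6 s) firing rates are Gaussian bumps of
#' width 0.8 s with peaks uniformly tiling the interval,
#' `x_i(t) = exp(-(t - (i/n) * 6)^2 / (2 * 0.8^2))`, sampled at 1 ms. The
#' short-interval (3 s) dynamics follow the requested coding regime:
#'
#' * `"scaling"` — uniform temporal subsampling of the long dynamics
#'   (every 2nd column), i.e. the same trajectory traversed twice as fast;
#' * `"absolute"` — the first 3 s of the long dynamics, so early units are
#'   identical across intervals and late-field units simply have not become
#'   active yet in the short trial;
#' * `"stimulus-specific"` — the scaling matrix with unit rows shuffled by
#'   a seeded random permutation, destroying any common trajectory.
#'
#' @param regime `"scaling"`, `"absolute"`, or `"stimulus-specific"`.
#' @param nUnits Number of units (100).
#' @param shortInterval,longInterval Interval lengths in seconds (3, 6).
#' @param dt Sampling step in seconds (0.001).
#' @param width Gaussian tuning width in seconds (0.8).
#' @param permuteFraction Fraction of rows shuffled in the
#'   stimulus-specific regime (1 = full shuffle; smaller values permute a
#'   random subset among themselves, interpolating toward the scaling
#'   regime).
#' @param permutation Optional explicit row permutation (overrides the
#'   seeded draw).
#' @param seed RNG seed for the permutation.
#' @return A [PrototypePair-class].
#' @examples
#' p <- makePrototype("scaling")
#' all(rateMatrix(p, "short") == rateMatrix(p, "long")[, seq(2, 6000, 2)])
#' @export
makePrototype <- function(regime = c("scaling", "absolute", "stimulus-specific"),
                          nUnits = 100, shortInterval = 3, longInterval = 6,
                          dt = 0.001, width = 0.8, permuteFraction = 1,
                          permutation = NULL, seed = NULL) {
  regime <- match.arg(regime)
  Tl <- round(longInterval / dt)
  Ts <- round(shortInterval / dt)
  t <- seq_len(Tl) * dt
  centers <- (seq_len(nUnits) / nUnits) * longInterval
  long <- exp(-(outer(centers, t, "-"))^2 / (2 * width^2))

  ratio <- Tl / Ts
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("longInterval must be an integer multiple of shortInterval")
  subsample <- seq.int(ratio, Tl, by = ratio)

  perm <- seq_len(nUnits)
  short <- switch(regime,
    scaling = long[, subsample, drop = FALSE],
    absolute = long[, seq_len(Ts), drop = FALSE],
    "stimulus-specific" = {
      scaled <- long[, subsample, drop = FALSE]
      perm <- withSeed(seed, {
        if (is.null(permutation)) {
          k <- round(permuteFraction * nUnits)
          p <- seq_len(nUnits)
          if (k >= 2) {
            rows <- sample.int(nUnits, k)
            p[rows] <- rows[sample.int(k)]
          }
          p
        } else as.integer(permutation)
      })
      scaled[perm, , drop = FALSE]
    })

  new("PrototypePair", short = short, long = long, regime = regime,
      permutation = as.integer(perm), dt = dt)
}
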