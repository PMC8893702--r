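#' Delete units from the recurrent matrix
#'
#' Removes all recurrent connections attached to the given units: the
#' corresponding rows and columns of the raw recurrent weights are zeroed.
#' Input and output weights are untouched, so a deleted unit still receives
#' external input and contributes its (input-driven) rate to the readout.
#'
#' @param params A [NetworkParams-class].
#' @param units Integer indices of units to delete (may be empty).
#' @return The lesioned [NetworkParams-class].
#' @export
deleteUnits <- function(params, units) {
  stopifnot(is(params, "NetworkParams"))
  units <- as.integer(units)
  if (length(units)) {
    stopifnot(all(units >= 1), all(units <= nrow(params@wRec)))
    params@wRec[units, ] <- 0
    params@wRec[, units] <- 0
  }
  params
}

#' Delete one synapse group
#'
#' Zeroes every recurrent weight whose presynaptic (column) and
#' postsynaptic (row) populations match the named group. The four groups
#' `E->E`, `E->I`, `I->E`, `I->I` partition all off-diagonal entries.
#'
#' @param params A [NetworkParams-class].
#' @param group `"EE"`, `"EI"`, `"IE"`, or `"II"` (source then destination:
#'   `"IE"` deletes inhibitory-onto-excitatory synapses).
#' @return The lesioned [NetworkParams-class].
#' @export
deleteGroup <- function(params, group = c("EE", "EI", "IE", "II")) {
  group <- match.arg(group)
  m <- groupMaskSrcDst(params, group)
  params@wRec[m] <- 0
  params
}

# mask with "source -> destination" reading of the group name
groupMaskSrcDst <- function(params, group) {
  e <- isExcitatory(params)
  src <- substr(group, 1, 1) == "E"
  dst <- substr(group, 2, 2) == "E"
  outer(e == dst, e == src, "&")  # rows = destination, cols = source
}

#' Connectivity statistics per synapse group
#'
#' For each of the four Dale's-law groups, the connection probability
#' (fraction of off-diagonal entries whose clipped magnitude exceeds
#' `weightFloor`) and the mean magnitude over those present connections.
#' Training drives clipped weights to exactly zero, so a small floor
#' separates present from silenced synapses.
#'
#' @param params A [NetworkParams-class].
#' @param weightFloor Presence threshold on the clipped magnitude (1e-6).
#' @return Data frame with one row per group: `group`, `probability`,
#'   `meanWeight`.
#' @export
connectivityStats <- function(params, weightFloor = 1e-6) {
  W <- pmax(params@wRec, 0)
  diag(W) <- NA  # self-connections do not exist
  rows <- lapply(c("EE", "EI", "IE", "II"), function(g) {
    m <- groupMaskSrcDst(params, g)
    w <- W[m]
    w <- w[!is.na(w)]
    present <- w > weightFloor
    data.frame(group = g, probability = mean(present),
               meanWeight = if (any(present)) mean(w[present]) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Synapse-group deletion experiment
#'
#' Deletes each of the four connection groups in turn and measures
#' performance and mean error over noise-on test trials (plus the intact
#' baseline).
#'
#' @param params A trained [NetworkParams-class].
#' @param config The task's [TaskConfig-class].
#' @param trialsPerInterval Test trials per interval per condition (20).
#' @param seed Optional RNG seed.
#' @return Data frame `{condition, performance, meanError}` with rows
#'   `intact`, `EE`, `EI`, `IE`, `II`.
#' @export
groupDeletionExperiment <- function(params, config, trialsPerInterval = 20,
                                    seed = NULL) {
  withSeed(seed, {
    conds <- c("intact", "EE", "EI", "IE", "II")
    rows <- lapply(conds, function(g) {
      p <- if (g == "intact") params else deleteGroup(params, g)
      ev <- evaluateNetwork(p, config, nTrials = 2 * trialsPerInterval)
      data.frame(condition = g, performance = ev$performance,
                 meanError = ev$meanError)
    })
    do.call(rbind, rows)
  })
}

#' Class-targeted unit-deletion experiment
#'
#' For each timing class (stimulus-specific / scaling / absolute) crossed
#' with population (excitatory / inhibitory) and each deletion count,
#' randomly draws the units to delete from the class-by-population pool
#' `nSelections` times, runs `trialsPerInterval` noise-on test trials per
#' interval per selection, and averages performance and error across
#' selections and trials. Counts exceeding a pool are skipped with a
#' message.
#'
#' @param params A trained [NetworkParams-class].
#' @param classification The network's [TimingClassification-class].
#' @param config The task's [TaskConfig-class].
#' @param counts Deletion counts to sweep.
#' @param nSelections Random pool draws per condition (10).
#' @param trialsPerInterval Test trials per interval per selection (20).
#' @param seed Optional RNG seed.
#' @return Data frame `{class, population, count, poolSize, performance,
#'   meanError}`.
#' @export
runDeletionExperiment <- function(params, classification, config,
                                  counts = c(1, 2, 4, 6, 8, 10, 12),
                                  nSelections = 10, trialsPerInterval = 20,
                                  seed = NULL) {
  stopifnot(is(classification, "TimingClassification"))
  cls <- classLabels(classification)
  exc <- isExcitatory(params)
  withSeed(seed, {
    rows <- list()
    for (cl in c("stimulus-specific", "scaling", "absolute")) {
      for (pop in c("E", "I")) {
        pool <- which(cls == cl & (exc == (pop == "E")))
        for (count in counts) {
          if (count > length(pool)) {
            message(sprintf("pool %s/%s has %d units; skipping count %d",
                            cl, pop, length(pool), count))
            next
          }
          perf <- err <- numeric(nSelections)
          for (s in seq_len(nSelections)) {
            del <- pool[sample.int(length(pool), count)]
            ev <- evaluateNetwork(deleteUnits(params, del), config,
                                  nTrials = 2 * trialsPerInterval)
            perf[s] <- ev$performance
            err[s] <- ev$meanError
          }
          rows[[length(rows) + 1L]] <-
            data.frame(class = cl, population = pop, count = count,
                       poolSize = length(pool),
                       performance = mean(perf), meanError = mean(err))
        }
      }
    }
    do.call(rbind, rows)
  })
}
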