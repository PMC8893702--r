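#' Run the full analysis pipeline
#'
#' Orchestrates the stages train -> dynamics (1 ms trial-averaged rates) ->
#' behavior (generalization and noise sweeps) -> metrics (population SSI
#' and unit classification) -> perturb (synapse-group and class deletions)
#' -> geometry (PCA and segment angles), writing delimited tables and a
#' manifest to `outDir`. Stages can be restricted; later stages require the
#' artifacts of earlier ones (a checkpoint can be supplied instead of the
#' train stage). A `prototypes` stage generates the three analytic regime
#' pairs and their population SSI without any training. All randomness is
#' fanned out from the master seed with a counter-based scheme, so adding
#' a stage never shifts another stage's stream.
#'
#' @param config A [TaskConfig-class], or the path of a YAML task config.
#' @param outDir Output directory (created if needed).
#' @param stages Character vector of stages to run, in dependency order.
#' @param seed Master seed.
#' @param checkpoint Optional checkpoint path to load instead of training.
#' @param maxTrials Training budget.
#' @param nTrialsAverage Trials averaged for the analysis dynamics (25).
#' @param deletionCounts Counts for the class-deletion sweep.
#' @param verbose Log stage progress.
#' @return The manifest (named list), invisibly; also written as
#'   `manifest.yaml`.
#' @export
runPipeline <- function(config, outDir,
                        stages = c("train", "dynamics", "behavior",
                                   "metrics", "perturb", "geometry"),
                        seed = 1, checkpoint = NULL, maxTrials = 50000,
                        nTrialsAverage = 25,
                        deletionCounts = c(1, 2, 4, 6, 8, 10, 12),
                        verbose = TRUE) {
  if (is.character(config)) config <- readTaskConfig(config)
  stopifnot(is(config, "TaskConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(taskName = config@taskName, seed = seed,
                   stages = stages, completed = character(),
                   artifacts = list(),
                   rVersion = as.character(getRversion()))
  note <- function(...) if (verbose) message(sprintf(...))
  saveManifest <- function() {
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  }
  emit <- function(df, name) {
    path <- file.path(outDir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$artifacts[[name]] <<- path
    path
  }

  params <- NULL
  dynShort <- dynLong <- NULL
  classification <- NULL

  if ("prototypes" %in% stages) {
    note("stage prototypes")
    rows <- lapply(c("scaling", "absolute", "stimulus-specific"),
      function(rg) {
        p <- makePrototype(rg, seed = stageSeed(seed, "prototypes"))
        writeTrajectory(p, file.path(outDir, paste0("prototype-", rg, ".rds")))
        s <- computeSSIPop(p@short, p@long)
        data.frame(regime = rg, tauMin = s@tauMin, cTauMin = s@cTauMin,
                   ssiPop = s@ssiPop)
      })
    emit(do.call(rbind, rows), "prototype-ssi")
    manifest$completed <- c(manifest$completed, "prototypes")
    saveManifest()
  }

  if ("train" %in% stages) {
    note("stage train (%s)", config@taskName)
    st <- trainNetwork(config, maxTrials = maxTrials,
                       seed = stageSeed(seed, "train"), verbose = verbose)
    if (!st@converged) {
      manifest$failure <- "training did not converge"
      saveManifest()
      stop("training did not converge within ", maxTrials, " trials")
    }
    params <- networkParams(st)
    ck <- file.path(outDir, "checkpoint.rds")
    writeCheckpoint(params, ck, taskName = config@taskName, seed = seed)
    manifest$artifacts$checkpoint <- ck
    emit(st@history, "training-history")
    manifest$completed <- c(manifest$completed, "train")
    saveManifest()
  } else if (!is.null(checkpoint)) {
    params <- readCheckpoint(checkpoint)
    manifest$artifacts$checkpoint <- checkpoint
  }

  needNet <- intersect(stages, c("dynamics", "behavior", "metrics",
                                 "perturb", "geometry"))
  if (length(needNet) && is.null(params))
    stop("stages ", paste(needNet, collapse = ", "),
         " require a trained network: run the train stage or pass ",
         "`checkpoint`")

  if ("dynamics" %in% stages) {
    note("stage dynamics")
    s <- stageSeed(seed, "dynamics")
    dynShort <- averageDynamics(params, config, "short",
                                nTrials = nTrialsAverage, seed = s)
    dynLong <- averageDynamics(params, config, "long",
                               nTrials = nTrialsAverage, seed = s + 1L)
    writeTrajectory(dynShort, file.path(outDir, "dynamics-short.rds"))
    writeTrajectory(dynLong, file.path(outDir, "dynamics-long.rds"))
    manifest$completed <- c(manifest$completed, "dynamics")
    saveManifest()
  }

  if ("behavior" %in% stages) {
    note("stage behavior")
    gs <- generalizationSweep(params, config,
                              seed = stageSeed(seed, "behavior"))
    emit(gs$summary, "generalization")
    manifest$generalization <- list(r = gs$r, absR = gs$absR,
                                    g = if (!is.null(gs$fit)) gs$fit$g else NA)
    ns <- noiseSweep(params, config, seed = stageSeed(seed, "behavior") + 1L)
    emit(ns, "noise-sweep")
    manifest$completed <- c(manifest$completed, "behavior")
    saveManifest()
  }

  if ("metrics" %in% stages) {
    note("stage metrics")
    if (is.null(dynShort))
      stop("metrics stage requires the dynamics stage artifacts")
    s <- computeSSIPop(dynShort, dynLong)
    emit(data.frame(tauMin = s@tauMin, cTauMin = s@cTauMin,
                    ssiPop = s@ssiPop), "population-ssi")
    classification <- classifyUnits(dynShort, dynLong, tauStep = 10)
    emit(as.data.frame(classification), "unit-classification")
    manifest$completed <- c(manifest$completed, "metrics")
    saveManifest()
  }

  if ("perturb" %in% stages) {
    note("stage perturb")
    gd <- groupDeletionExperiment(params, config,
                                  seed = stageSeed(seed, "perturb"))
    emit(gd, "group-deletion")
    emit(connectivityStats(params), "connectivity")
    if (!is.null(classification)) {
      ud <- runDeletionExperiment(params, classification, config,
                                  counts = deletionCounts,
                                  seed = stageSeed(seed, "perturb") + 1L)
      emit(ud, "unit-deletion")
    }
    manifest$completed <- c(manifest$completed, "perturb")
    saveManifest()
  }

  if ("geometry" %in% stages) {
    note("stage geometry")
    if (is.null(dynShort))
      stop("geometry stage requires the dynamics stage artifacts")
    proj <- fitSubspace(dynShort, dynLong, params = params)
    emit(data.frame(component = seq_along(proj@varExplained),
                    varExplained = proj@varExplained), "variance-explained")
    emit(segmentAngles(proj), "segment-angles")
    manifest$completed <- c(manifest$completed, "geometry")
    saveManifest()
  }

  saveManifest()
  invisible(manifest)
}
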