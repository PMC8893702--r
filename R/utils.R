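# internal helpers

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic fan-out of a master seed into independent stage streams.
# Counter-based so inserting a stage never shifts another stage's stream;
# kept below 2^31 to stay a valid R integer seed.
stageSeed <- function(master, stage) {
  offsets <- c(tasks = 1L, train = 2L, dynamics = 3L, behavior = 4L,
               metrics = 5L, perturb = 6L, geometry = 7L, prototypes = 8L,
               eval = 9L)
  k <- if (is.character(stage)) offsets[[stage]] else as.integer(stage)
  as.integer((as.double(master) * 7919 + k * 104729) %% 2147483647)
}

# first index at or above threshold, NA_integer_ if none
firstCrossing <- function(x, threshold) {
  idx <- which(x >= threshold)
  if (length(idx)) idx[1L] else NA_integer_
}
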