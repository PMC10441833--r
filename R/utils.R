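# Internal helpers shared across modules.

# Run code with a local RNG state: seeds, then restores whatever state the
# caller had, so generators never perturb the session stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit string fingerprint (multiplicative rolling hash).
# Provenance / sub-seed derivation only, not cryptographic.
stringHash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Derive a per-stage sub-seed from a global seed
#'
#' Hashes the stage name into the global seed so that adding a pipeline
#' stage never perturbs the random streams of earlier stages.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return an integer seed below 2^31.
#' @export
subSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 2147483647 + stringHash(stage)) %%
             2147483647)
}

# Consistent condition classes so callers can distinguish failure modes.
lgeError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "lgentropyError")))
}
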