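## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
## seed = NULL leaves the RNG untouched (code draws from the ambient stream).
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derive a bounded child seed from a user seed (keeps values well inside
## 32-bit integer range so downstream set.seed() is always valid).
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + k) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Number of samples in a stimulus measurement window at a sampling rate.
windowSamples <- function(stim, samplingRate) {
  round(stim@measurementWindow / 1000 * samplingRate)
}
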