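# Evaluate `code` in the caller's frame under a temporary RNG state seeded
# by `seed`; the caller's RNG state is restored afterwards.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

MURMUR_CLASSES <- c("Present", "Unknown", "Absent")
OUTCOME_CLASSES <- c("Abnormal", "Normal")
LOCATIONS <- c("AV", "PV", "TV", "MV")
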