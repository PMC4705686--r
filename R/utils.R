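# Run code under a fixed RNG seed without disturbing the caller's RNG state.
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

# numbers formatted for TSV output; >= 10 significant digits so a
# write/read round trip reproduces scores to working precision
.fmtNum <- function(x, digits = 12L) {
  vapply(x, function(v) sprintf("%.*g", digits, v), character(1))
}

.stopIf <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)
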