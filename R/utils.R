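# Internal helpers.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# round() that matches the reporting precision of the results tables:
# currency and ratios to whole yuan, QALYs to 0.1.
fmt_yuan <- function(x) formatC(round(x), format = "d", big.mark = ",")
fmt_qaly <- function(x) formatC(x, format = "f", digits = 1)
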