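# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls do not perturb user RNG
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rt_categories <- c("fast", "medium", "slow")
rt_categories_all <- c("fast", "medium", "slow", "outlier")
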