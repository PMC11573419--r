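## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
## state afterwards so library calls do not perturb user simulations.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

## Deterministic sub-seed derivation; keeps results below .Machine$integer.max.
derive_seed <- function(master, ...) {
  idx <- c(...)
  x <- as.numeric(master) %% 2147483647
  for (i in idx) x <- (x * 48271 + as.numeric(i) * 9973 + 1) %% 2147483647
  as.integer(x %% 2147483646) + 1L
}

stop_config <- function(...) stop(..., call. = FALSE)

## last-observation-carried-forward then back-fill of the leading gap,
## within one patient series; fully-missing series returned unchanged.
fill_series <- function(x) {
  o <- !is.na(x)
  if (!any(o)) return(x)
  n <- length(x)
  idx <- cummax(ifelse(o, seq_len(n), 0L))
  idx[idx == 0L] <- which(o)[1L]
  x[idx]
}
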