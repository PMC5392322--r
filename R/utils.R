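# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All generator randomness is routed through this so no global state leaks.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == round(x)

# block mean of a numeric matrix by factor f (partial edge blocks averaged
# over the pixels they actually contain); result is ceil(h/f) x ceil(w/f)
block_mean <- function(m, f) {
  if (f == 1) return(m)
  gi <- ceiling(seq_len(nrow(m)) / f)
  gj <- ceiling(seq_len(ncol(m)) / f)
  s <- rowsum(m, gi, reorder = TRUE)
  s <- t(rowsum(t(s), gj, reorder = TRUE))
  s / outer(tabulate(gi), tabulate(gj))
}
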