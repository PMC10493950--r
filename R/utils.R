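## Internal helpers: seeded evaluation, argument checks, sparse
## 8-connectivity component labelling.

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched, so generators are pure functions of their
# arguments.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a master seed; stays below 2^31.
childSeed <- function(seed, k) {
  (as.numeric(seed) * 1000003 + as.numeric(k) * 7919) %% 2147483647
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Label connected components of a logical matrix under 8-connectivity.
# Operates on the sparse set of TRUE pixels (event masks are sparse), so the
# cost is proportional to the flagged area, not the frame size.
# Returns an integer matrix of labels (0 = background).
labelComponents <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (!length(idx)) return(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  inMask <- mask
  current <- 0L
  for (s in seq_along(idx)) {
    if (lab[idx[s]] != 0L) next
    current <- current + 1L
    queue <- idx[s]
    lab[idx[s]] <- current
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1L:1L) for (dc in -1L:1L) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (inMask[q] && lab[q] == 0L) {
          lab[q] <- current
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Sizes of the components of a logical matrix (named by label).
componentSizes <- function(mask) {
  lab <- labelComponents(mask)
  v <- lab[lab > 0L]
  if (!length(v)) return(integer(0))
  tabulate(v)
}
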