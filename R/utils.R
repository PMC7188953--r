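# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG state
#'
#' Runs `expr` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generation never perturbs surrounding randomness.
#'
#' @param seed integer seed (must be below 2^31).
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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

# Derive a stream-specific child seed from a base seed; keeps everything
# inside the 32-bit signed range.
derive_seed <- function(base, offset) {
  as.integer((as.numeric(base) * 48271 + as.numeric(offset)) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.dir_cache <- new.env(parent = emptyenv())

# The 13 unique distance-1 direction offsets of a 3D lattice (one per
# +/- pair of the 26-neighborhood).
directions13 <- function() {
  if (is.null(.dir_cache$d13)) {
    d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    d <- d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), , drop = FALSE]
    # keep one representative per +/- pair: first nonzero component positive
    keep <- apply(d, 1, function(v) {
      nz <- v[v != 0]
      nz[1] > 0
    })
    .dir_cache$d13 <- unname(d[keep, , drop = FALSE])
  }
  .dir_cache$d13
}

# All 26 neighbor offsets.
offsets26 <- function() {
  if (is.null(.dir_cache$o26)) {
    d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    .dir_cache$o26 <- unname(d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), ,
                               drop = FALSE])
  }
  .dir_cache$o26
}
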