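#' @include AllClasses.R
NULL

## Depth of every cell below the founder (founder = 0); NA signals a cycle or
## a broken chain. Vectorized pointer-chasing, O(n * depth).
.lv_depths <- function(ids, parents) {
  idx <- match(parents, ids)
  n <- length(ids)
  depth <- rep(NA_integer_, n)
  depth[is.na(idx)] <- 0L
  cur <- which(is.na(idx))
  d <- 0L
  while (length(cur) && d <= n) {
    d <- d + 1L
    cur <- which(idx %in% cur)
    cur <- cur[is.na(depth[cur])]
    depth[cur] <- d
  }
  depth
}

## Evaluate expr under a temporary RNG stream seeded with `seed`, restoring the
## caller's .Random.seed afterwards. seed = NULL uses the ambient stream.
.lv_with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.lv_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## closest index of `grid` to each element of `x`
.lv_nearest <- function(grid, x) {
  vapply(x, function(v) which.min(abs(grid - v)), integer(1))
}
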