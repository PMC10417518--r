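`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression under a temporary RNG seed
#'
#' Evaluates `expr` with the global random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards so that seeded package
#' operations never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream label, staying inside
# the 32-bit integer range.
deriveSeed <- function(seed, stream) {
  ch <- utf8ToInt(as.character(stream))
  s <- sum(ch * seq_along(ch))
  as.integer((as.double(seed) * 48271 + s) %% 2147483647)
}

# MobileNet-style channel rounding: nearest multiple of `divisor`, never
# below 90% of the requested width.
makeDivisible <- function(v, divisor = 8L) {
  newv <- max(divisor, as.integer(v + divisor / 2) %/% divisor * divisor)
  if (newv < 0.9 * v) newv <- newv + divisor
  as.integer(newv)
}

# 4-connected component labelling of a logical matrix (used by tests and the
# scene generator's self-checks).  Returns an integer matrix of labels, 0 for
# background.
labelComponents <- function(mask) {
  stopifnot(is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% H + 1L
      cc <- (p - 1L) %/% H + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1L]; cc2 <- cc + d[2L]
        if (rr >= 1L && rr <= H && cc2 >= 1L && cc2 <= W) {
          q <- rr + (cc2 - 1L) * H
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}
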