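# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state afterwards
# so library code never clobbers a user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Exact 1-NN distances from each row of `from` to the nearest row of `to`,
# both n x 2 coordinate matrices. Chunked so the pairwise block never exceeds
# ~8e6 doubles. `self` = TRUE means `from` and `to` are the same point set and
# a point must not count as its own neighbor.
nn_dist_chunked <- function(from, to, self = FALSE) {
  n_from <- nrow(from)
  n_to <- nrow(to)
  if (n_to == 0L || (self && n_to < 2L)) {
    stop("no target points available for nearest-neighbor search")
  }
  out <- numeric(n_from)
  chunk <- max(1L, floor(8e6 / n_to))
  tox <- to[, 1L]
  toy <- to[, 2L]
  start <- 1L
  while (start <= n_from) {
    end <- min(start + chunk - 1L, n_from)
    idx <- start:end
    dx <- outer(from[idx, 1L], tox, "-")
    dy <- outer(from[idx, 2L], toy, "-")
    d2 <- dx * dx + dy * dy
    if (self) {
      # same point set: mask the diagonal entries of the full matrix
      d2[cbind(seq_along(idx), idx)] <- Inf
    }
    out[idx] <- sqrt(.rowMins(d2))
    start <- end + 1L
  }
  out
}

.rowMins <- function(m) {
  # apply() would copy row-wise; pmin over columns is much faster here
  res <- rep(Inf, nrow(m))
  for (j in seq_len(ncol(m))) res <- pmin(res, m[, j])
  res
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
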