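# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force initialisation so we can save/restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of a master seed into per-stage / per-unit seeds.
# Keeps results in [0, 2^31): R's set.seed() takes a 32-bit integer.
derive_seed <- function(master, index) {
  if (is.null(master)) return(NULL)
  as.integer((as.numeric(master) + 7919 * as.numeric(index)) %% 2147483647)
}

# Circular shift: element i of the result is x[i + s] with periodic wrap.
circ_shift <- function(x, s) {
  n <- length(x)
  x[((seq_len(n) - 1 + s) %% n) + 1]
}

# Segment-intersection test for polygon simplicity (closed, first != last).
# O(n^2) over edge pairs; adjacent edges share an endpoint and are skipped.
is_simple_polygon <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  x1 <- xy[, 1]; y1 <- xy[, 2]
  x2 <- circ_shift(x1, 1); y2 <- circ_shift(y1, 1)
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    # candidate edges j > i, excluding neighbours of i (and edge n vs edge 1)
    j <- seq.int(i + 2, n)
    if (i == 1) j <- j[j != n]
    d1 <- cross(x1[i], y1[i], x2[i], y2[i], x1[j], y1[j])
    d2 <- cross(x1[i], y1[i], x2[i], y2[i], x2[j], y2[j])
    d3 <- cross(x1[j], y1[j], x2[j], y2[j], rep(x1[i], length(j)), rep(y1[i], length(j)))
    d4 <- cross(x1[j], y1[j], x2[j], y2[j], rep(x2[i], length(j)), rep(y2[i], length(j)))
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(FALSE)
  }
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a
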