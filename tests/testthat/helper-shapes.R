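# Shared fixture builders: all fixtures are rasterized in code.

draw_disk <- function(nr, nc, cr, cc, r) {
  m <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    span <- r^2 - (i - cr)^2
    if (span >= 0) {
      j0 <- ceiling(cc - sqrt(span)); j1 <- floor(cc + sqrt(span))
      m[i, max(1, j0):min(nc, j1)] <- 1L
    }
  }
  m
}

draw_rect <- function(nr, nc, r0, r1, c0, c1) {
  m <- matrix(0L, nr, nc)
  m[r0:r1, c0:c1] <- 1L
  m
}

# random rasterized convex polygon: intersection of half-planes through
# points on a circle
draw_convex <- function(nr, nc, n_sides, radius, seed) {
  set.seed(seed)
  ang <- sort(runif(n_sides, 0, 2 * pi))
  cr <- nr / 2; cc <- nc / 2
  m <- matrix(TRUE, nr, nc)
  for (a in ang) {
    # half-plane: points on the center side of the tangent at angle a
    px <- cr + radius * cos(a); py <- cc + radius * sin(a)
    d <- outer(seq_len(nr) - px, rep(1, nc)) * cos(a) +
      outer(rep(1, nr), seq_len(nc) - py) * sin(a)
    m <- m & (d <= 0)
  }
  mode(m) <- "integer"
  m
}

# brute-force all-pairs maximum distance (independent Feret oracle)
brute_feret <- function(idx) {
  best <- 0
  for (i in seq_len(nrow(idx))) {
    d2 <- (idx[, 1] - idx[i, 1])^2 + (idx[, 2] - idx[i, 2])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}
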