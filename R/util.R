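# Internal helpers: seeded RNG scoping, seed derivation, raster primitives.

# Evaluate expr under set.seed(seed) without disturbing the caller's RNG
# stream. All randomness in the package flows through this.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed from a master seed and integer offsets.
# Kept within [1, 2^31 - 2] so set.seed() always accepts it.
derive_seed <- function(master, ...) {
  off <- c(...)
  x <- as.double(master) %% 2147483647
  for (o in off) x <- (x * 48271 + as.double(o) + 1) %% 2147483647
  as.integer(x + 1)
}

# Pixels inside an ellipse, with a chord ("partial-volume") weight: the 2-D
# projection of an ellipsoidal body is brightest on its axis and falls off
# as sqrt(1 - q^2) toward the silhouette edge (q = normalised radius).
# Returns list(idx = linear indices (column-major), w = weights in (0, 1]).
# center = c(row, col), axes = c(a_row, a_col) semi-axes, theta rotation (rad).
ellipse_pixels <- function(shape, center, axes, theta = 0, chord = TRUE) {
  rr <- ceiling(max(axes)) + 1L
  r0 <- max(1L, floor(center[1] - rr)); r1 <- min(shape[1], ceiling(center[1] + rr))
  c0 <- max(1L, floor(center[2] - rr)); c1 <- min(shape[2], ceiling(center[2] + rr))
  if (r0 > r1 || c0 > c1) return(list(idx = integer(0), w = numeric(0)))
  rows <- r0:r1; cols <- c0:c1
  dr <- outer(rows - center[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - center[2])
  u <-  dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  q2 <- (u / axes[1])^2 + (v / axes[2])^2
  inside <- q2 <= 1
  ij <- which(inside, arr.ind = TRUE)
  idx <- (c0 - 1L + ij[, 2] - 1L) * shape[1] + (r0 - 1L + ij[, 1])
  w <- if (chord) sqrt(pmax(1 - q2[inside], 0.05)) else rep(1, length(idx))
  list(idx = idx, w = w)
}

disk_pixels <- function(shape, center, radius, chord = TRUE) {
  ellipse_pixels(shape, center, c(radius, radius), chord = chord)
}

# Pixels of a thick line segment (capsule of half-width w/2) from p0 to p1,
# each c(row, col), with the chord weight of a cylindrical process.
segment_pixels <- function(shape, p0, p1, width, chord = TRUE) {
  hw <- width / 2
  r0 <- max(1L, floor(min(p0[1], p1[1]) - hw - 1))
  r1 <- min(shape[1], ceiling(max(p0[1], p1[1]) + hw + 1))
  c0 <- max(1L, floor(min(p0[2], p1[2]) - hw - 1))
  c1 <- min(shape[2], ceiling(max(p0[2], p1[2]) + hw + 1))
  if (r0 > r1 || c0 > c1) return(list(idx = integer(0), w = numeric(0)))
  rows <- r0:r1; cols <- c0:c1
  pr <- outer(rows, rep(1, length(cols))); pc <- outer(rep(1, length(rows)), cols)
  v <- p1 - p0
  L2 <- sum(v^2)
  if (L2 < 1e-12) {
    d2 <- (pr - p0[1])^2 + (pc - p0[2])^2
  } else {
    tt <- pmin(pmax(((pr - p0[1]) * v[1] + (pc - p0[2]) * v[2]) / L2, 0), 1)
    d2 <- (pr - (p0[1] + tt * v[1]))^2 + (pc - (p0[2] + tt * v[2]))^2
  }
  inside <- d2 <= hw^2
  ij <- which(inside, arr.ind = TRUE)
  idx <- (c0 - 1L + ij[, 2] - 1L) * shape[1] + (r0 - 1L + ij[, 1])
  w <- if (chord) sqrt(pmax(1 - d2[inside] / hw^2, 0.05))
  else rep(1, length(idx))
  list(idx = idx, w = w)
}

# 8-connected labelling of a logical matrix by iterative flood fill.
# Works on a zero-padded copy so neighbour offsets cannot wrap across
# matrix edges. Intended for cell-sized crops; returns an integer matrix
# of labels (0 = background).
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  pr <- nr + 2L
  pad <- matrix(FALSE, pr, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  lab <- matrix(0L, pr, nc + 2L)
  nb <- c(-1L, 1L, -pr, pr, -pr - 1L, -pr + 1L, pr - 1L, pr + 1L)
  seen <- !pad
  cur <- 0L
  for (s in which(pad)) {
    if (seen[s]) next
    cur <- cur + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      lab[queue] <- cur
      cand <- unique(as.vector(outer(queue, nb, `+`)))
      cand <- cand[!seen[cand]]
      seen[cand] <- TRUE
      queue <- cand
    }
  }
  lab[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}

# Binary morphological closing with a 3x3 square structuring element,
# computed on a padded copy (dilation then erosion).
close3 <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  shift_or <- function(m, combine) {
    p <- matrix(FALSE, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- m
    out <- matrix(combine == "and", nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      s <- p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc), drop = FALSE]
      out <- if (combine == "or") out | s else out & s
    }
    out
  }
  dil <- shift_or(mask, "or")
  # erosion must treat outside-the-crop as foreground, or closing would
  # eat pixels on the crop border; pad with TRUE for the erosion pass
  p <- matrix(TRUE, nr + 4L, nc + 4L)
  p[3:(nr + 2L), 3:(nc + 2L)] <- dil
  ero <- matrix(TRUE, nr + 2L, nc + 2L)
  for (dr in -1:1) for (dc in -1:1)
    ero <- ero & p[(2 + dr):(nr + 3 + dr), (2 + dc):(nc + 3 + dc), drop = FALSE]
  ero[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}
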