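# Shared fixtures: all built in code at test time.

# Draw a filled ellipse mask directly (independent of the phantom module's
# coverage rasterization): pixel centres strictly inside the ellipse.
ellipse_mask <- function(shape, center, a, b, theta_deg = 0) {
  rows <- shape[1]; cols <- shape[2]
  x <- matrix(seq_len(cols) - center[2], rows, cols, byrow = TRUE)
  y <- -(matrix(seq_len(rows) - center[1], rows, cols))
  th <- theta_deg * pi / 180
  xp <- x * cos(th) + y * sin(th)
  yp <- -x * sin(th) + y * cos(th)
  m <- matrix(0L, rows, cols)
  m[(xp / a)^2 + (yp / b)^2 <= 1] <- 1L
  m
}

# A random smooth blob: union of a few overlapping discs around a centre.
random_blob <- function(shape = c(60L, 60L), n_discs = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(0L, shape[1], shape[2])
    ctr <- shape / 2
    for (i in seq_len(n_discs)) {
      c0 <- ctr + runif(2, -8, 8)
      r <- runif(1, 6, 14)
      rowd <- matrix(seq_len(shape[1]) - c0[1], shape[1], shape[2])
      cold <- matrix(seq_len(shape[2]) - c0[2], shape[1], shape[2], byrow = TRUE)
      m[rowd^2 + cold^2 <= r^2] <- 1L
    }
    m
  })
}

# O(n^2) oracles, deliberately naive and independent of the implementation
# (one explicit loop over points, vectorized arithmetic inside).
oracle_farthest_pair_length <- function(pts) {
  best <- 0
  for (i in seq_len(nrow(pts))) {
    d <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)
    best <- max(best, d)
  }
  best
}

oracle_max_of_nearest <- function(a, b) {
  best <- 0
  for (i in seq_len(nrow(a))) {
    dmin <- min(sqrt((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2))
    if (dmin > best) best <- dmin
  }
  best
}

oracle_surface_stats <- function(ca, cb) {
  mins_a <- apply(ca, 1, function(p) {
    min(sqrt((cb[, 1] - p[1])^2 + (cb[, 2] - p[2])^2))
  })
  mins_b <- apply(cb, 1, function(p) {
    min(sqrt((ca[, 1] - p[1])^2 + (ca[, 2] - p[2])^2))
  })
  list(mad = (mean(mins_a) + mean(mins_b)) / 2,
       hd = max(max(mins_a), max(mins_b)),
       ssd = (sum(mins_a) + sum(mins_b)) / (length(mins_a) + length(mins_b)))
}

# 64x64 phantom training pairs for the learning tests.
phantom_training_set <- function(n, seed, shape = c(64L, 64L)) {
  images <- array(0, c(shape[1], shape[2], 1L, n))
  masks <- array(0, c(shape[1], shape[2], 1L, n))
  rng <- phantom_ranges(shape)
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      p <- renalus:::sample_phantom_params(rng, shape, seed * 10000 + i,
                                           "sagittal")
      ph <- generate_sagittal_phantom(p)
      images[, , 1, i] <- ph$image$pixels
      masks[, , 1, i] <- ph$capsule
    }
  })
  list(images = images, masks = masks)
}

# Small nested config used across network tests.
tiny_config <- function(shape = c(32L, 32L), nested = TRUE) {
  network_config(depth = 3L, filters_per_level = c(2L, 4L, 8L),
                 kernel_size = 3L, input_shape = c(shape, 1L),
                 nested = nested)
}
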