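# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Validate a binary mask; returns an integer 0/1 matrix.
as_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) abort(sprintf("`%s` must be a matrix", arg))
  m <- mask
  storage.mode(m) <- "integer"
  if (anyNA(m) || any(m != 0L & m != 1L)) {
    abort(sprintf("`%s` must be binary (0/1)", arg))
  }
  m
}

mask_points <- function(mask) {
  which(mask != 0L, arr.ind = TRUE)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive scalar", name))
  }
  invisible(x)
}

# Separable Gaussian blur of a matrix (reflected borders).
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_reflect <- function(m, r, along) {
    if (along == 1) {
      rbind(m[r:1, , drop = FALSE], m, m[nrow(m):(nrow(m) - r + 1), , drop = FALSE])
    } else {
      cbind(m[, r:1, drop = FALSE], m, m[, ncol(m):(ncol(m) - r + 1), drop = FALSE])
    }
  }
  conv1 <- function(m, along) {
    p <- pad_reflect(m, r, along)
    out <- 0
    for (i in seq_along(k)) {
      if (along == 1) {
        out <- out + k[i] * p[i:(i + nrow(m) - 1L), , drop = FALSE]
      } else {
        out <- out + k[i] * p[, i:(i + ncol(m) - 1L), drop = FALSE]
      }
    }
    out
  }
  conv1(conv1(x, 1), 2)
}

# Bilinear resize of a numeric matrix to (rows, cols).
resize_bilinear <- function(x, rows, cols) {
  H <- nrow(x); W <- ncol(x)
  if (H == rows && W == cols) return(x)
  # map output pixel centers to input pixel centers
  ry <- (seq_len(rows) - 0.5) * H / rows + 0.5 - 0.5
  cx <- (seq_len(cols) - 0.5) * W / cols + 0.5 - 0.5
  r0 <- pmin(pmax(floor(ry), 1), H); r1 <- pmin(r0 + 1, H)
  c0 <- pmin(pmax(floor(cx), 1), W); c1 <- pmin(c0 + 1, W)
  fr <- pmin(pmax(ry - r0, 0), 1)
  fc <- pmin(pmax(cx - c0, 0), 1)
  a <- x[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc)
  b <- x[r1, c0, drop = FALSE] * outer(fr, 1 - fc)
  d <- x[r0, c1, drop = FALSE] * outer(1 - fr, fc)
  e <- x[r1, c1, drop = FALSE] * outer(fr, fc)
  a + b + d + e
}

euclid <- function(p1, p2) {
  sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
}
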